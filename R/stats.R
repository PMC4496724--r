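# Group-level statistics: integer percentage convention of the development/
# mutation-rate table, two-sided Fisher's exact test by hypergeometric
# enumeration, and a binomial logit-link model on per-embryo read counts
# fitted by iteratively reweighted least squares.

#' Integer percentage, rounded half away from zero
#'
#' The reporting convention of the development/mutation-rate table:
#' `100 * k / n` rounded half away from zero to an integer (so 22/48 gives
#' 46 and 4/35 gives 11).
#'
#' @param k Numerator count (0 <= k <= n).
#' @param n Denominator count (> 0).
#' @return Integer percent (vectorised).
#' @export
rate_percent <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  as.integer(floor(100 * k / n + 0.5))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration: the sum of probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (with a 1e-7 relative tolerance against floating-
#' point ties).
#'
#' @param a,b,c,d Cell counts, row-wise (`a b / c d`).
#' @return p-value in (0, 1]. A degenerate margin (an all-zero row or
#'   column) returns 1 with attribute `degenerate = TRUE` and a warning.
#' @export
#' @examples
#' fisher_exact_2x2(22, 26, 4, 31)
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate margin: p = 1 by convention", call. = FALSE)
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Fit the binomial logit-link model on per-embryo read counts
#'
#' Fits `(reads_edited, reads_not_edited) ~ nucleic_acid * enzyme` with a
#' logit link by iteratively reweighted least squares. Treatment coding
#' with reference levels `nucleic_acid = "DNA"` and `enzyme = "TALEN"`
#' (the best-performing combination); terms for single-level factors are
#' dropped, so a one-group data set fits an intercept-only model. Rows
#' with `time` equal to `"8h"`/`"8 h"` are excluded before fitting (no
#' TALEN data exists at that time point).
#'
#' @param data Data frame with columns `reads_edited`, `reads_not_edited`,
#'   and optionally `nucleic_acid`, `enzyme`, `time`, `embryo_id`.
#' @param ref_nucleic_acid,ref_enzyme Reference factor levels.
#' @param tol Convergence tolerance on the deviance change (default 1e-8).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A `binom_logit_fit`: `coefficients` (data frame `term`,
#'   `estimate`, `se`, `z`, `p`), `deviance`, `deviance_trace`,
#'   `iterations`, `converged`, `n`, plus the design matrix and fitted
#'   probabilities.
#' @export
fit_binomial_logit <- function(data, ref_nucleic_acid = "DNA",
                               ref_enzyme = "TALEN", tol = 1e-8,
                               max_iter = 100L) {
  stopifnot(all(c("reads_edited", "reads_not_edited") %in% names(data)))
  if ("time" %in% names(data)) {
    is8 <- gsub(" ", "", tolower(data$time)) == "8h"
    if (any(is8)) {
      message(sprintf("excluding %d embryo(s) at the 8 h time point", sum(is8)))
      data <- data[!is8, , drop = FALSE]
    }
  }
  k <- data$reads_edited; m <- data$reads_not_edited
  if (any(k < 0) || any(m < 0) || any(k + m == 0)) {
    stop("read counts must be non-negative and not both zero", call. = FALSE)
  }
  n <- k + m; y <- k / n

  X <- matrix(1, nrow = nrow(data), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  term_col <- function(col, ref, prefix) {
    f <- stats::relevel(factor(data[[col]]), ref = ref)
    if (nlevels(f) < 2L) return(NULL)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(prefix, levels(f)[-1])
    mm
  }
  na_col <- if ("nucleic_acid" %in% names(data))
    term_col("nucleic_acid", ref_nucleic_acid, "nucleic_acid") else NULL
  enz_col <- if ("enzyme" %in% names(data))
    term_col("enzyme", ref_enzyme, "enzyme") else NULL
  if (!is.null(na_col)) X <- cbind(X, na_col)
  if (!is.null(enz_col)) X <- cbind(X, enz_col)
  if (!is.null(na_col) && !is.null(enz_col)) {
    for (i in seq_len(ncol(na_col))) for (j in seq_len(ncol(enz_col))) {
      X <- cbind(X, na_col[, i] * enz_col[, j])
      colnames(X)[ncol(X)] <- paste0(colnames(na_col)[i], ":",
                                     colnames(enz_col)[j])
    }
  }

  dev_fun <- function(mu) {
    t1 <- ifelse(k > 0, k * log(k / (n * mu)), 0)
    t2 <- ifelse(m > 0, m * log(m / (n * (1 - mu))), 0)
    2 * sum(t1 + t2)
  }

  beta <- rep(0, ncol(X))
  mu <- rep(0.5, length(y))
  dev <- dev_fun(mu)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(1 - 1e-12, pmax(1e-12, mu))
    w <- n * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- tryCatch(solve(crossprod(X, X * w), crossprod(X, w * z)),
                    error = function(e) {
                      stop("IRLS failed (singular system): possible separation",
                           call. = FALSE)
                    })
    beta <- drop(fit)
    mu_new <- pmin(1 - 1e-12, pmax(1e-12, stats::plogis(drop(X %*% beta))))
    dev_new <- dev_fun(mu_new)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) / (0.1 + abs(dev_new)) < tol) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
  }
  if (!converged) {
    warning("IRLS did not converge within max_iter (possible separation)",
            call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- pmin(1 - 1e-12, pmax(1e-12, stats::plogis(eta)))
  w <- (k + m) * mu * (1 - mu)
  vcov <- solve(crossprod(X, X * w))
  se <- sqrt(diag(vcov))
  zstat <- beta / se
  coef <- data.frame(term = colnames(X), estimate = beta, se = se, z = zstat,
                     p = 2 * stats::pnorm(-abs(zstat)), stringsAsFactors = FALSE,
                     row.names = NULL)
  structure(list(coefficients = coef, deviance = dev,
                 deviance_trace = trace[-1], iterations = length(trace) - 1L,
                 converged = converged, n = nrow(X), design = X, fitted = mu,
                 vcov = vcov),
            class = "binom_logit_fit")
}

#' @export
print.binom_logit_fit <- function(x, ...) {
  cat(sprintf("<binom_logit_fit> %d embryos, deviance %.3f (%d IRLS iterations%s)\n",
              x$n, x$deviance, x$iterations,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between two nested binomial fits
#'
#' @param fit_full,fit_reduced `binom_logit_fit` objects on the same data.
#' @return List `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  stat <- fit_reduced$deviance - fit_full$deviance
  df <- ncol(fit_full$design) - ncol(fit_reduced$design)
  if (df <= 0) stop("fits are not nested in the expected order", call. = FALSE)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Validate a treatment-group count table
#'
#' Checks `0 <= n_edited <= n_analyzed <= n_blastocysts <= n_injected`;
#' the blastocyst/injected ordering may be violated when the analysis
#' included morulae, in which case the row is flagged rather than rejected.
#'
#' @param groups Data frame with columns `n_injected`, `n_blastocysts`,
#'   `n_analyzed`, `n_edited` (label columns are carried through).
#' @return The input with a logical `flag_morulae` column.
#' @export
validate_group_counts <- function(groups) {
  need <- c("n_injected", "n_blastocysts", "n_analyzed", "n_edited")
  stopifnot(all(need %in% names(groups)))
  with(groups, {
    if (any(n_edited < 0) || any(n_edited > n_analyzed)) {
      stop("need 0 <= n_edited <= n_analyzed", call. = FALSE)
    }
    if (any(n_analyzed > pmax(n_blastocysts, n_injected))) {
      stop("n_analyzed exceeds available embryos", call. = FALSE)
    }
  })
  groups$flag_morulae <- groups$n_blastocysts > groups$n_injected |
    groups$n_analyzed > groups$n_blastocysts
  groups
}

#' Bundled embryo development / mutation-rate cells
#'
#' Long-format table of the printed development and mutation-rate cells
#' (one row per `k/n (percent)` cell) used to validate [rate_percent()]
#' and the group comparisons.
#' @return Data frame with columns `nucleic_acid`, `protein`, `odn`,
#'   `time`, `metric`, `k`, `n`, `printed_pct`.
#' @export
group_rate_cells <- function() {
  path <- system.file("extdata", "embryo_group_rates.tsv", package = "ampledit")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(odn = "character"))
}

#' Bundled per-embryo allele-profile summaries (nuclease-only injections)
#'
#' Deep-sequencing allele summaries for nuclease-only injected embryos:
#' up to two mutant variants with their read percentages plus the combined
#' wild-type percentage.
#' @return Data frame `sample`, `material`, `time`, `variant1`, `pct1`,
#'   `variant2`, `pct2`, `pct_wt`.
#' @export
embryo_variant_profiles <- function() {
  path <- system.file("extdata", "zfn_embryo_allele_profiles.tsv",
                      package = "ampledit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
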