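# Internal helpers: seeded RNG scoping, DNA string utilities, Phred codecs,
# and the typed-rejection value used by the QC/mapping stages.

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Evaluate an expression under a local, explicit seed
#'
#' Saves and restores `.Random.seed` so no global random state leaks out of
#' seeded operations. All randomised functions in the package take an
#' explicit `seed` argument and route through this helper.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

is_dna <- function(seq) {
  grepl("^[ACGT]*$", seq)
}

assert_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !is_dna(seq)) {
    stop(sprintf("%s must be a single A/C/G/T string", what), call. = FALSE)
  }
  invisible(seq)
}

# Phred+33 (Sanger) codecs. Qualities are integer vectors internally.
phred_decode <- function(qual_string) {
  if (nchar(qual_string) == 0L) return(integer(0))
  utf8ToInt(qual_string) - 33L
}

phred_encode <- function(quals) {
  if (length(quals) == 0L) return("")
  intToUtf8(as.integer(quals) + 33L)
}

phred_to_error <- function(q) 10^(-q / 10)

# Typed rejection used by join_pair / align_read / extract_window so callers
# can count discards instead of handling conditions.
rejection <- function(reason, ...) {
  structure(list(reason = reason, ...), class = "ampledit_rejection")
}

#' Test whether a stage result is a typed rejection
#' @param x Object returned by [join_pair()], [align_read()] or
#'   [extract_window()].
#' @return `TRUE` for a rejection (e.g. `NO_OVERLAP`, `UNMAPPED`,
#'   `PARTIAL_SPAN`), `FALSE` otherwise.
#' @export
is_rejection <- function(x) inherits(x, "ampledit_rejection")

#' @export
print.ampledit_rejection <- function(x, ...) {
  cat("<rejection>", x$reason, "\n")
  invisible(x)
}

rejection_reason <- function(x) if (is_rejection(x)) x$reason else NA_character_

# substitution kind of a single base change
sub_kind <- function(from, to) {
  if (from == to) stop("not a substitution", call. = FALSE)
  if ((from %in% PURINES) == (to %in% PURINES)) "TS" else "TV"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
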