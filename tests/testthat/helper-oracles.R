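# Independent brute-force oracles. These deliberately share no code with
# the implementation: the trimmer scores every substring, the joiner tries
# every overlap, the aligner is a plain-R Gotoh DP, and the Fisher oracle
# enumerates every table with the observed margins.

# Longest substring whose bases all have error probability < max_err,
# by scoring every substring (O(n^2)); leftmost tie wins.
oracle_trim <- function(seq, quals, max_err = 0.01) {
  n <- nchar(seq)
  ok <- 10^(-quals / 10) < max_err
  best <- c(start = 0L, len = 0L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(ok[i:j]) && (j - i + 1L) > best["len"]) {
        best <- c(start = i, len = j - i + 1L)
      }
    }
  }
  if (best["len"] == 0L) return("")
  substr(seq, best[["start"]], best[["start"]] + best[["len"]] - 1L)
}

# All-offsets joiner: reverse-complement r2, try every overlap length,
# return the longest >= min_overlap with 100% identity (or NA).
oracle_join <- function(r1, r2, min_overlap = 14) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r2rc <- paste(rev(comp[strsplit(r2, "")[[1]]]), collapse = "")
  n1 <- nchar(r1); n2 <- nchar(r2rc)
  for (ov in rev(seq_len(min(n1, n2)))) {
    if (ov < min_overlap) break
    if (substr(r1, n1 - ov + 1L, n1) == substr(r2rc, 1L, ov)) {
      return(list(seq = paste0(r1, substr(r2rc, ov + 1L, n2)), overlap = ov))
    }
  }
  NA
}

# Plain-R affine-gap semi-global DP (pattern global, free subject
# overhangs). Gap of length L costs open + L * ext, matching the
# implementation's convention. Returns the optimal score only.
oracle_semiglobal_score <- function(pattern, subject, match = 2,
                                    mismatch = -3, open = 12, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)  # gap in subject (pattern insertion)
  Iy <- matrix(NEG, m + 1, n + 1)  # gap in pattern (deletion)
  M[1, ] <- 0                      # free subject prefix
  for (i in 1:m) Ix[i + 1, 1] <- -(open + ext * i)
  for (i in 1:m) {
    for (j in 1:n) {
      sc <- if (p[i] == s[j]) match else mismatch
      M[i + 1, j + 1] <- sc + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext,
                              Iy[i, j + 1] - (open + ext))
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext,
                              Ix[i + 1, j] - (open + ext))
    }
  }
  max(M[m + 1, ], Ix[m + 1, ])     # free subject suffix
}

# Exact two-sided Fisher p by enumerating all tables with the observed
# margins; probabilities from binomial coefficients directly.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  p_tab <- function(k) {
    exp(lchoose(c1, k) + lchoose(c2, r1 - k) - lchoose(N, r1))
  }
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(ks, p_tab, 0)
  sum(probs[probs <= p_tab(a) * (1 + 1e-7)])
}

random_phred <- function(n) sample(2:41, n, replace = TRUE)

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
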