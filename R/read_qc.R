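# Read pre-processing: quality trimming to the longest contiguous
# high-quality segment, exact-overlap pair joining, and joined-length
# filtering. Thresholds follow the assay defaults: per-base error
# probability < 0.01 (Phred > 20), minimum overlap 14 bases at 100%
# identity, minimum joined length 250 bases.

#' Trimming configuration
#' @param max_error_prob A base is kept when its per-base error probability
#'   `10^(-Q/10)` is strictly below this (default 0.01, i.e. Q > 20).
#' @return A `trim_config` object.
#' @export
trim_config <- function(max_error_prob = 0.01) {
  if (max_error_prob <= 0 || max_error_prob >= 1) {
    stop("max_error_prob must be in (0, 1)", call. = FALSE)
  }
  structure(list(max_error_prob = max_error_prob), class = "trim_config")
}

#' Joining configuration
#' @param min_overlap Minimum read overlap in bases (default 14).
#' @param min_joined_length Joined reads shorter than this are removed
#'   (default 250).
#' @return A `join_config` object. Overlap identity is fixed at 100%:
#'   mismatch-tolerant joining is deliberately not offered.
#' @export
join_config <- function(min_overlap = 14, min_joined_length = 250) {
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  structure(list(min_overlap = as.integer(min_overlap),
                 required_identity = 1.0,
                 min_joined_length = as.integer(min_joined_length)),
            class = "join_config")
}

#' Trim a read to its longest contiguous high-quality segment
#'
#' Keeps the longest run of bases whose per-base error probability
#' `10^(-Q/10)` is strictly below `cfg$max_error_prob`; ties between
#' equally long runs go to the leftmost. The result may be empty.
#'
#' @param seq DNA string.
#' @param quals Phred qualities: an integer vector or a Phred+33 string of
#'   the same length as `seq`.
#' @param cfg A [trim_config()].
#' @return List `seq`, `quals` (integer vector), `start`, `end` (1-based
#'   coordinates in the input; 0/-1 when everything is trimmed).
#' @export
trim_longest_segment <- function(seq, quals, cfg = trim_config()) {
  if (is.character(quals)) quals <- phred_decode(quals)
  if (nchar(seq) != length(quals)) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  good <- phred_to_error(quals) < cfg$max_error_prob
  if (!any(good)) {
    return(list(seq = "", quals = integer(0), start = 0L, end = -1L))
  }
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the leftmost tie
  list(seq = substr(seq, starts[best], ends[best]),
       quals = quals[starts[best]:ends[best]],
       start = starts[best], end = ends[best])
}

#' Join one read pair by exact overlap
#'
#' Read 2 is supplied in raw orientation and reverse-complemented
#' internally. Candidate overlaps are scanned from the longest possible
#' down to `cfg$min_overlap`; the first (longest) overlap with 100% base
#' identity wins. In the overlap the shared base is kept with the maximum
#' of the two qualities.
#'
#' @param r1_seq,r1_qual Read 1 sequence and qualities (integer vector or
#'   Phred+33 string).
#' @param r2_seq,r2_qual Read 2, raw orientation.
#' @param cfg A [join_config()].
#' @return List `seq`, `quals`, `overlap_len` on success, or a typed
#'   `NO_OVERLAP` rejection (see [is_rejection()]).
#' @export
join_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual, cfg = join_config()) {
  if (is.character(r1_qual)) r1_qual <- phred_decode(r1_qual)
  if (is.character(r2_qual)) r2_qual <- phred_decode(r2_qual)
  n1 <- nchar(r1_seq); n2 <- nchar(r2_seq)
  if (min(n1, n2) < cfg$min_overlap) return(rejection("NO_OVERLAP"))
  r2rc <- revcomp(r2_seq)
  q2rc <- rev(r2_qual)
  for (ov in seq(min(n1, n2), cfg$min_overlap)) {
    if (substr(r1_seq, n1 - ov + 1L, n1) == substr(r2rc, 1L, ov)) {
      seq <- paste0(r1_seq, substr(r2rc, ov + 1L, n2))
      q_ov <- pmax(r1_qual[(n1 - ov + 1L):n1], q2rc[seq_len(ov)])
      quals <- c(r1_qual[seq_len(n1 - ov)], q_ov,
                 if (ov < n2) q2rc[(ov + 1L):n2] else integer(0))
      return(list(seq = seq, quals = quals, overlap_len = ov))
    }
  }
  rejection("NO_OVERLAP")
}

# Vectorised joiner used by the pipeline: same contract as join_pair()
# applied row-wise to data frames (id, seq, qual). Scans overlap lengths
# from longest to shortest across all still-undecided pairs at once.
join_pairs <- function(r1, r2, cfg = join_config()) {
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  if (n == 0L) {
    return(list(joined = data.frame(id = character(0), seq = character(0),
                                    qual = character(0),
                                    overlap_len = integer(0)),
                n_rejected = 0L, rejected_ids = character(0)))
  }
  n1 <- nchar(r1$seq); n2 <- nchar(r2$seq)
  r2rc <- revcomp(r2$seq)  # empty strings reverse-complement to ""
  overlap <- rep(NA_integer_, n)
  for (ov in seq(max(c(pmin(n1, n2), cfg$min_overlap)), cfg$min_overlap)) {
    open <- which(is.na(overlap) & pmin(n1, n2) >= ov)
    if (!length(open)) next
    hit <- substr(r1$seq[open], n1[open] - ov + 1L, n1[open]) ==
      substr(r2rc[open], 1L, ov)
    overlap[open[hit]] <- ov
  }
  ok <- which(!is.na(overlap))
  joined <- data.frame(id = r1$id[ok], seq = character(length(ok)),
                       qual = character(length(ok)),
                       overlap_len = overlap[ok], stringsAsFactors = FALSE)
  for (j in seq_along(ok)) {
    i <- ok[j]; ov <- overlap[i]
    q1 <- phred_decode(r1$qual[i]); q2rc <- rev(phred_decode(r2$qual[i]))
    joined$seq[j] <- paste0(r1$seq[i], substr(r2rc[i], ov + 1L, n2[i]))
    q_ov <- pmax(q1[(n1[i] - ov + 1L):n1[i]], q2rc[seq_len(ov)])
    joined$qual[j] <- phred_encode(
      c(q1[seq_len(n1[i] - ov)], q_ov,
        if (ov < n2[i]) q2rc[(ov + 1L):n2[i]] else integer(0)))
  }
  list(joined = joined, n_rejected = n - length(ok),
       rejected_ids = r1$id[is.na(overlap)])
}

#' Remove joined reads shorter than the minimum length
#'
#' @param reads Data frame of joined reads (column `seq`).
#' @param cfg A [join_config()]; the boundary length itself
#'   (`min_joined_length`, default 250) is kept.
#' @return List `kept` (surviving rows), `n_removed`.
#' @export
length_filter <- function(reads, cfg = join_config()) {
  keep <- nchar(reads$seq) >= cfg$min_joined_length
  list(kept = reads[keep, , drop = FALSE], n_removed = sum(!keep))
}
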