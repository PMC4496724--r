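# Mapping joined reads to the reference amplicon and enumerating key-window
# alleles. Alignment is single-pass semi-global (read global, reference
# local) with affine gap penalties, replacing the interactive mapper the
# assay used; contiguous 5-24 bp indels are recovered as single gap events
# under the default scores.

#' Alignment configuration
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -3).
#' @param gap_open Gap opening penalty, positive (default 12). A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty per base, positive (default 1).
#' @param min_identity_to_map Reads whose matching-base fraction (matches /
#'   read length) falls below this are rejected as `UNMAPPED` (default 0.7).
#' @param require_full_window_span Reject reads that do not cover both key
#'   window boundaries (`PARTIAL_SPAN`; default `TRUE`).
#' @return An `align_config` object.
#' @export
align_config <- function(match = 2, mismatch = -3, gap_open = 12,
                         gap_extend = 1, min_identity_to_map = 0.7,
                         require_full_window_span = TRUE) {
  if (gap_open < gap_extend || gap_extend < 0) {
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_identity_to_map = min_identity_to_map,
                 require_full_window_span = require_full_window_span),
            class = "align_config")
}

substitution_matrix <- function(cfg) {
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$match,
                                           mismatch = cfg$mismatch,
                                           baseOnly = TRUE)
}

#' Align a joined read to the reference amplicon
#'
#' Semi-global alignment (the full read against a substring of the
#' reference; reference overhangs are free). Both orientations are tried
#' and the higher-scoring one wins. Identity is the fraction of read bases
#' matching the reference; below `min_identity_to_map` the read is rejected.
#'
#' @param seq Read sequence (joined read).
#' @param locus A `reference_locus`.
#' @param cfg An [align_config()].
#' @return List `pattern` and `subject` (aligned strings with `-` gaps),
#'   `ref_start`, `ref_end` (1-based reference span), `score`, `identity`,
#'   `orientation` (`"+"`/`"-"`), or an `UNMAPPED` rejection.
#' @export
align_read <- function(seq, locus, cfg = align_config()) {
  if (nchar(seq) == 0L) stop("cannot align an empty read", call. = FALSE)
  res <- align_reads(seq, locus, cfg)[[1]]
  res
}

# Vectorised alignment of many reads (deduplicated by the caller if
# desired). Returns a list, per read, of alignment lists or rejections.
align_reads <- function(seqs, locus, cfg = align_config()) {
  sm <- substitution_matrix(cfg)
  subject <- Biostrings::DNAString(locus$amplicon_seq)
  pat_fwd <- Biostrings::DNAStringSet(seqs)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  aln_one <- function(pat, score_only = FALSE) {
    Biostrings::pairwiseAlignment(pat, subject, type = "global-local",
                                  substitutionMatrix = sm,
                                  gapOpening = cfg$gap_open,
                                  gapExtension = cfg$gap_extend,
                                  scoreOnly = score_only)
  }
  # cheap score-only pre-pass decides the orientation; full alignments are
  # computed once per read in its winning orientation
  use_rev <- aln_one(pat_rev, score_only = TRUE) >
    aln_one(pat_fwd, score_only = TRUE)
  out <- vector("list", length(seqs))
  for (orient in c(FALSE, TRUE)) {
    idx <- which(use_rev == orient)
    if (!length(idx)) next
    aln <- aln_one(if (orient) pat_rev[idx] else pat_fwd[idx])
    pa <- as.character(Biostrings::pattern(aln))
    sa <- as.character(Biostrings::subject(aln))
    sc <- Biostrings::score(aln)
    nm <- Biostrings::nmatch(aln)
    st <- BiocGenerics::start(Biostrings::subject(aln))
    en <- BiocGenerics::end(Biostrings::subject(aln))
    for (j in seq_along(idx)) {
      i <- idx[j]
      identity <- nm[j] / nchar(seqs[i])
      out[[i]] <- if (identity < cfg$min_identity_to_map) {
        rejection("UNMAPPED", identity = identity)
      } else {
        list(pattern = pa[j], subject = sa[j], ref_start = st[j],
             ref_end = en[j], score = sc[j], identity = identity,
             orientation = if (orient) "-" else "+")
      }
    }
  }
  out
}

#' Extract the gap-free key-window sequence from an alignment
#'
#' Takes the read bases aligned within the key window (reference
#' coordinates), including insertions anchored inside the window, and
#' removes gap characters. Reads that do not cover both window boundaries
#' are rejected as `PARTIAL_SPAN` when the configuration requires a full
#' span.
#'
#' @param alignment Result of [align_read()].
#' @param locus A `reference_locus`.
#' @param require_full_window_span Override of the alignment-config flag.
#' @return The gap-free window DNA string, or a `PARTIAL_SPAN` rejection.
#' @export
extract_window <- function(alignment, locus, require_full_window_span = TRUE) {
  if (is_rejection(alignment)) return(alignment)
  ws <- locus$key_start; we <- locus$key_end
  if (require_full_window_span &&
      (alignment$ref_start > ws || alignment$ref_end < we)) {
    return(rejection("PARTIAL_SPAN", ref_start = alignment$ref_start,
                     ref_end = alignment$ref_end))
  }
  pa <- strsplit(alignment$pattern, "")[[1]]
  sa <- strsplit(alignment$subject, "")[[1]]
  is_ref <- sa != "-"
  refpos <- numeric(length(sa))
  refpos[is_ref] <- alignment$ref_start + cumsum(is_ref)[is_ref] - 1L
  # insertions sit between reference bases: anchor them after the previous
  # reference position (pos + 0.5); insertions before the aligned region
  # cannot occur in a global-local alignment of the pattern
  prev <- cummax(ifelse(is_ref, refpos, 0))
  refpos[!is_ref] <- prev[!is_ref] + 0.5
  keep <- refpos >= ws & refpos <= we & pa != "-"
  paste(pa[keep], collapse = "")
}

#' Enumerate unique key-window alleles
#'
#' Counts every distinct window sequence. The report always contains the
#' two wild-type window sequences (even at count 0) plus every other
#' sequence whose fraction of `total_joined` strictly exceeds
#' `report_threshold` (the "over 1% of reads" rule). Sorted by count
#' descending, ties lexicographically by sequence.
#'
#' @param window_seqs Character vector of gap-free window sequences.
#' @param total_joined Denominator for fractions; defaults to
#'   `length(window_seqs)` (mapped joined reads).
#' @param locus A `reference_locus` (provides the wild-type windows).
#' @param report_threshold Strict reporting threshold (default 0.01).
#' @return Data frame `seq`, `count`, `fraction`, `wt` (`"A"`, `"B"` or
#'   `NA`), with attributes `total` and `n_unreported` (reads in
#'   sub-threshold non-wild-type sequences).
#' @export
enumerate_alleles <- function(window_seqs, total_joined = length(window_seqs),
                              locus, report_threshold = 0.01) {
  if (total_joined < length(window_seqs)) {
    stop("total_joined cannot be smaller than the number of sequences",
         call. = FALSE)
  }
  wt_a <- wt_seq(locus, "A", window = TRUE)
  wt_b <- wt_seq(locus, "B", window = TRUE)
  tab <- table(window_seqs)
  seqs <- names(tab)
  counts <- as.integer(tab)
  # wild-type rows are always present
  for (w in unique(c(wt_a, wt_b))) {
    if (!w %in% seqs) {
      seqs <- c(seqs, w); counts <- c(counts, 0L)
    }
  }
  fraction <- counts / total_joined
  is_wt <- seqs == wt_a | seqs == wt_b
  keep <- is_wt | fraction > report_threshold
  out <- data.frame(seq = seqs[keep], count = counts[keep],
                    fraction = fraction[keep],
                    wt = ifelse(seqs[keep] == wt_a, "A",
                                ifelse(seqs[keep] == wt_b, "B", NA_character_)),
                    stringsAsFactors = FALSE)
  if (wt_a == wt_b) out$wt[out$seq == wt_a] <- "A/B"
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- as.integer(total_joined)
  attr(out, "n_unreported") <- sum(counts[!keep])
  out
}

#' Map joined reads and extract key-window sequences in bulk
#'
#' Deduplicates identical joined reads before alignment, aligns the unique
#' sequences, extracts the key window from each, and expands back to
#' per-read window sequences.
#'
#' @param reads Data frame of joined reads (column `seq`).
#' @param locus A `reference_locus`.
#' @param cfg An [align_config()].
#' @return List `windows` (character vector, one entry per surviving read),
#'   `n_unmapped`, `n_partial_span`.
#' @export
map_reads <- function(reads, locus, cfg = align_config()) {
  if (nrow(reads) == 0L) {
    return(list(windows = character(0), n_unmapped = 0L, n_partial_span = 0L))
  }
  uniq <- unique(reads$seq)
  alns <- align_reads(uniq, locus, cfg)
  win <- vapply(alns, function(a) {
    w <- extract_window(a, locus, cfg$require_full_window_span)
    if (is_rejection(w)) paste0("__", w$reason) else w
  }, "")
  per_read <- win[match(reads$seq, uniq)]
  list(windows = per_read[!startsWith(per_read, "__")],
       n_unmapped = sum(per_read == "__UNMAPPED"),
       n_partial_span = sum(per_read == "__PARTIAL_SPAN"))
}
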