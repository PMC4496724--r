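# Reference amplicon locus: the sequenced amplicon, the key-mutation window
# that allele calling operates on, the two wild-type backgrounds A/B defined
# by polymorphic sites, and the nuclease cut-site cassette that carries the
# diagnostic restriction motifs.

# Cut-site cassette layout, anchored at `cut_site` (1-based, the "T"):
#   [T][GGCGCC][TGA]
# The SfoI motif (GGCGCC) sits at cut_site+1 .. cut_site+6. The canonical
# 9-base deletion template removes cut_site+1 .. cut_site+9 (destroying
# SfoI); the canonical 5-base insertion template inserts "CTAGA" after the
# anchor T, creating an XbaI motif (TCTAGA).
CASSETTE <- "TGGCGCCTGA"
XBAI_MOTIF <- "TCTAGA"
SFOI_MOTIF <- "GGCGCC"

#' Construct a reference amplicon locus with a key-mutation window
#'
#' Generates a random amplicon of the study geometry: a ~550 bp amplicon,
#' a centred key-mutation window (71 bp by default), a nuclease cut-site
#' cassette in the middle of the window carrying one SfoI site, and
#' `n_poly_sites` polymorphic positions that distinguish the two wild-type
#' backgrounds A and B. The amplicon sequence is the B background; A is
#' obtained by substituting the A-state bases at the polymorphic sites.
#'
#' The flanks are rejection-sampled so that the wild-type alleles and the
#' two canonical edit templates (9 bp deletion, 5 bp insertion; see
#' [odn_template_edits()]) carry exactly the diagnostic motif counts:
#' one SfoI and no XbaI site in wild type, SfoI lost after the deletion,
#' XbaI gained after the insertion.
#'
#' @param length Amplicon length in bases (default 550).
#' @param key_region_length Key-window length in bases (default 71).
#' @param n_poly_sites Number of A/B polymorphic sites (default 3); sites
#'   are placed inside the key window but outside a protected zone of
#'   `cut_margin` bases around the cut cassette, so deletions at the cut
#'   site leave the background-diagnostic bases intact.
#' @param seed Integer seed; the locus is byte-identical for a fixed seed.
#' @param name Locus name used in reports and FASTA headers.
#' @param cut_margin Half-width of the protected zone around the cassette.
#' @return An object of class `reference_locus`: a list with
#'   `name`, `amplicon_seq`, `key_start`, `key_end` (1-based inclusive),
#'   `cut_site`, and `poly_sites` (data frame `pos`, `base_a`, `base_b`).
#' @export
#' @examples
#' loc <- make_reference_locus(seed = 1)
#' substr(loc$amplicon_seq, loc$key_start, loc$key_end)
make_reference_locus <- function(length = 550, key_region_length = 71,
                                 n_poly_sites = 3, seed = 1,
                                 name = "amplicon", cut_margin = 15) {
  if (length <= 0 || key_region_length <= 0) {
    stop("amplicon and key-region lengths must be positive", call. = FALSE)
  }
  if (key_region_length > length) {
    stop("key region cannot exceed the amplicon", call. = FALSE)
  }
  if (n_poly_sites < 0 || n_poly_sites > key_region_length) {
    stop("n_poly_sites must be between 0 and the key-region length",
         call. = FALSE)
  }
  cass_len <- nchar(CASSETTE)
  if (key_region_length < cass_len + 2 * cut_margin + n_poly_sites) {
    stop("key region too short for cassette, protected zone and poly sites",
         call. = FALSE)
  }

  key_start <- (length - key_region_length) %/% 2 + 1L
  key_end <- key_start + key_region_length - 1L
  cut_site <- key_start + (key_region_length - cass_len) %/% 2

  with_seed(seed, {
    repeat {
      chars <- sample(DNA_BASES, length, replace = TRUE)
      chars[cut_site:(cut_site + cass_len - 1L)] <- strsplit(CASSETTE, "")[[1]]
      seq_b <- paste(chars, collapse = "")

      protected <- (cut_site - cut_margin):(cut_site + cass_len - 1L + cut_margin)
      candidates <- setdiff(key_start:key_end, protected)
      pos <- sort(sample(candidates, n_poly_sites))
      base_b <- chars[pos]
      base_a <- vapply(base_b, function(b) sample(setdiff(DNA_BASES, b), 1L), "")

      locus <- structure(
        list(name = name, amplicon_seq = seq_b,
             key_start = key_start, key_end = key_end, cut_site = cut_site,
             poly_sites = data.frame(pos = as.integer(pos), base_a = unname(base_a),
                                     base_b = unname(base_b),
                                     stringsAsFactors = FALSE)),
        class = "reference_locus")
      if (locus_motifs_clean(locus)) return(locus)
    }
  })
}

# Validate that wild types and canonical template alleles carry exactly the
# expected diagnostic motif counts (rejection-sampling predicate).
locus_motifs_clean <- function(locus) {
  count <- function(seq, motif) {
    length(Biostrings::matchPattern(motif, Biostrings::DNAString(seq)))
  }
  edits <- odn_template_edits(locus)
  for (bg in c("A", "B")) {
    wt <- wt_seq(locus, bg)
    if (count(wt, SFOI_MOTIF) != 1L || count(wt, XBAI_MOTIF) != 0L) return(FALSE)
    del <- apply_edit_chars(locus, edits$del9, bg)$seq
    if (count(del, SFOI_MOTIF) != 0L || count(del, XBAI_MOTIF) != 0L) return(FALSE)
    ins <- apply_edit_chars(locus, edits$ins5, bg)$seq
    if (count(ins, SFOI_MOTIF) != 1L || count(ins, XBAI_MOTIF) != 1L) return(FALSE)
  }
  TRUE
}

validate_locus <- function(locus) {
  stopifnot(inherits(locus, "reference_locus"))
  n <- nchar(locus$amplicon_seq)
  assert_dna(locus$amplicon_seq, "amplicon_seq")
  if (locus$key_start < 1L || locus$key_end > n || locus$key_start > locus$key_end) {
    stop("key region must lie within the amplicon", call. = FALSE)
  }
  ps <- locus$poly_sites
  if (nrow(ps) > 0 &&
      (any(ps$pos < locus$key_start) || any(ps$pos > locus$key_end))) {
    stop("polymorphic sites must lie within the key region", call. = FALSE)
  }
  if (anyDuplicated(ps$pos)) stop("polymorphic sites must be distinct", call. = FALSE)
  if (nrow(ps) > 0 && any(ps$base_a == ps$base_b)) {
    stop("polymorphic sites must differ between A and B", call. = FALSE)
  }
  invisible(locus)
}

#' Wild-type allele sequence for a background
#'
#' @param locus A `reference_locus`.
#' @param background `"A"` or `"B"`. The amplicon sequence is the B
#'   background; A substitutes the A-state bases at the polymorphic sites.
#' @param window If `TRUE`, return only the key-window sequence.
#' @return DNA string.
#' @export
wt_seq <- function(locus, background = c("B", "A"), window = FALSE) {
  background <- match.arg(background)
  chars <- strsplit(locus$amplicon_seq, "")[[1]]
  if (background == "A" && nrow(locus$poly_sites) > 0) {
    chars[locus$poly_sites$pos] <- locus$poly_sites$base_a
  }
  if (window) chars <- chars[locus$key_start:locus$key_end]
  paste(chars, collapse = "")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s: %d bp amplicon, key window %d-%d (%d bp), cut site %d, %d polymorphic site(s)\n",
              x$name, nchar(x$amplicon_seq), x$key_start, x$key_end,
              x$key_end - x$key_start + 1L, x$cut_site, nrow(x$poly_sites)))
  invisible(x)
}

#' Write / read a locus description (YAML)
#'
#' Serialises the locus (sequence, window, cut site, polymorphic sites) so a
#' pipeline run can be reproduced from files alone.
#' @param locus A `reference_locus`.
#' @param path Output file.
#' @return `write_locus` returns `path` invisibly; `read_locus` returns the
#'   `reference_locus`.
#' @export
write_locus <- function(locus, path) {
  obj <- unclass(locus)
  obj$poly_sites <- lapply(seq_len(nrow(locus$poly_sites)), function(i)
    as.list(locus$poly_sites[i, , drop = FALSE]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_locus
#' @export
read_locus <- function(path) {
  obj <- yaml::read_yaml(path)
  ps <- if (length(obj$poly_sites)) {
    do.call(rbind, lapply(obj$poly_sites, function(e)
      data.frame(pos = as.integer(e$pos), base_a = e$base_a, base_b = e$base_b,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(pos = integer(0), base_a = character(0), base_b = character(0))
  }
  locus <- structure(
    list(name = obj$name, amplicon_seq = obj$amplicon_seq,
         key_start = as.integer(obj$key_start), key_end = as.integer(obj$key_end),
         cut_site = as.integer(obj$cut_site), poly_sites = ps),
    class = "reference_locus")
  validate_locus(locus)
}
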