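# Allele construction: edit descriptions, application of a single edit to a
# wild-type background, and assembly of named allele sets with field-style
# labels ("9 bp DEL-B", "1 bp INS-A", "A-T TV-A", ...).

#' Describe a single edit on a wild-type background
#'
#' @param kind One of `"DEL"`, `"INS"`, `"TV"`, `"TS"`. For point edits the
#'   kind is validated against the actual base change (transversion =
#'   purine/pyrimidine swap, transition otherwise).
#' @param position 1-based amplicon coordinate. For `DEL`, the first deleted
#'   base; for `INS`, the base after which the new bases are inserted; for
#'   point edits, the substituted base.
#' @param length Deletion length in bases (`DEL` only).
#' @param bases Inserted bases (`INS`) or the single replacement base
#'   (`TV`/`TS`).
#' @param background `"A"` or `"B"`: which wild-type allele the edit sits on.
#' @param intended `TRUE` for template-specified (homology-directed) edits;
#'   these become `INTENDED_EDIT` alleles, everything else is `INDEL` or
#'   `POINT`.
#' @return An `edit_desc` object.
#' @export
#' @examples
#' edit_desc("DEL", position = 250, length = 9, background = "B")
edit_desc <- function(kind = c("DEL", "INS", "TV", "TS"), position,
                      length = NULL, bases = NULL,
                      background = c("B", "A"), intended = FALSE) {
  kind <- match.arg(kind)
  background <- match.arg(background)
  position <- as.integer(position)
  if (position < 1L) stop("edit position must be positive", call. = FALSE)
  if (kind == "DEL") {
    if (is.null(length) || length < 1L) stop("DEL needs a positive length", call. = FALSE)
    length <- as.integer(length)
    bases <- NULL
  } else if (kind == "INS") {
    if (is.null(bases) || !is_dna(bases) || nchar(bases) < 1L) {
      stop("INS needs inserted bases (A/C/G/T)", call. = FALSE)
    }
    length <- nchar(bases)
  } else {
    if (is.null(bases) || nchar(bases) != 1L || !is_dna(bases)) {
      stop("point edits need a single replacement base", call. = FALSE)
    }
    length <- 1L
  }
  structure(list(kind = kind, position = position, length = length,
                 bases = bases, background = background, intended = intended),
            class = "edit_desc")
}

# Apply one edit to a wild-type background; track reference positions so the
# key window can be read off the edited allele without re-alignment.
# Inserted bases get fractional reference coordinates (pos + 0.5).
apply_edit_chars <- function(locus, edit, background = edit$background) {
  wt <- wt_seq(locus, background)
  n <- nchar(wt)
  chars <- strsplit(wt, "")[[1]]
  refpos <- as.numeric(seq_len(n))
  p <- edit$position
  if (edit$kind == "DEL") {
    if (p + edit$length - 1L > n) {
      stop("deletion extends beyond the amplicon", call. = FALSE)
    }
    keep <- setdiff(seq_len(n), p:(p + edit$length - 1L))
    chars <- chars[keep]; refpos <- refpos[keep]
  } else if (edit$kind == "INS") {
    if (p > n) stop("insertion position beyond the amplicon", call. = FALSE)
    ins <- strsplit(edit$bases, "")[[1]]
    chars <- append(chars, ins, after = p)
    refpos <- append(refpos, rep(p + 0.5, length(ins)), after = p)
  } else {
    if (p > n) stop("substitution position beyond the amplicon", call. = FALSE)
    from <- chars[p]
    if (from == edit$bases) {
      stop("substitution must change the base", call. = FALSE)
    }
    actual <- sub_kind(from, edit$bases)
    if (actual != edit$kind) {
      stop(sprintf("%s->%s is a %s, not a %s", from, edit$bases, actual, edit$kind),
           call. = FALSE)
    }
    chars[p] <- edit$bases
  }
  inwin <- refpos >= locus$key_start & refpos <= locus$key_end
  list(seq = paste(chars, collapse = ""),
       window_seq = paste(chars[inwin], collapse = ""),
       window_start = if (any(inwin)) min(which(inwin)) else NA_integer_)
}

edit_label <- function(locus, edit) {
  bg <- edit$background
  if (edit$kind == "DEL") return(sprintf("%d bp DEL-%s", edit$length, bg))
  if (edit$kind == "INS") return(sprintf("%d bp INS-%s", edit$length, bg))
  from <- substr(wt_seq(locus, bg), edit$position, edit$position)
  sprintf("%s-%s %s-%s", from, edit$bases, edit$kind, bg)
}

new_allele_spec <- function(label, seq, window_seq, window_start,
                            allele_class, background, edit = NULL) {
  structure(list(label = label, seq = seq, window_seq = window_seq,
                 window_start = window_start, allele_class = allele_class,
                 background = background, edit = edit),
            class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(sprintf("<allele_spec> %s [%s/%s] %d bp (window %d bp)\n",
              x$label, x$allele_class, x$background, nchar(x$seq),
              nchar(x$window_seq)))
  invisible(x)
}

#' Build a named allele set from edit descriptions
#'
#' Always returns the two wild-type alleles, plus one allele per edit with
#' labels following the reporting convention (`"9 bp DEL-B"`,
#' `"1 bp INS-A"`, `"A-T TV-A"`, `"A-G TS-A"`). Edits flagged `intended`
#' produce `INTENDED_EDIT` alleles (template-specified edits); other
#' deletions/insertions are `INDEL` and substitutions are `POINT`.
#'
#' @param locus A `reference_locus`.
#' @param edits List of [edit_desc()] objects (possibly empty).
#' @return Named list of `allele_spec` objects (`"WT-A"`, `"WT-B"`, then one
#'   per edit, keyed by label).
#' @export
#' @examples
#' loc <- make_reference_locus(seed = 1)
#' alls <- make_allele_set(loc, list(
#'   edit_desc("DEL", loc$cut_site + 1, length = 9, background = "B")))
#' names(alls)
make_allele_set <- function(locus, edits = list()) {
  validate_locus(locus)
  out <- list(
    "WT-A" = new_allele_spec("WT-A", wt_seq(locus, "A"),
                             wt_seq(locus, "A", window = TRUE),
                             locus$key_start, "WT_A", "A"),
    "WT-B" = new_allele_spec("WT-B", wt_seq(locus, "B"),
                             wt_seq(locus, "B", window = TRUE),
                             locus$key_start, "WT_B", "B"))
  for (edit in edits) {
    stopifnot(inherits(edit, "edit_desc"))
    built <- apply_edit_chars(locus, edit)
    label <- edit_label(locus, edit)
    class <- if (isTRUE(edit$intended)) "INTENDED_EDIT"
             else if (edit$kind %in% c("DEL", "INS")) "INDEL" else "POINT"
    if (label %in% names(out)) {
      stop(sprintf("duplicate allele label '%s'", label), call. = FALSE)
    }
    out[[label]] <- new_allele_spec(label, built$seq, built$window_seq,
                                    built$window_start, class,
                                    edit$background, edit)
  }
  out
}

#' Canonical template (ODN-style) edits for a locus
#'
#' The two homology-template edits the assay is built around, anchored at
#' the locus cut site: a 9 bp deletion that removes the SfoI site (and in
#' the modelled gene creates a premature stop codon), and a 5 bp insertion
#' that creates a new XbaI site at the cut.
#'
#' @param locus A `reference_locus`.
#' @param background Background(s) the templates are instantiated on.
#' @return List with elements `del9` and `ins5` (single background) or
#'   `del9_A`, `ins5_A`, `del9_B`, `ins5_B` when both are requested.
#' @export
odn_template_edits <- function(locus, background = "B") {
  one <- function(bg) list(
    del9 = edit_desc("DEL", position = locus$cut_site + 1L, length = 9,
                     background = bg, intended = TRUE),
    ins5 = edit_desc("INS", position = locus$cut_site, bases = "CTAGA",
                     background = bg, intended = TRUE))
  if (length(background) == 1L) return(one(background))
  out <- list()
  for (bg in background) {
    e <- one(bg)
    out[[paste0("del9_", bg)]] <- e$del9
    out[[paste0("ins5_", bg)]] <- e$ins5
  }
  out
}
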