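# Allele classification against the wild-type backgrounds and edit
# templates, per-embryo profiles with mosaicism calls, and the two
# in-silico diagnostics (restriction digest, degenerate TaqMan-style probe
# match).

#' Built-in diagnostic restriction enzymes
#'
#' XbaI (TCTAGA; gained by the 5 bp insertion template), SfoI (GGCGCC;
#' lost by the 9 bp deletion template) and RsaI (GTAC).
#' @return Data frame `enzyme`, `motif`.
#' @export
restriction_sites <- function() {
  data.frame(enzyme = c("XbaI", "SfoI", "RsaI"),
             motif = c("TCTAGA", "GGCGCC", "GTAC"),
             stringsAsFactors = FALSE)
}

#' In-silico restriction digest
#'
#' Finds all exact motif occurrences on the given strand and reports cut
#' positions and fragment lengths. Cuts are placed at the motif start
#' (fragment presence/absence is the diagnostic signal, not cut chemistry);
#' fragment lengths always partition the sequence length.
#'
#' @param seq DNA string.
#' @param sites Data frame `enzyme`, `motif` (default [restriction_sites()]).
#' @return Named list per enzyme: `positions` (1-based motif starts),
#'   `fragments` (integer lengths summing to `nchar(seq)`).
#' @export
#' @examples
#' digest("AAATCTAGAAAA")$XbaI
digest <- function(seq, sites = restriction_sites()) {
  assert_dna(seq, "seq")
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    starts <- if (n >= nchar(sites$motif[i])) {
      BiocGenerics::start(
        Biostrings::matchPattern(sites$motif[i], Biostrings::DNAString(seq)))
    } else integer(0)
    bounds <- sort(unique(c(0L, starts - 1L, n)))
    out[[sites$enzyme[i]]] <- list(positions = as.integer(starts),
                                   fragments = as.integer(diff(bounds)))
  }
  out
}

#' Degenerate (IUPAC) probe match
#'
#' `TRUE` when the probe, with IUPAC ambiguity codes expanded, matches a
#' substring of the sequence or of its reverse complement with zero
#' mismatches. Models a hydrolysis probe whose binding is abolished by
#' indels or SNPs under its footprint.
#'
#' @param seq Plain A/C/G/T string (may be empty).
#' @param probe IUPAC string (e.g. `"ACYGT"`; Y = C or T).
#' @return Logical.
#' @export
probe_match <- function(seq, probe) {
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(toupper(probe), "")[[1]]
  if (length(chars) == 0L || !all(chars %in% iupac)) {
    stop("probe must be a non-empty IUPAC nucleotide string", call. = FALSE)
  }
  if (nchar(seq) < length(chars)) return(FALSE)
  probe <- paste(chars, collapse = "")
  hit <- function(s) {
    Biostrings::countPattern(probe, Biostrings::DNAString(s),
                             fixed = "subject") > 0
  }
  hit(seq) || hit(revcomp(seq))
}

# Parse a global pairwise alignment (query vs a wild-type window) into
# elementary edit operations. Positions are 1-based window coordinates of
# the reference; insertions anchor after the preceding reference base.
alignment_edits <- function(pattern, subject) {
  pa <- strsplit(pattern, "")[[1]]
  sa <- strsplit(subject, "")[[1]]
  ops <- list()
  i <- 1L; refpos <- 0L
  while (i <= length(pa)) {
    if (sa[i] != "-" && pa[i] == "-") {            # deletion run
      start <- refpos + 1L; del <- character(0)
      while (i <= length(pa) && sa[i] != "-" && pa[i] == "-") {
        refpos <- refpos + 1L; del <- c(del, sa[i]); i <- i + 1L
      }
      ops[[length(ops) + 1L]] <- list(kind = "DEL", position = start,
                                      length = length(del),
                                      bases = paste(del, collapse = ""))
    } else if (sa[i] == "-") {                     # insertion run
      ins <- character(0)
      while (i <= length(pa) && sa[i] == "-") {
        ins <- c(ins, pa[i]); i <- i + 1L
      }
      ops[[length(ops) + 1L]] <- list(kind = "INS", position = refpos,
                                      length = length(ins),
                                      bases = paste(ins, collapse = ""))
    } else {
      refpos <- refpos + 1L
      if (pa[i] != sa[i]) {
        ops[[length(ops) + 1L]] <- list(kind = sub_kind(sa[i], pa[i]),
                                        position = refpos, length = 1L,
                                        bases = paste0(sa[i], ">", pa[i]))
      }
      i <- i + 1L
    }
  }
  if (!length(ops)) {
    return(data.frame(kind = character(0), position = integer(0),
                      length = integer(0), bases = character(0)))
  }
  do.call(rbind, lapply(ops, function(o)
    data.frame(kind = o$kind, position = as.integer(o$position),
               length = as.integer(o$length), bases = o$bases,
               stringsAsFactors = FALSE)))
}

call_label <- function(edits, background) {
  parts <- vapply(seq_len(nrow(edits)), function(i) {
    e <- edits[i, ]
    if (e$kind %in% c("DEL", "INS")) {
      sprintf("%d bp %s", e$length, e$kind)
    } else {
      sprintf("%s-%s %s", substr(e$bases, 1, 1), substr(e$bases, 3, 3), e$kind)
    }
  }, "")
  label <- paste(parts, collapse = ", ")
  if (background %in% c("A", "B")) label <- paste0(label, "-", background)
  label
}

#' Classify one key-window allele sequence
#'
#' Precedence: (1) exact match to an intended-edit template window;
#' (2) exact match to a wild-type window; (3) otherwise global affine-gap
#' alignment to both wild-type backgrounds. The background is read off the
#' surviving polymorphic-site bases when possible, else from the alignment
#' score, else `"ambiguous"` (never silently A or B). Edits are read off
#' the chosen alignment: a single pure indel gives `INDEL`, substitutions
#' only give `POINT` (TV = purine/pyrimidine swap, TS otherwise), anything
#' mixed gives `COMPLEX`.
#'
#' @param seq Gap-free window sequence.
#' @param locus A `reference_locus`.
#' @param templates Named list of `allele_spec` objects; entries with class
#'   `INTENDED_EDIT` are matched exactly before generic calling.
#' @param cfg [align_config()] used for the background alignments.
#' @return An `allele_call`: list `seq`, `allele_class`, `background`,
#'   `label`, `edits` (data frame, 1-based amplicon positions),
#'   `template_plus_sub` (template label when the call is a template indel
#'   plus extra substitutions, else `NA`).
#' @export
classify_allele <- function(seq, locus, templates = list(),
                            cfg = align_config()) {
  if (!nzchar(seq)) stop("cannot classify an empty sequence", call. = FALSE)
  assert_dna(seq, "window sequence")
  tmpl <- Filter(function(t) t$allele_class == "INTENDED_EDIT", templates)
  for (t in tmpl) {
    if (seq == t$window_seq) {
      edits <- data.frame(kind = t$edit$kind, position = t$edit$position,
                          length = t$edit$length,
                          bases = t$edit$bases %||% NA_character_,
                          stringsAsFactors = FALSE)
      return(structure(list(seq = seq, allele_class = "INTENDED_EDIT",
                            background = t$background, label = t$label,
                            edits = edits, template_plus_sub = NA_character_),
                       class = "allele_call"))
    }
  }
  wt_a <- wt_seq(locus, "A", window = TRUE)
  wt_b <- wt_seq(locus, "B", window = TRUE)
  if (seq == wt_b) {
    return(structure(list(seq = seq, allele_class = "WT_B", background = "B",
                          label = "WT-B", edits = alignment_edits(seq, seq),
                          template_plus_sub = NA_character_),
                     class = "allele_call"))
  }
  if (seq == wt_a) {
    return(structure(list(seq = seq, allele_class = "WT_A", background = "A",
                          label = "WT-A", edits = alignment_edits(seq, seq),
                          template_plus_sub = NA_character_),
                     class = "allele_call"))
  }

  sm <- substitution_matrix(cfg)
  aln_to <- function(wt) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(seq),
                                  Biostrings::DNAString(wt), type = "global",
                                  substitutionMatrix = sm,
                                  gapOpening = cfg$gap_open,
                                  gapExtension = cfg$gap_extend)
  }
  aln_a <- aln_to(wt_a); aln_b <- aln_to(wt_b)
  s_a <- Biostrings::score(aln_a); s_b <- Biostrings::score(aln_b)

  # surviving polymorphic-site bases decide the background when readable
  poly_win <- locus$poly_sites$pos - locus$key_start + 1L
  surviving_base <- function(aln) {
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    pos <- cumsum(sa != "-")
    vapply(poly_win, function(p) {
      col <- which(pos == p & sa != "-")[1]
      if (is.na(col) || pa[col] == "-") NA_character_ else pa[col]
    }, "")
  }
  background <- "ambiguous"
  if (length(poly_win)) {
    bases <- surviving_base(aln_b)
    seen <- !is.na(bases)
    if (any(seen)) {
      if (all(bases[seen] == locus$poly_sites$base_a[seen])) background <- "A"
      else if (all(bases[seen] == locus$poly_sites$base_b[seen])) background <- "B"
    }
  }
  if (background == "ambiguous" && s_a != s_b) {
    background <- if (s_a > s_b) "A" else "B"
  }
  aln <- switch(background, A = aln_a, B = aln_b, aln_b)
  edits <- alignment_edits(as.character(Biostrings::alignedPattern(aln)),
                           as.character(Biostrings::alignedSubject(aln)))
  edits$position <- edits$position + locus$key_start - 1L

  n_indel <- sum(edits$kind %in% c("DEL", "INS"))
  n_sub <- sum(edits$kind %in% c("TV", "TS"))
  allele_class <- if (n_indel == 1L && n_sub == 0L) "INDEL"
                  else if (n_indel == 0L && n_sub >= 1L) "POINT"
                  else "COMPLEX"

  # template indel plus extra substitutions (e.g. "T-A TV, 9 bp DEL-B")
  template_plus_sub <- NA_character_
  if (n_indel == 1L && n_sub >= 1L) {
    ind <- edits[edits$kind %in% c("DEL", "INS"), ]
    for (t in tmpl) {
      if (t$edit$kind == ind$kind[1] && t$edit$length == ind$length[1] &&
          abs(t$edit$position - ind$position[1]) <= 2L &&
          t$background == background) {
        template_plus_sub <- t$label
        break
      }
    }
  }

  structure(list(seq = seq, allele_class = allele_class,
                 background = background,
                 label = call_label(edits, background), edits = edits,
                 template_plus_sub = template_plus_sub),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("<allele_call> %s [%s, background %s]\n", x$label,
              x$allele_class, x$background))
  invisible(x)
}

#' Classify every enumerated allele of an embryo
#'
#' @param counts Data frame from [enumerate_alleles()].
#' @param locus A `reference_locus`.
#' @param templates Template allele set (see [classify_allele()]).
#' @param cfg [align_config()].
#' @return List of `allele_call` objects, one per row of `counts`.
#' @export
classify_alleles <- function(counts, locus, templates = list(),
                             cfg = align_config()) {
  lapply(counts$seq, classify_allele, locus = locus, templates = templates,
         cfg = cfg)
}

#' Build a per-embryo profile with a mosaicism call
#'
#' Aggregates enumerated-allele fractions by class. The embryo is called
#' `NON_MOSAIC_BIALLELIC` when the intended-edit percentage exceeds
#' `biallelic_threshold` (default 96%), `UNEDITED` when all edited classes
#' together stay below 1%, and `MOSAIC_EDITED` otherwise.
#'
#' @param counts Data frame from [enumerate_alleles()].
#' @param calls Matching list from [classify_alleles()].
#' @param embryo_id Identifier carried into the profile.
#' @param biallelic_threshold Percent threshold for the biallelic call.
#' @param include_template_plus_sub Count alleles that carry a template
#'   indel plus extra substitutions toward the intended percentage
#'   (default `FALSE`: exact template matches only).
#' @return An `embryo_profile`: per-allele table plus `pct_intended`,
#'   `pct_wt`, `pct_other` and `mosaicism_call`.
#' @export
build_profile <- function(counts, calls, embryo_id = "embryo",
                          biallelic_threshold = 96,
                          include_template_plus_sub = FALSE) {
  if (nrow(counts) == 0L) stop("counts must be non-empty", call. = FALSE)
  stopifnot(length(calls) == nrow(counts))
  cls <- vapply(calls, `[[`, "", "allele_class")
  tps <- vapply(calls, `[[`, "", "template_plus_sub")
  pct <- 100 * counts$fraction
  intended <- cls == "INTENDED_EDIT"
  if (include_template_plus_sub) intended <- intended | !is.na(tps)
  wt <- cls %in% c("WT_A", "WT_B")
  edited <- !wt
  pct_intended <- sum(pct[intended])
  pct_wt <- sum(pct[wt])
  pct_other <- sum(pct[!intended & !wt])
  mosaicism_call <- if (pct_intended > biallelic_threshold) {
    "NON_MOSAIC_BIALLELIC"
  } else if (sum(pct[edited]) < 1) {
    "UNEDITED"
  } else {
    "MOSAIC_EDITED"
  }
  tab <- data.frame(label = vapply(calls, `[[`, "", "label"),
                    allele_class = cls,
                    background = vapply(calls, `[[`, "", "background"),
                    count = counts$count, fraction = counts$fraction,
                    pct = pct, stringsAsFactors = FALSE)
  structure(list(embryo_id = embryo_id, calls = tab,
                 pct_intended = pct_intended, pct_wt = pct_wt,
                 pct_other = pct_other, mosaicism_call = mosaicism_call,
                 biallelic_threshold = biallelic_threshold),
            class = "embryo_profile")
}

#' @export
print.embryo_profile <- function(x, ...) {
  cat(sprintf("<embryo_profile> %s: %s\n", x$embryo_id, x$mosaicism_call))
  cat(sprintf("  intended %.1f%% | wild type %.1f%% | other %.1f%%\n",
              x$pct_intended, x$pct_wt, x$pct_other))
  top <- utils::head(x$calls[order(-x$calls$pct), ], 6L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-24s %8d reads  %5.1f%%\n", top$label[i], top$count[i],
                top$pct[i]))
  }
  invisible(x)
}
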