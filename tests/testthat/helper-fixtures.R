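# Shared fixtures: a small locus (shorter flanks, same key-window
# geometry) keeps alignment-heavy tests fast; the full-size locus is used
# where read lengths matter.

small_locus <- function(seed = 11) {
  make_reference_locus(length = 200, key_region_length = 71,
                       n_poly_sites = 3, seed = seed)
}

full_locus <- function(seed = 1) {
  make_reference_locus(seed = seed)
}

# allele set with the canonical templates plus assorted random-repair edits
demo_allele_set <- function(locus) {
  tmpl <- odn_template_edits(locus, "B")
  wt_a <- wt_seq(locus, "A")
  pick_sub <- function(offset, kind) {
    pos <- locus$cut_site + offset
    from <- substr(wt_a, pos, pos)
    to <- if (kind == "TS") c(A = "G", G = "A", C = "T", T = "C")[[from]]
          else c(A = "T", T = "A", C = "G", G = "C")[[from]]
    edit_desc(kind, position = pos, bases = to, background = "A")
  }
  make_allele_set(locus, list(
    tmpl$del9, tmpl$ins5,
    edit_desc("DEL", locus$cut_site - 5L, length = 24, background = "A"),
    edit_desc("INS", locus$cut_site, bases = "G", background = "A"),
    pick_sub(-12L, "TS"),
    pick_sub(13L, "TV")))
}
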