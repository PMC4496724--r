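# allele classification, profiles/mosaicism, in-silico diagnostics

test_that("exact wild-type and template matches short-circuit", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  tmpl <- alls
  wt_call <- classify_allele(wt_seq(loc, "A", window = TRUE), loc, tmpl)
  expect_equal(wt_call$allele_class, "WT_A")
  expect_equal(nrow(wt_call$edits), 0)
  del_call <- classify_allele(alls[["9 bp DEL-B"]]$window_seq, loc, tmpl)
  expect_equal(del_call$allele_class, "INTENDED_EDIT")
  expect_equal(del_call$label, "9 bp DEL-B")
  expect_error(classify_allele("", loc), "empty")
})

test_that("generic indels and point mutations get field-style labels", {
  loc <- small_locus()
  alls <- demo_allele_set(loc)
  # without templates the 9 bp deletion is a plain indel with the same label
  call <- classify_allele(alls[["9 bp DEL-B"]]$window_seq, loc)
  expect_equal(call$allele_class, "INDEL")
  expect_equal(call$label, "9 bp DEL-B")
  call24 <- classify_allele(alls[["24 bp DEL-A"]]$window_seq, loc)
  expect_equal(call24$allele_class, "INDEL")
  expect_equal(call24$label, "24 bp DEL-A")
  ins <- classify_allele(alls[["1 bp INS-A"]]$window_seq, loc)
  expect_equal(ins$label, "1 bp INS-A")
  point_labels <- names(alls)[grepl("T[VS]-A$", names(alls))]
  for (lab in point_labels) {
    call <- classify_allele(alls[[lab]]$window_seq, loc)
    expect_equal(call$allele_class, "POINT")
    expect_equal(call$label, lab)
  }
})

test_that("every generated allele classifies back to its own label", {
  loc <- small_locus()
  alls <- demo_allele_set(loc)
  tmpl <- alls
  for (spec in alls) {
    call <- classify_allele(spec$window_seq, loc, tmpl)
    expect_equal(call$allele_class, spec$allele_class, info = spec$label)
    expect_equal(call$label, spec$label, info = spec$label)
    expect_equal(call$background, spec$background, info = spec$label)
  }
})

test_that("classification is idempotent and deterministic", {
  loc <- small_locus()
  alls <- demo_allele_set(loc)
  seq <- alls[["24 bp DEL-A"]]$window_seq
  expect_identical(classify_allele(seq, loc), classify_allele(seq, loc))
})

test_that("template indel plus substitution is COMPLEX and flagged", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  del_win <- alls[["9 bp DEL-B"]]$window_seq
  # plant a T-A transversion a few bases left of the cut site
  rel <- loc$cut_site - loc$key_start + 1L - 4L
  ch <- strsplit(del_win, "")[[1]]
  ch[rel] <- c(A = "T", T = "A", C = "G", G = "C")[[ch[rel]]]
  variant <- paste(ch, collapse = "")
  call <- classify_allele(variant, loc, alls)
  expect_equal(call$allele_class, "COMPLEX")
  expect_equal(call$template_plus_sub, "9 bp DEL-B")
  expect_match(call$label, "T[VS], 9 bp DEL-B$")
})

test_that("background falls to 'ambiguous' when sites are gone and scores tie", {
  # pick a locus whose polymorphic sites all sit away from the window edges,
  # so removing the window interior removes every background-diagnostic base
  loc <- NULL
  for (seed in 1:50) {
    cand <- small_locus(seed)
    if (all(cand$poly_sites$pos > cand$key_start + 5 &
              cand$poly_sites$pos < cand$key_end - 5)) {
      loc <- cand; break
    }
  }
  # delete the entire key window except short flanks: all poly sites gone
  win <- wt_seq(loc, "B", window = TRUE)
  chopped <- paste0(substr(win, 1, 5),
                    substr(win, nchar(win) - 4, nchar(win)))
  call <- classify_allele(chopped, loc)
  expect_equal(call$background, "ambiguous")
  expect_false(grepl("-(A|B)$", call$label))
})

test_that("digest partitions the sequence and finds planted motifs", {
  set.seed(9)
  flank <- gsub("TCTAGA|GGCGCC|GTAC", "AAAAAA", random_seq(444))
  seq <- paste0(substr(flank, 1, 100), "TCTAGA",
                substr(flank, 101, nchar(flank)))
  d <- digest(seq)
  expect_equal(d$XbaI$positions, 101)
  expect_equal(d$XbaI$fragments, c(100, nchar(seq) - 100))
  expect_equal(sum(d$XbaI$fragments), nchar(seq))
  # zero motifs -> a single whole-sequence fragment
  expect_equal(d$SfoI$fragments, nchar(seq))
  expect_equal(length(d$SfoI$positions), 0)
})

test_that("fragment lengths always sum to sequence length", {
  set.seed(10)
  for (i in 1:50) {
    seq <- random_seq(sample(20:300, 1))
    d <- digest(seq)
    for (enz in names(d)) expect_equal(sum(d[[enz]]$fragments), nchar(seq))
  }
})

test_that("templates recapitulate the diagnostic digest changes", {
  loc <- small_locus()
  for (bg in c("A", "B")) {
    alls <- make_allele_set(loc, odn_template_edits(loc, bg))
    wt <- alls[[paste0("WT-", bg)]]$seq
    del <- alls[[paste0("9 bp DEL-", bg)]]$seq
    ins <- alls[[paste0("5 bp INS-", bg)]]$seq
    # 9 bp deletion: exactly one SfoI site lost, XbaI unchanged
    expect_equal(length(digest(wt)$SfoI$positions) -
                   length(digest(del)$SfoI$positions), 1)
    expect_equal(length(digest(del)$XbaI$positions),
                 length(digest(wt)$XbaI$positions))
    # 5 bp insertion: exactly one XbaI site gained, SfoI unchanged
    expect_equal(length(digest(ins)$XbaI$positions) -
                   length(digest(wt)$XbaI$positions), 1)
    expect_equal(length(digest(ins)$SfoI$positions),
                 length(digest(wt)$SfoI$positions))
  }
})

test_that("degenerate probe matching honours IUPAC codes and strands", {
  expect_true(probe_match("AAACCGTAAA", "ACYGT"))
  expect_true(probe_match("AAACTGTAAA", "ACYGT"))
  expect_false(probe_match("AAAGGGGAAA", "ACYGT"))
  # reverse-complement strand
  expect_true(probe_match(revcomp("AAACCGTAAA"), "ACYGT"))
  expect_false(probe_match("", "ACYGT"))
  expect_error(probe_match("ACGT", "ACZGT"), "IUPAC")
})

test_that("an insertion under the probe footprint abolishes binding", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  # a 20-base probe spanning the cut site
  probe <- substr(wt_seq(loc, "B"), loc$cut_site - 7, loc$cut_site + 12)
  expect_true(probe_match(alls[["WT-B"]]$seq, probe))
  expect_false(probe_match(alls[["5 bp INS-B"]]$seq, probe))
  expect_false(probe_match(alls[["9 bp DEL-B"]]$seq, probe))
})

test_that("profiles aggregate percentages and call mosaicism", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  del <- alls[["9 bp DEL-B"]]$window_seq
  wt <- alls[["WT-B"]]$window_seq
  mk <- function(seqs) {
    tab <- enumerate_alleles(seqs, locus = loc)
    build_profile(tab, classify_alleles(tab, loc, alls), "e")
  }
  p100 <- mk(rep(del, 500))
  expect_equal(p100$pct_intended, 100)
  expect_equal(p100$mosaicism_call, "NON_MOSAIC_BIALLELIC")
  p63 <- mk(c(rep(del, 630), rep(wt, 370)))
  expect_equal(p63$pct_intended, 63)
  expect_equal(p63$pct_wt, 37)
  expect_equal(p63$mosaicism_call, "MOSAIC_EDITED")
  pwt <- mk(rep(wt, 200))
  expect_equal(pwt$pct_wt, 100)
  expect_equal(pwt$mosaicism_call, "UNEDITED")
  # threshold boundary: 96% exactly is still mosaic, above 96% is biallelic
  p96 <- mk(c(rep(del, 960), rep(wt, 40)))
  expect_equal(p96$mosaicism_call, "MOSAIC_EDITED")
  p97 <- mk(c(rep(del, 970), rep(wt, 30)))
  expect_equal(p97$mosaicism_call, "NON_MOSAIC_BIALLELIC")
})

test_that("template-plus-substitution alleles are countable as intended", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  del <- alls[["9 bp DEL-B"]]$window_seq
  rel <- loc$cut_site - loc$key_start + 1L - 4L
  ch <- strsplit(del, "")[[1]]
  ch[rel] <- c(A = "T", T = "A", C = "G", G = "C")[[ch[rel]]]
  variant <- paste(ch, collapse = "")
  tab <- enumerate_alleles(c(rep(del, 930), rep(variant, 70)), locus = loc)
  calls <- classify_alleles(tab, loc, alls)
  strict <- build_profile(tab, calls, "z")
  expect_equal(strict$pct_intended, 93)
  loose <- build_profile(tab, calls, "z", include_template_plus_sub = TRUE)
  expect_equal(loose$pct_intended, 100)
})
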