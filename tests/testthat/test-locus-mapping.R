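# semi-global alignment, key-window extraction, allele enumeration

test_that("an exact reference read aligns with no gaps or mismatches", {
  loc <- small_locus()
  read <- substr(loc$amplicon_seq, loc$key_start - 20, loc$key_end + 20)
  aln <- align_read(read, loc)
  expect_false(is_rejection(aln))
  expect_equal(aln$identity, 1)
  expect_false(grepl("-", aln$pattern))
  expect_false(grepl("-", aln$subject))
  expect_equal(aln$ref_start, loc$key_start - 20)
  expect_equal(aln$ref_end, loc$key_end + 20)
  expect_equal(aln$orientation, "+")
})

test_that("a 9-base deletion aligns as a single contiguous gap run", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  read <- alls[["9 bp DEL-B"]]$seq
  aln <- align_read(read, loc)
  gaps <- regmatches(aln$pattern, gregexpr("-+", aln$pattern))[[1]]
  expect_identical(gaps, "---------")
  expect_false(grepl("-", aln$subject))
})

test_that("a 5-base insertion aligns as a single subject gap run", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  aln <- align_read(alls[["5 bp INS-B"]]$seq, loc)
  expect_identical(regmatches(aln$subject, gregexpr("-+", aln$subject))[[1]],
                   "-----")
})

test_that("unrelated sequence is rejected as UNMAPPED", {
  loc <- small_locus()
  set.seed(5)
  out <- align_read(random_seq(100), loc)
  expect_true(is_rejection(out))
  expect_identical(out$reason, "UNMAPPED")
  expect_error(align_read("", loc), "empty")
})

test_that("reverse-orientation reads map with orientation '-'", {
  loc <- small_locus()
  read <- revcomp(substr(loc$amplicon_seq, loc$key_start - 10, loc$key_end + 10))
  aln <- align_read(read, loc)
  expect_equal(aln$orientation, "-")
  expect_identical(extract_window(aln, loc), wt_seq(loc, "B", window = TRUE))
})

test_that("alignment scores match the plain-R Gotoh oracle", {
  set.seed(31)
  cfg <- align_config(min_identity_to_map = 0)
  for (i in 1:200) {
    subject_len <- sample(8:20, 1)
    subject <- random_seq(subject_len)
    # mix related reads (mutated substrings) and unrelated ones
    read <- if (runif(1) < 0.6) {
      s <- sample(1:max(1, subject_len - 6), 1)
      sub <- substr(subject, s, min(subject_len, s + sample(4:12, 1)))
      ch <- strsplit(sub, "")[[1]]
      if (length(ch) > 3 && runif(1) < 0.5) {
        j <- sample(length(ch), 1)
        ch[j] <- sample(c("A", "C", "G", "T"), 1)
      }
      if (length(ch) > 5 && runif(1) < 0.3) ch <- ch[-sample(length(ch), 2)]
      paste(ch, collapse = "")
    } else {
      random_seq(sample(4:15, 1))
    }
    if (!nzchar(read)) next
    loc <- structure(list(name = "t", amplicon_seq = subject, key_start = 1L,
                          key_end = nchar(subject), cut_site = 1L,
                          poly_sites = data.frame(pos = integer(0),
                                                  base_a = character(0),
                                                  base_b = character(0))),
                     class = "reference_locus")
    aln <- align_read(read, loc, cfg)
    # align_read picks the better orientation, so the oracle must too
    want <- max(oracle_semiglobal_score(read, subject),
                oracle_semiglobal_score(revcomp(read), subject))
    expect_equal(aln$score, want,
                 info = sprintf("read=%s subject=%s", read, subject))
  }
})

test_that("window extraction recovers wild type and indel windows", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  wt_read <- alls[["WT-B"]]$seq
  expect_identical(extract_window(align_read(wt_read, loc), loc),
                   wt_seq(loc, "B", window = TRUE))
  del_win <- extract_window(align_read(alls[["9 bp DEL-B"]]$seq, loc), loc)
  expect_equal(nchar(del_win), 71 - 9)
  expect_identical(del_win, alls[["9 bp DEL-B"]]$window_seq)
  ins_win <- extract_window(align_read(alls[["5 bp INS-B"]]$seq, loc), loc)
  expect_identical(ins_win, alls[["5 bp INS-B"]]$window_seq)
})

test_that("reads not spanning the window are rejected as PARTIAL_SPAN", {
  loc <- small_locus()
  mid <- (loc$key_start + loc$key_end) %/% 2
  read <- substr(loc$amplicon_seq, mid, nchar(loc$amplicon_seq))
  out <- extract_window(align_read(read, loc), loc)
  expect_true(is_rejection(out))
  expect_identical(out$reason, "PARTIAL_SPAN")
})

test_that("enumeration counts, thresholds and ordering behave", {
  loc <- small_locus()
  wt_b <- wt_seq(loc, "B", window = TRUE)
  wt_a <- wt_seq(loc, "A", window = TRUE)
  # all wild-type B
  tab <- enumerate_alleles(rep(wt_b, 100), locus = loc)
  expect_equal(tab$fraction[tab$wt == "B"], 1)
  expect_equal(tab$fraction[tab$wt == "A"], 0)
  # 930/70 mixture mirrors a 93/7 profile
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  del <- alls[["9 bp DEL-B"]]$window_seq
  var2 <- paste0("T", substr(del, 2, nchar(del)))
  seqs <- c(rep(del, 930), rep(var2, 70))
  tab <- enumerate_alleles(seqs, locus = loc)
  expect_equal(tab$count[tab$seq == del], 930)
  expect_equal(tab$fraction[tab$seq == del], 0.93)
  expect_equal(tab$fraction[tab$seq == var2], 0.07)
  expect_equal(sum(tab$count) + attr(tab, "n_unreported"), length(seqs))
  # counts sorted descending
  expect_false(is.unsorted(rev(tab$count)))
})

test_that("the reporting threshold is strictly 'over 1%'", {
  loc <- small_locus()
  wt_b <- wt_seq(loc, "B", window = TRUE)
  rare <- paste0("A", substr(wt_b, 2, nchar(wt_b)))
  rare <- if (rare == wt_b) paste0("C", substr(wt_b, 2, nchar(wt_b))) else rare
  seqs <- c(rep(wt_b, 990), rep(rare, 10))       # exactly 1.0%
  tab <- enumerate_alleles(seqs, locus = loc)
  expect_false(rare %in% tab$seq)
  seqs <- c(rep(wt_b, 989), rep(rare, 11))       # 1.1%
  tab <- enumerate_alleles(seqs, locus = loc)
  expect_true(rare %in% tab$seq)
})

test_that("noiseless enumeration reproduces ground truth exactly", {
  loc <- small_locus()
  alls <- make_allele_set(loc, odn_template_edits(loc, "B"))
  truth <- c("9 bp DEL-B" = 60, "WT-B" = 30, "WT-A" = 10)
  seqs <- unlist(mapply(function(lab, k) rep(alls[[lab]]$window_seq, k),
                        names(truth), truth))
  tab <- enumerate_alleles(seqs, locus = loc)
  for (lab in names(truth)) {
    expect_equal(tab$count[tab$seq == alls[[lab]]$window_seq],
                 unname(truth[lab]))
  }
})
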