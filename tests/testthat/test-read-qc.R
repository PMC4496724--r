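# quality trimming, exact-overlap joining, length filtering

test_that("trimming keeps everything at high quality, nothing at low", {
  seq <- random_seq(40)
  t_hi <- trim_longest_segment(seq, rep(40L, 40))
  expect_identical(t_hi$seq, seq)
  t_lo <- trim_longest_segment(seq, rep(10L, 40))
  expect_identical(t_lo$seq, "")
  expect_length(t_lo$quals, 0)
})

test_that("threshold is strict: Q20 fails, Q21 passes at 0.01", {
  seq <- "ACGT"
  expect_identical(trim_longest_segment(seq, rep(20L, 4))$seq, "")
  expect_identical(trim_longest_segment(seq, rep(21L, 4))$seq, seq)
})

test_that("constructed 5/12/7 quality runs give the 12-base segment", {
  set.seed(1)
  seq <- random_seq(30)
  quals <- c(rep(30L, 5), rep(10L, 2), rep(35L, 12), rep(12L, 4), rep(31L, 7))
  out <- trim_longest_segment(seq, quals)
  expect_identical(out$seq, substr(seq, 8, 19))
  expect_identical(out$seq, oracle_trim(seq, quals))
})

test_that("trimmer matches the all-substrings oracle on random reads", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    seq <- random_seq(n)
    quals <- random_phred(n)
    got <- trim_longest_segment(seq, quals)
    expect_identical(got$seq, oracle_trim(seq, quals))
    # output is a contiguous substring of the input, never longer
    if (nzchar(got$seq)) {
      expect_identical(got$seq, substr(seq, got$start, got$end))
    }
  }
})

test_that("mismatched lengths are rejected", {
  expect_error(trim_longest_segment("ACGT", c(30L, 30L)), "differ")
})

test_that("joining basic geometries", {
  set.seed(2)
  core <- random_seq(400)
  r1 <- substr(core, 1, 250)
  r2 <- revcomp(substr(core, 151, 400))          # exact 100-base overlap
  j <- join_pair(r1, rep(30L, 250), r2, rep(30L, 250))
  expect_equal(j$overlap_len, 100)
  expect_equal(nchar(j$seq), 400)
  expect_identical(j$seq, core)
  # identical reads: degenerate full overlap
  r <- random_seq(250)
  j2 <- join_pair(r, rep(30L, 250), revcomp(r), rep(30L, 250))
  expect_equal(j2$overlap_len, 250)
  expect_identical(j2$seq, r)
})

test_that("a best overlap of 13 bases is rejected as NO_OVERLAP", {
  set.seed(3)
  repeat {
    r1 <- random_seq(60)
    tail13 <- substr(r1, 48, 60)
    r2rc <- paste0(tail13, random_seq(47))
    r2 <- revcomp(r2rc)
    if (identical(oracle_join(r1, r2, 14), NA) &&
        !identical(oracle_join(r1, r2, 13), NA)) break
  }
  out <- join_pair(r1, rep(30L, 60), r2, rep(30L, 60))
  expect_true(is_rejection(out))
  expect_identical(out$reason, "NO_OVERLAP")
  expect_equal(join_pair(r1, rep(30L, 60), r2, rep(30L, 60),
                         join_config(min_overlap = 13))$overlap_len, 13)
})

test_that("overlap qualities take the per-base maximum", {
  core <- "ACGTACGTACGTACGTACGT"
  r1 <- substr(core, 1, 16)
  r2 <- revcomp(substr(core, 3, 20))             # overlap 14
  q1 <- c(rep(30L, 2), rep(10L, 14))
  q2 <- rep(25L, 18)
  j <- join_pair(r1, q1, r2, q2)
  expect_equal(j$overlap_len, 14)
  expect_equal(j$quals, c(30L, 30L, rep(25L, 14), rep(25L, 4)))
})

test_that("join matches the all-offsets oracle on random pairs", {
  set.seed(7)
  for (i in 1:300) {
    n1 <- sample(14:60, 1); n2 <- sample(14:60, 1)
    if (runif(1) < 0.6) {                        # planted overlap
      core <- random_seq(n1 + n2 - sample(14:min(n1, n2), 1))
      r1 <- substr(core, 1, n1)
      r2 <- revcomp(substr(core, nchar(core) - n2 + 1, nchar(core)))
    } else {                                     # unrelated reads
      r1 <- random_seq(n1); r2 <- random_seq(n2)
    }
    got <- join_pair(r1, rep(30L, n1), r2, rep(30L, n2))
    want <- oracle_join(r1, r2, 14)
    if (identical(want, NA)) {
      expect_true(is_rejection(got))
    } else {
      expect_identical(got$seq, want$seq)
      expect_equal(got$overlap_len, want$overlap)
      expect_equal(nchar(got$seq), n1 + n2 - got$overlap_len)
    }
  }
})

test_that("vectorised joiner agrees with the scalar joiner", {
  set.seed(12)
  n <- 60
  r1 <- data.frame(id = paste0("p", 1:n), seq = character(n),
                   qual = character(n), stringsAsFactors = FALSE)
  r2 <- r1
  for (i in 1:n) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    if (runif(1) < 0.5) {
      core <- random_seq(max(n1, n2) + 10)
      r1$seq[i] <- substr(core, 1, n1)
      r2$seq[i] <- revcomp(substr(core, nchar(core) - n2 + 1, nchar(core)))
    } else {
      r1$seq[i] <- random_seq(n1); r2$seq[i] <- random_seq(n2)
    }
    r1$qual[i] <- intToUtf8(random_phred(n1) + 33)
    r2$qual[i] <- intToUtf8(random_phred(n2) + 33)
  }
  batch <- join_pairs(r1, r2)
  scalar <- lapply(1:n, function(i)
    join_pair(r1$seq[i], r1$qual[i], r2$seq[i], r2$qual[i]))
  ok <- !vapply(scalar, is_rejection, TRUE)
  expect_equal(nrow(batch$joined), sum(ok))
  expect_equal(batch$n_rejected, sum(!ok))
  expect_identical(batch$joined$seq, vapply(scalar[ok], `[[`, "", "seq"))
  expect_identical(batch$joined$qual,
                   vapply(scalar[ok], function(x) ampledit:::phred_encode(x$quals), ""))
  # conservation: pairs in = joined + rejected
  expect_equal(nrow(batch$joined) + batch$n_rejected, n)
})

test_that("length filter keeps the 250 boundary and counts removals", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = vapply(c(249, 250, 251), random_seq, ""),
                      qual = "", stringsAsFactors = FALSE)
  out <- length_filter(reads)
  expect_equal(nrow(out$kept), 2)
  expect_equal(out$n_removed, 1)
  expect_identical(out$kept$id, c("b", "c"))
  empty <- length_filter(reads[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(empty$n_removed, 0)
})

test_that("constructed short joints are filtered at the expected rate", {
  set.seed(21)
  seqs <- c(vapply(rep(300, 70), random_seq, ""),
            vapply(rep(180, 30), random_seq, ""))
  reads <- data.frame(id = paste0("r", 1:100), seq = seqs, qual = "",
                      stringsAsFactors = FALSE)
  out <- length_filter(reads)
  expect_equal(nrow(out$kept), 70)
  expect_equal(out$n_removed, 30)
})
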