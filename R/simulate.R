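# Synthetic paired-end read generator. Emulates the assay geometry:
# a sequencing fragment centred on the key window of each allele, 2 x 250 bp
# reads from either fragment end, Sanger/Phred+33 qualities, and per-base
# substitution errors whose probability is derived from the emitted quality
# (p = 10^(-Q/10)). Sequencing indel errors are off by default so ground
# truth stays unambiguous; an explicit rate can switch them on.

#' Read-simulation configuration
#'
#' @param read_length Read length in bases (default 250, MiSeq 2x250).
#' @param mean_quality Mean per-base Phred quality (default 30, i.e. 0.1%
#'   substitution error per base).
#' @param quality_sd Per-base quality jitter (SD in Phred units; default 2).
#' @param min_overlap_generated Minimum overlap the two reads of a pair are
#'   generated with; the fragment length is
#'   `2 * read_length - min_overlap_generated` (default 100, giving the
#'   ~400 bp fragments the assay sequences).
#' @param tail_degradation Optional list `list(tail_length=, drop=)`:
#'   qualities decline linearly by `drop` Phred units over the last
#'   `tail_length` bases of each read (3' quality decay).
#' @param indel_error_rate Per-base sequencing indel rate (default 0;
#'   substitution-only errors keep ground truth exact).
#' @param error_free When `TRUE`, no errors are injected at all (qualities
#'   are still emitted); used for noiseless identity checks.
#' @return A `read_sim_config` object.
#' @export
read_sim_config <- function(read_length = 250, mean_quality = 30,
                            quality_sd = 2, min_overlap_generated = 100,
                            tail_degradation = NULL, indel_error_rate = 0,
                            error_free = FALSE) {
  if (read_length < 1) stop("read_length must be >= 1", call. = FALSE)
  if (mean_quality < 2 || mean_quality > 41) {
    stop("mean_quality must be within the Phred+33 range [2, 41]", call. = FALSE)
  }
  if (min_overlap_generated < 1 || min_overlap_generated > read_length) {
    stop("min_overlap_generated must be in [1, read_length]", call. = FALSE)
  }
  if (indel_error_rate < 0 || indel_error_rate > 1) {
    stop("indel_error_rate must be a probability", call. = FALSE)
  }
  structure(list(read_length = as.integer(read_length),
                 mean_quality = mean_quality, quality_sd = quality_sd,
                 min_overlap_generated = as.integer(min_overlap_generated),
                 tail_degradation = tail_degradation,
                 indel_error_rate = indel_error_rate,
                 error_free = isTRUE(error_free)),
            class = "read_sim_config")
}

#' Specify an embryo as a mixture of alleles
#'
#' @param embryo_id Identifier used in read names and reports.
#' @param alleles Named list of `allele_spec` objects ([make_allele_set()]).
#' @param freqs Numeric vector of allele frequencies, same length/order as
#'   `alleles`; must sum to 1 within 1e-9.
#' @param n_read_pairs Number of read pairs to simulate (default 20000,
#'   within the assay's 11,000-405,000 per-sample range).
#' @param seed Integer seed for this embryo's draws.
#' @return An `embryo_mix` object.
#' @export
embryo_mix <- function(embryo_id, alleles, freqs, n_read_pairs = 20000,
                       seed = 1) {
  stopifnot(length(alleles) == length(freqs), length(alleles) >= 1)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(freqs < 0)) stop("allele frequencies must be non-negative", call. = FALSE)
  if (n_read_pairs < 1) stop("n_read_pairs must be >= 1", call. = FALSE)
  structure(list(embryo_id = embryo_id, alleles = alleles,
                 freqs = as.numeric(freqs),
                 n_read_pairs = as.integer(n_read_pairs),
                 seed = as.integer(seed)),
            class = "embryo_mix")
}

# Fragment of an allele centred on its key window.
allele_fragment <- function(spec, frag_len) {
  n <- nchar(spec$seq)
  wlen <- nchar(spec$window_seq)
  centre <- (spec$window_start %||% 1L) + wlen %/% 2L
  fstart <- max(1L, centre - frag_len %/% 2L)
  fend <- min(n, fstart + frag_len - 1L)
  fstart <- max(1L, fend - frag_len + 1L)
  substr(spec$seq, fstart, fend)
}

# Vectorised batch of reads: one sequence per template string, qualities
# drawn around the mean (with optional 3' tail decline) and substitution
# errors at 10^(-Q/10) per base. Operates on all reads of a file at once.
sim_read_batch <- function(templates, cfg) {
  rl <- nchar(templates)
  n_bases <- sum(rl)
  pos <- sequence(rl)                    # position within each read
  read_len <- rep(rl, rl)
  q <- round(stats::rnorm(n_bases, cfg$mean_quality, cfg$quality_sd))
  td <- cfg$tail_degradation
  if (!is.null(td)) {
    k <- max(2L, as.integer(td$tail_length))
    rel <- pos - (read_len - k)          # 1..k inside the degraded tail
    intail <- rel >= 1L
    q[intail] <- q[intail] - round(td$drop * (rel[intail] - 1) / (k - 1))
  }
  q <- pmin(41L, pmax(2L, as.integer(q)))

  # qualities to Phred+33 strings, one substring per read
  ends <- cumsum(rl)
  starts <- ends - rl + 1L
  qual_all <- intToUtf8(q + 33L)
  quals <- substring(qual_all, starts, ends)

  seqs <- templates
  if (cfg$error_free) return(list(seq = seqs, qual = quals))
  hit <- which(stats::runif(n_bases) < phred_to_error(q))
  if (length(hit)) {
    read_of <- rep(seq_along(rl), rl)[hit]
    pos_of <- pos[hit]
    cur <- substring(seqs[read_of], pos_of, pos_of)
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "",
                   USE.NAMES = FALSE)
    for (j in seq_along(hit)) {
      substr(seqs[read_of[j]], pos_of[j], pos_of[j]) <- repl[j]
    }
  }
  if (cfg$indel_error_rate > 0) {
    ind <- which(stats::runif(n_bases) < cfg$indel_error_rate)
    for (j in ind) {
      r <- rep(seq_along(rl), rl)[j]
      p <- pos[j]
      ch <- strsplit(seqs[r], "")[[1]]
      qv <- phred_decode(quals[r])
      if (stats::runif(1) < 0.5 && length(ch) > 1L) {
        ch <- ch[-p]; qv <- qv[-p]
      } else {
        ch <- append(ch, sample(DNA_BASES, 1L), after = p)
        qv <- append(qv, qv[p], after = p)
      }
      seqs[r] <- paste(ch, collapse = "")
      quals[r] <- phred_encode(qv)
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate paired-end reads for one embryo
#'
#' Each read pair is drawn from the embryo's allele mixture; read 1 is the
#' first `read_length` bases of the allele fragment and read 2 the reverse
#' complement of the last `read_length` bases (raw orientation). Qualities
#' are Phred+33 and substitution errors follow `10^(-Q/10)` per base. The
#' ground-truth table records the source allele of every pair.
#'
#' @param mix An [embryo_mix()].
#' @param cfg A [read_sim_config()].
#' @param locus The `reference_locus` the alleles were built on (written
#'   alongside the reads when `out_dir` is given).
#' @param out_dir Optional directory; when given, writes `r1.fastq`,
#'   `r2.fastq`, `truth.tsv`, `reference.fasta` and `locus.yaml`.
#' @return List with `r1`, `r2` (data frames `id`, `seq`, `qual`), `truth`
#'   (data frame `pair_id`, `allele_label`), and `paths` (when written).
#' @export
simulate_embryo_reads <- function(mix, cfg = read_sim_config(), locus = NULL,
                                  out_dir = NULL) {
  stopifnot(inherits(mix, "embryo_mix"), inherits(cfg, "read_sim_config"))
  frag_len <- 2L * cfg$read_length - cfg$min_overlap_generated
  min_survivable <- 250L
  short <- vapply(mix$alleles, function(a) nchar(a$seq) < min_survivable, TRUE)
  if (any(short)) {
    warning(sprintf("allele(s) %s shorter than %d bases; their joined reads will be length-filtered",
                    paste(names(mix$alleles)[short], collapse = ", "),
                    min_survivable), call. = FALSE)
  }
  fragments <- vapply(mix$alleles, allele_fragment, "", frag_len = frag_len)
  labels <- vapply(mix$alleles, `[[`, "", "label")

  out <- with_seed(mix$seed, {
    n <- mix$n_read_pairs
    src <- sample.int(length(fragments), n, replace = TRUE, prob = mix$freqs)
    pair_id <- sprintf("%s:pair%06d", mix$embryo_id, seq_len(n))
    frag <- unname(fragments[src])
    fl <- nchar(frag)
    rl <- pmin(cfg$read_length, fl)
    fwd <- substr(frag, 1L, rl)
    rev <- revcomp(substring(frag, fl - rl + 1L, fl))
    e1 <- sim_read_batch(fwd, cfg)
    e2 <- sim_read_batch(rev, cfg)
    list(
      r1 = data.frame(id = pair_id, seq = e1$seq, qual = e1$qual,
                      stringsAsFactors = FALSE),
      r2 = data.frame(id = pair_id, seq = e2$seq, qual = e2$qual,
                      stringsAsFactors = FALSE),
      truth = data.frame(pair_id = pair_id, allele_label = unname(labels[src]),
                         stringsAsFactors = FALSE))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(r1 = file.path(out_dir, "r1.fastq"),
                  r2 = file.path(out_dir, "r2.fastq"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_fastq(out$r1, paths$r1)
    write_fastq(out$r2, paths$r2)
    utils::write.table(out$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(locus)) {
      paths$reference <- file.path(out_dir, "reference.fasta")
      paths$locus <- file.path(out_dir, "locus.yaml")
      writeLines(c(paste0(">", locus$name), locus$amplicon_seq), paths$reference)
      write_locus(locus, paths$locus)
    }
    out$paths <- paths
  }
  out
}
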