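# End-to-end pipeline: FASTQ pairs -> trim -> join -> length filter ->
# map -> enumerate -> classify -> per-embryo profile, with a stage log
# that accounts for every read at every boundary.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (FASTQ/locus YAML) or in-memory objects
#' (read data frames, `reference_locus`, lists of [edit_desc()]).
#'
#' @param r1,r2 Paired FASTQ paths or data frames (`id`, `seq`, `qual`).
#' @param locus Locus YAML path or a `reference_locus`.
#' @param template_edits Template edits: a YAML path or a list of
#'   [edit_desc()]; instantiated into template alleles for classification.
#' @param trim,join,align Stage configurations.
#' @param report_threshold Allele reporting threshold (strict; default 0.01).
#' @param biallelic_threshold Percent threshold for the biallelic call.
#' @param include_template_plus_sub See [build_profile()].
#' @param embryo_id Sample identifier.
#' @param out_dir Optional output directory; when set, the run writes its
#'   report and resolved configuration there.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(r1, r2, locus, template_edits = NULL,
                            trim = trim_config(), join = join_config(),
                            align = align_config(), report_threshold = 0.01,
                            biallelic_threshold = 96,
                            include_template_plus_sub = FALSE,
                            embryo_id = "embryo", out_dir = NULL) {
  if (report_threshold < 0 || report_threshold >= 1) {
    stop("report_threshold must be in [0, 1)", call. = FALSE)
  }
  if (biallelic_threshold <= 0 || biallelic_threshold > 100) {
    stop("biallelic_threshold must be a percentage in (0, 100]", call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, locus = locus,
                 template_edits = template_edits, trim = trim, join = join,
                 align = align, report_threshold = report_threshold,
                 biallelic_threshold = biallelic_threshold,
                 include_template_plus_sub = include_template_plus_sub,
                 embryo_id = embryo_id, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write template-edit descriptions (YAML)
#' @param edits List of [edit_desc()] objects.
#' @param path YAML file.
#' @return `write_edits` returns `path` invisibly; `read_edits` the list.
#' @export
write_edits <- function(edits, path) {
  yaml::write_yaml(lapply(edits, function(e)
    list(kind = e$kind, position = e$position, length = e$length,
         bases = e$bases, background = e$background,
         intended = e$intended)), path)
  invisible(path)
}

#' @rdname write_edits
#' @export
read_edits <- function(path) {
  lapply(yaml::read_yaml(path), function(e) {
    edit_desc(kind = e$kind, position = e$position,
              length = if (e$kind == "DEL") e$length else NULL,
              bases = e$bases, background = e$background,
              intended = isTRUE(e$intended))
  })
}

resolve_reads <- function(x) if (is.character(x)) read_fastq(x) else x
resolve_locus <- function(x) if (is.character(x)) read_locus(x) else validate_locus(x)

#' Run the full analysis pipeline for one embryo
#'
#' Deterministic given its inputs; the stage log records the read count
#' entering and leaving every stage (pairs in = joined + no-overlap;
#' joined = kept + length-removed; kept = mapped + unmapped + partial).
#'
#' @param cfg A [pipeline_config()].
#' @return List `profile` (an `embryo_profile`), `alleles` (enumerated
#'   counts), `calls`, `stage_log` (data frame `stage`, `n_in`, `n_out`,
#'   `n_dropped`), and `paths` when `out_dir` was set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  r1 <- resolve_reads(cfg$r1)
  r2 <- resolve_reads(cfg$r2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("read pair files differ in record count (%d vs %d)",
                 nrow(r1), nrow(r2)), call. = FALSE)
  }
  locus <- resolve_locus(cfg$locus)
  edits <- cfg$template_edits
  if (is.character(edits)) edits <- read_edits(edits)
  templates <- make_allele_set(locus, edits %||% list())

  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out,
                                           n_dropped = n_in - n_out)
  }

  n_pairs <- nrow(r1)
  trim_df <- function(df) {
    for (i in seq_len(nrow(df))) {
      t <- trim_longest_segment(df$seq[i], df$qual[i], cfg$trim)
      df$seq[i] <- t$seq
      df$qual[i] <- phred_encode(t$quals)
    }
    df
  }
  r1 <- trim_df(r1); r2 <- trim_df(r2)
  n_empty <- sum(nchar(r1$seq) == 0L | nchar(r2$seq) == 0L)
  note("trim", n_pairs, n_pairs - n_empty)

  jn <- join_pairs(r1, r2, cfg$join)
  note("join", n_pairs, nrow(jn$joined))

  lf <- length_filter(jn$joined, cfg$join)
  note("length_filter", nrow(jn$joined), nrow(lf$kept))

  mp <- map_reads(lf$kept, locus, cfg$align)
  note("map", nrow(lf$kept), length(mp$windows))

  alleles <- enumerate_alleles(mp$windows, total_joined = length(mp$windows),
                               locus = locus,
                               report_threshold = cfg$report_threshold)
  note("enumerate", length(mp$windows),
       length(mp$windows) - attr(alleles, "n_unreported"))

  calls <- classify_alleles(alleles, locus, templates, cfg$align)
  profile <- build_profile(alleles, calls, embryo_id = cfg$embryo_id,
                           biallelic_threshold = cfg$biallelic_threshold,
                           include_template_plus_sub = cfg$include_template_plus_sub)
  stage_log <- do.call(rbind, log)
  out <- list(profile = profile, alleles = alleles, calls = calls,
              stage_log = stage_log)
  if (!is.null(cfg$out_dir)) {
    out$paths <- write_report(list(profile), dir = cfg$out_dir,
                              stage_logs = list(stage_log))
    resolved <- unclass(cfg)
    resolved$r1 <- if (is.character(cfg$r1)) cfg$r1 else "<in-memory>"
    resolved$r2 <- if (is.character(cfg$r2)) cfg$r2 else "<in-memory>"
    resolved$locus <- if (is.character(cfg$locus)) cfg$locus else locus$name
    resolved$template_edits <- if (is.character(cfg$template_edits))
      cfg$template_edits else sprintf("<%d in-memory edits>",
                                      length(edits %||% list()))
    resolved[c("trim", "join", "align")] <-
      lapply(resolved[c("trim", "join", "align")], unclass)
    yaml::write_yaml(resolved, file.path(cfg$out_dir, "resolved_config.yaml"))
  }
  out
}

profile_to_list <- function(p) {
  list(embryo_id = p$embryo_id, mosaicism_call = p$mosaicism_call,
       pct_intended = p$pct_intended, pct_wt = p$pct_wt,
       pct_other = p$pct_other, biallelic_threshold = p$biallelic_threshold,
       calls = p$calls)
}

list_to_profile <- function(l) {
  calls <- as.data.frame(l$calls, stringsAsFactors = FALSE)
  structure(list(embryo_id = l$embryo_id, calls = calls,
                 pct_intended = l$pct_intended, pct_wt = l$pct_wt,
                 pct_other = l$pct_other, mosaicism_call = l$mosaicism_call,
                 biallelic_threshold = l$biallelic_threshold),
            class = "embryo_profile")
}

#' Write / read a machine-readable report for a set of embryo profiles
#'
#' Writes `profiles.json` (round-trips via [read_report()]), `alleles.tsv`
#' (one row per enumerated allele across embryos), `summary.txt`, and
#' optional per-embryo stage logs.
#'
#' @param profiles List of `embryo_profile` objects.
#' @param dir Output directory (created if needed).
#' @param stats Optional statistics list included verbatim in the JSON.
#' @param stage_logs Optional list of stage-log data frames.
#' @return Named list of written paths, invisibly.
#' @export
write_report <- function(profiles, dir, stats = NULL, stage_logs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(dir, "profiles.json"),
                tsv = file.path(dir, "alleles.tsv"),
                summary = file.path(dir, "summary.txt"))
  payload <- list(profiles = lapply(profiles, profile_to_list))
  if (!is.null(stats)) payload$stats <- stats
  jsonlite::write_json(payload, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  tab <- do.call(rbind, lapply(profiles, function(p)
    cbind(embryo_id = p$embryo_id, p$calls)))
  if (is.null(tab)) {
    tab <- data.frame(embryo_id = character(0), label = character(0),
                      allele_class = character(0), background = character(0),
                      count = integer(0), fraction = numeric(0),
                      pct = numeric(0))
  }
  utils::write.table(tab, paths$tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- unlist(lapply(profiles, function(p) {
    c(sprintf("%s\t%s\tintended=%.2f%%\twt=%.2f%%\tother=%.2f%%",
              p$embryo_id, p$mosaicism_call, p$pct_intended, p$pct_wt,
              p$pct_other))
  }))
  writeLines(c("embryo\tmosaicism_call\tpercentages", lines), paths$summary)
  if (!is.null(stage_logs)) {
    paths$stage_log <- file.path(dir, "stage_log.tsv")
    logtab <- do.call(rbind, lapply(seq_along(stage_logs), function(i)
      cbind(embryo = profiles[[i]]$embryo_id, stage_logs[[i]])))
    utils::write.table(logtab, paths$stage_log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_report
#' @param dir Report directory written by `write_report`.
#' @export
read_report <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "profiles.json"),
                                 simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  profiles <- lapply(seq_along(payload$profiles$embryo_id), function(i) {
    list_to_profile(list(
      embryo_id = payload$profiles$embryo_id[i],
      mosaicism_call = payload$profiles$mosaicism_call[i],
      pct_intended = payload$profiles$pct_intended[i],
      pct_wt = payload$profiles$pct_wt[i],
      pct_other = payload$profiles$pct_other[i],
      biallelic_threshold = payload$profiles$biallelic_threshold[i],
      calls = payload$profiles$calls[[i]]))
  })
  list(profiles = profiles, stats = payload$stats)
}
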