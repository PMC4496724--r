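# Minimal, strict FASTQ/FASTA I/O. A bespoke reader is used (rather than a
# heavyweight container) because the QC contract requires parse errors that
# name the offending record and line, and reads are carried as plain
# data frames (id, seq, qual) throughout the pipeline.

#' Read a 4-line FASTQ file into a data frame
#'
#' Strict parser: every record must be 4 lines, start with `@`, have a `+`
#' separator, equal sequence/quality lengths, and A/C/G/T/N bases.
#' Malformed input raises an error naming the offending record and line.
#' Gzip-compressed files are handled transparently.
#'
#' @param path FASTQ file ('.gz' allowed).
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ, %d lines is not a multiple of 4 (record starting at line %d is incomplete)",
                 path, length(lines), 4L * (length(lines) %/% 4L) + 1L),
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop(sprintf("%s: record %d (line %d) does not start with '@'",
                 path, bad[1], 4L * (bad[1] - 1L) + 1L), call. = FALSE)
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop(sprintf("%s: record %d (line %d) is missing the '+' separator",
                 path, bad[1], 4L * (bad[1] - 1L) + 3L), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("%s: record %d ('%s') sequence and quality lengths differ",
                 path, bad[1], sub("^@", "", hdr[bad[1]])), call. = FALSE)
  }
  bad <- which(!grepl("^[ACGTNacgtn]*$", seq))
  if (length(bad)) {
    stop(sprintf("%s: record %d ('%s') contains non-nucleotide characters",
                 path, bad[1], sub("^@", "", hdr[bad[1]])), call. = FALSE)
  }
  data.frame(id = sub("^@", "", hdr), seq = toupper(seq), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output file; a path ending in `.gz` is gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a single-sequence FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
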