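# Readers/writers for the plain-text formats the pipeline touches.
# Internal coordinates are 0-based half-open throughout; BED is native,
# human-readable reports convert to 1-based inclusive.

#' Read a FASTA file
#'
#' @param path path to a FASTA file (any line wrapping).
#' @return named character vector of upper-case sequences; names are the
#'   first whitespace-delimited word of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (wrapped at 70 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of ACGT(N) sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) .cpp_revcomp(x)

.strip_mate_suffix <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))

.parse_fastq_one <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record in '%s': file ends at line %d (not a multiple of 4)",
                 path, n), call. = FALSE)
  if (n == 0L)
    return(data.frame(name = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  hi <- seq(1L, n, by = 4L)
  bad <- hi[!startsWith(lines[hi], "@")]
  if (length(bad))
    stop(sprintf("FASTQ parse error in '%s' at line %d: header does not start with '@'",
                 path, bad[1]), call. = FALSE)
  pi <- hi + 2L
  bad <- pi[!startsWith(lines[pi], "+")]
  if (length(bad))
    stop(sprintf("FASTQ parse error in '%s' at line %d: separator does not start with '+'",
                 path, bad[1]), call. = FALSE)
  sq <- lines[hi + 1L]
  ql <- lines[hi + 3L]
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop(sprintf("FASTQ parse error in '%s' at line %d: sequence and quality lengths differ",
                 path, hi[bad[1]] + 3L), call. = FALSE)
  data.frame(name = substring(lines[hi], 2L), seq = sq, qual = ql,
             stringsAsFactors = FALSE)
}

#' Parse a pair of FASTQ files into read pairs
#'
#' Strict 4-line records. Mate pairing is validated by name after stripping
#' a trailing `/1` or `/2` suffix and anything after whitespace.
#'
#' @param path1,path2 mate FASTQ files.
#' @return a `read_pairs` data frame with columns `name`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
parse_fastq_pair <- function(path1, path2) {
  r1 <- .parse_fastq_one(path1)
  r2 <- .parse_fastq_one(path2)
  if (nrow(r1) != nrow(r2))
    stop(sprintf("mate pairing error: %d records in '%s' vs %d in '%s'",
                 nrow(r1), path1, nrow(r2), path2), call. = FALSE)
  n1 <- .strip_mate_suffix(r1$name)
  n2 <- .strip_mate_suffix(r2$name)
  bad <- which(n1 != n2)
  if (length(bad))
    stop(sprintf("mate pairing error at record %d: '%s' vs '%s'",
                 bad[1], r1$name[bad[1]], r2$name[bad[1]]), call. = FALSE)
  out <- data.frame(name = n1, seq1 = r1$seq, qual1 = r1$qual,
                    seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Write read pairs to a pair of FASTQ files
#'
#' Emits 4-line records with `/1` and `/2` suffixed names and Unix line
#' endings, so output is byte-reproducible.
#'
#' @param pairs a `read_pairs` data frame.
#' @param path1,path2 output mate files.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pair <- function(pairs, path1, path2) {
  .write_one <- function(name, seq, qual, suffix, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (length(name))
      writeLines(as.vector(rbind(paste0("@", name, suffix), seq, "+", qual)),
                 con, sep = "\n")
  }
  .write_one(pairs$name, pairs$seq1, pairs$qual1, "/1", path1)
  .write_one(pairs$name, pairs$seq2, pairs$qual2, "/2", path2)
  invisible(c(path1, path2))
}

#' Write interval records as 6-column BED
#'
#' 0-based half-open, tab-separated, sorted by (contig, start).
#'
#' @param records data frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(records, path) {
  cols <- c("contig", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(records)))
  records <- records[, cols, drop = FALSE]
  if (nrow(records)) {
    if (any(records$start < 0) || any(records$start >= records$end))
      stop("invalid interval: require 0 <= start < end", call. = FALSE)
    if (!all(records$strand %in% c("+", "-", ".")))
      stop("invalid strand: must be one of +, -, .", call. = FALSE)
    records <- records[order(records$contig, records$start, records$end), ,
                       drop = FALSE]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(records))
    writeLines(do.call(paste, c(records, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a 6-column BED file
#'
#' @param path BED6 file.
#' @return data frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:6] <- c("contig", "start", "end", "name", "score", "strand")
  x[, 1:6]
}

#' Read a flat key-value configuration file
#'
#' INI-style: `key = value` lines, `#` or `;` comments, optional
#' `[section]` headers which prefix keys as `section.key`. All values are
#' returned as character; callers coerce.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("config parse error: '%s' is not key = value", ln),
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(section)) key <- paste0(section, ".", key)
    out[[key]] <- val
  }
  out
}

#' Merge configuration lists (later sources win)
#'
#' @param base named list (e.g. from [read_config()]).
#' @param override named list (e.g. parsed CLI flags).
#' @return merged named list.
#' @export
merge_config <- function(base, override) {
  for (k in names(override)) base[[k]] <- override[[k]]
  base
}
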