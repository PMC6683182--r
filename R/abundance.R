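# Per-genome transgene abundance from sequencing depth ratios,
# standardized for aneuploid karyotypes. Host mean depth is taken to
# represent the cell line's average chromosomal copy number (n_chrom / 23
# relative to a haploid set), so
#   copies_per_cell            = depth_ratio * n_chrom / 23
#   copies_per_standard_genome = copies_per_cell * 46 / n_chrom
# which makes the 46-chromosome standardization explicit and testable.

#' Karyotype lookup table
#'
#' Defaults to the packaged table: C4-2B 83, PC3 62, MDA-MB-231 67
#' (midpoint of the reported 65-69 range), standard 46 chromosomes.
#'
#' @param path optional TSV with columns `cell_line`, `chromosomes`.
#' @return data frame `cell_line`, `chromosomes`.
#' @export
karyotype_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "karyotypes.tsv", package = "lucitrace",
                        mustWork = TRUE)
  kt <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "chromosomes") %in% names(kt)))
    stop("karyotype table must have columns cell_line, chromosomes",
         call. = FALSE)
  if (any(kt$chromosomes < 23))
    stop("karyotype error: chromosome counts must be >= 23", call. = FALSE)
  kt
}

#' Compute mean depths over host and transgene from alignment segments
#'
#' Depth is (aligned bases on reference) / (reference length); split reads
#' contribute their segment lengths to each side.
#'
#' @param segments output of [align_read_pairs()].
#' @param index the `kmer_index` used for alignment.
#' @param junctions optional output of [find_split_junctions()], used for
#'   the chimeric read count.
#' @return a `depth_profile`: `mean_host_depth`, `mean_transgene_depth`,
#'   `transgene_chimeric_read_count`, `total_mapped_reads`.
#' @export
compute_depths <- function(segments, index, junctions = NULL) {
  tg <- index$transgene_ref
  host_len <- sum(index$ref_lengths[index$ref_names != tg])
  tg_len <- index$ref_lengths[index$ref_names == tg]
  if (!nrow(segments)) {
    lt_log("no aligned segments: depths are zero", level = "warn")
    host_b <- tg_b <- 0
    mapped <- 0L
  } else {
    blen <- segments$read_end - segments$read_start
    is_tg <- segments$ref == tg
    host_b <- sum(as.numeric(blen[!is_tg]))
    tg_b <- sum(as.numeric(blen[is_tg]))
    mapped <- length(unique(paste(segments$name, segments$mate)))
  }
  structure(list(
    mean_host_depth = host_b / host_len,
    mean_transgene_depth = tg_b / tg_len,
    transgene_chimeric_read_count =
      if (is.null(junctions)) NA_integer_ else nrow(junctions),
    total_mapped_reads = mapped), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> host %.2fx, transgene %.2fx, chimeric reads %s, mapped reads %d\n",
              x$mean_host_depth, x$mean_transgene_depth,
              x$transgene_chimeric_read_count, x$total_mapped_reads))
  invisible(x)
}

#' Karyotype-standardized transgene abundance
#'
#' @param depth a `depth_profile`.
#' @param cell_line name present in `karyotypes`.
#' @param karyotypes a karyotype table (default the packaged one).
#' @return an `abundance_estimate`: `raw_depth_ratio`, `copies_per_cell`,
#'   `copies_per_standard_genome`, plus the lookup used.
#' @export
normalize_abundance <- function(depth, cell_line,
                                karyotypes = karyotype_table()) {
  stopifnot(inherits(depth, "depth_profile"))
  i <- match(cell_line, karyotypes$cell_line)
  if (is.na(i))
    stop(sprintf("karyotype-lookup error: unknown cell line '%s'", cell_line),
         call. = FALSE)
  if (depth$mean_host_depth <= 0)
    stop("degenerate-input error: zero host depth", call. = FALSE)
  n_chrom <- karyotypes$chromosomes[i]
  ratio <- depth$mean_transgene_depth / depth$mean_host_depth
  cpc <- ratio * n_chrom / 23
  structure(list(cell_line = cell_line, n_chrom = n_chrom,
                 raw_depth_ratio = ratio, copies_per_cell = cpc,
                 copies_per_standard_genome = cpc * 46 / n_chrom),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate> %s (%d chromosomes): depth ratio %.3f, %.2f copies/cell, %.2f copies per standard (46-chromosome) genome\n",
              x$cell_line, x$n_chrom, x$raw_depth_ratio, x$copies_per_cell,
              x$copies_per_standard_genome))
  invisible(x)
}

#' Per-standard-genome abundance ratio between two samples
#'
#' @param a,b `abundance_estimate` objects.
#' @return `a$copies_per_standard_genome / b$copies_per_standard_genome`.
#' @export
abundance_ratio <- function(a, b) {
  stopifnot(inherits(a, "abundance_estimate"),
            inherits(b, "abundance_estimate"))
  if (b$copies_per_standard_genome <= 0)
    stop("degenerate-input error: zero denominator abundance", call. = FALSE)
  a$copies_per_standard_genome / b$copies_per_standard_genome
}
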