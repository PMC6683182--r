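# Synthetic-data generators: host genomes with planted transgene insertions,
# paired-end reads, and plate-assay tables. These define the simulated study
# conditions used throughout the tests: random (repeat-free) host sequence,
# clean insertions with no target-site microstructure, constant base quality.

.valid_dna <- function(x) grepl("^[ACGT]+$", x)

.random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

#' Construct a host genome object
#'
#' @param name genome name.
#' @param sequences named character vector of contig sequences (ACGT).
#' @return a `host_genome` object.
#' @export
host_genome <- function(name, sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)))
  if (any(nchar(sequences) == 0))
    stop("invalid-sequence: empty contig", call. = FALSE)
  if (!all(.valid_dna(sequences)))
    stop("invalid-sequence: contigs must be ACGT only", call. = FALSE)
  structure(list(name = name, sequences = sequences,
                 length_bp = sum(nchar(sequences))),
            class = "host_genome")
}

#' @export
print.host_genome <- function(x, ...) {
  cat(sprintf("<host_genome> %s: %d contig(s), %s bp total\n", x$name,
              length(x$sequences), format(x$length_bp, big.mark = ",")))
  invisible(x)
}

#' Construct a transgene (reporter cassette) description
#'
#' Spans are 0-based half-open intervals within the cassette; the reporter
#' span is the luciferase-like coding region, the promoter span (optional)
#' the upstream promoter.
#'
#' @param name cassette name.
#' @param sequence ACGT string.
#' @param reporter_span integer length-2 vector `c(start, end)`.
#' @param promoter_span optional integer length-2 vector.
#' @return a `transgene_construct` object.
#' @export
transgene_construct <- function(name, sequence, reporter_span,
                                promoter_span = NULL) {
  if (!.valid_dna(sequence))
    stop("invalid-sequence: transgene must be ACGT only", call. = FALSE)
  L <- nchar(sequence)
  chk <- function(sp, what) {
    if (is.null(sp)) return(NULL)
    sp <- as.integer(sp)
    if (length(sp) != 2 || sp[1] < 0 || sp[2] > L || sp[1] >= sp[2])
      stop(sprintf("invalid %s span", what), call. = FALSE)
    sp
  }
  reporter_span <- chk(reporter_span, "reporter")
  promoter_span <- chk(promoter_span, "promoter")
  if (!is.null(promoter_span) &&
      promoter_span[1] < reporter_span[2] && reporter_span[1] < promoter_span[2])
    stop("promoter and reporter spans overlap", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 reporter_span = reporter_span, promoter_span = promoter_span,
                 length_bp = L),
            class = "transgene_construct")
}

#' The packaged synthetic CMV-luciferase cassette
#'
#' A 2,253 bp synthetic stand-in for a CMV-promoter firefly-luciferase
#' reporter cassette: random sequence carrying the published primer
#' annealing sites at offsets that reproduce the published amplicon sizes
#' (see `system.file("extdata", "transgene_synthetic.fa", package =
#' "lucitrace")`). Promoter region occupies [0, 600), reporter [600, 2253).
#'
#' @return a `transgene_construct`.
#' @export
default_transgene <- function() {
  fa <- read_fasta(system.file("extdata", "transgene_synthetic.fa",
                               package = "lucitrace", mustWork = TRUE))
  transgene_construct("synthetic_CMV_Luc", unname(fa[1]),
                      reporter_span = c(600L, 2253L),
                      promoter_span = c(0L, 600L))
}

#' Describe planned transgene insertion events
#'
#' @param contig contig names.
#' @param pos0 0-based host coordinates (the base before which the cassette
#'   is spliced).
#' @param strand "+" or "-" per event.
#' @param copies copies concatenated head-to-tail at each site (>= 1).
#' @return an `insertion_plan` data frame.
#' @export
insertion_plan <- function(contig, pos0, strand = "+", copies = 1L) {
  n <- length(contig)
  df <- data.frame(contig = as.character(contig), pos0 = as.integer(pos0),
                   strand = rep_len(as.character(strand), n),
                   copies = rep_len(as.integer(copies), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      stop("invalid-plan: strand must be + or -", call. = FALSE)
    if (any(df$copies < 1L))
      stop("invalid-plan: copies must be >= 1", call. = FALSE)
    if (anyDuplicated(df[, c("contig", "pos0")]))
      stop("invalid-plan: duplicate positions on a contig", call. = FALSE)
  }
  class(df) <- c("insertion_plan", "data.frame")
  df
}

#' Deterministically place n insertion sites with a minimum spacing
#'
#' Positions are drawn uniformly conditional on pairwise gaps of at least
#' `min_gap_bp` and a margin from the contig ends, via the standard
#' spacing construction (uniform order statistics on the reduced interval).
#'
#' @param contig contig name.
#' @param contig_len_bp contig length.
#' @param n number of sites.
#' @param min_gap_bp minimum distance between consecutive sites.
#' @param seed RNG seed.
#' @param margin_bp keep-out from both contig ends.
#' @return an `insertion_plan`.
#' @export
random_insertion_plan <- function(contig, contig_len_bp, n, min_gap_bp,
                                  seed, margin_bp = 10000L) {
  free <- contig_len_bp - 2 * margin_bp - (n - 1) * min_gap_bp
  if (free <= n)
    stop("invalid-plan: contig too short for requested spacing", call. = FALSE)
  set.seed(seed)
  y <- sort(floor(runif(n, 0, free)))
  pos <- as.integer(margin_bp + y + (seq_len(n) - 1L) * min_gap_bp)
  insertion_plan(rep(contig, n), pos)
}

#' Generate a host genome and its transgene-inserted counterpart
#'
#' Contig sequences are i.i.d. uniform ACGT. The inserted genome equals the
#' clean genome with the cassette (reverse-complemented for "-" events,
#' `copies` concatenated head-to-tail) spliced in before each planned
#' 0-based position. The truth table reports events in clean-genome
#' coordinates. Identical seeds give identical output.
#'
#' @param genome_len_bp total genome length; split evenly across contigs.
#' @param n_contigs number of contigs (named `chr1`, `chr2`, ...).
#' @param transgene a `transgene_construct`.
#' @param plan an `insertion_plan`.
#' @param seed RNG seed for the host sequence.
#' @return list with elements `clean` and `inserted` (`host_genome`) and
#'   `truth` (data frame `contig`, `pos0`, `strand`, `copies`).
#' @export
make_genome_with_insertions <- function(genome_len_bp, n_contigs = 1L,
                                        transgene, plan, seed) {
  stopifnot(inherits(transgene, "transgene_construct"),
            inherits(plan, "insertion_plan"))
  set.seed(seed)
  base_len <- genome_len_bp %/% n_contigs
  lens <- rep(base_len, n_contigs)
  lens[1] <- lens[1] + genome_len_bp - sum(lens)
  seqs <- vapply(lens, .random_dna, character(1))
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  clean <- host_genome("synthetic_host", seqs)

  if (nrow(plan)) {
    if (!all(plan$contig %in% names(seqs)))
      stop("invalid-plan: unknown contig", call. = FALSE)
    lim <- nchar(seqs)[plan$contig]
    if (any(plan$pos0 < 0L) || any(plan$pos0 > lim))
      stop("invalid-plan: position out of contig bounds", call. = FALSE)
  }
  ins_seqs <- seqs
  if (nrow(plan)) {
    cassette <- function(strand, copies) {
      s <- if (strand == "-") revcomp(transgene$sequence) else transgene$sequence
      paste(rep(s, copies), collapse = "")
    }
    for (ctg in unique(plan$contig)) {
      ev <- plan[plan$contig == ctg, , drop = FALSE]
      ev <- ev[order(-ev$pos0), , drop = FALSE]  # splice right-to-left
      s <- ins_seqs[[ctg]]
      for (i in seq_len(nrow(ev))) {
        p <- ev$pos0[i]
        s <- paste0(substr(s, 1L, p), cassette(ev$strand[i], ev$copies[i]),
                    substr(s, p + 1L, nchar(s)))
      }
      ins_seqs[[ctg]] <- s
    }
  }
  inserted <- host_genome("synthetic_host_inserted", ins_seqs)
  truth <- as.data.frame(plan)[order(plan$contig, plan$pos0), , drop = FALSE]
  rownames(truth) <- NULL
  list(clean = clean, inserted = inserted, truth = truth)
}

#' Paired-end read simulation settings
#'
#' Defaults model a conventional short-insert library: 2 x 150 bp reads,
#' insert mean 350 bp (sd 50), and a 0.1% uniform substitution error rate.
#'
#' @param read_length_bp read length.
#' @param insert_mean_bp,insert_sd_bp Gaussian fragment-size model.
#' @param coverage_x mean sequenced bases per genome base.
#' @param per_base_error_rate i.i.d. substitution probability per base.
#' @param seed RNG seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(read_length_bp = 150L, insert_mean_bp = 350,
                            insert_sd_bp = 50, coverage_x = 30,
                            per_base_error_rate = 0.001, seed = 1L) {
  if (coverage_x <= 0) stop("config error: coverage must be > 0", call. = FALSE)
  if (insert_mean_bp <= read_length_bp)
    stop("config error: insert mean must exceed read length", call. = FALSE)
  if (per_base_error_rate < 0 || per_base_error_rate > 1)
    stop("config error: error rate must be in [0,1]", call. = FALSE)
  structure(list(read_length_bp = as.integer(read_length_bp),
                 insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
                 coverage_x = coverage_x,
                 per_base_error_rate = per_base_error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs)
  nerr <- rbinom(length(seqs), rl, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      sub <- sample(setdiff(bases, old), 1L)
      substr(seqs[i], p, p) <- sub
    }
  }
  seqs
}

#' Simulate paired-end reads from a genome
#'
#' Fragment count is `floor(coverage * genome_len / (2 * read_length))`.
#' Fragments are uniform over the genome with Gaussian insert sizes,
#' resampled until within `[read_length, insert_mean + 6 * insert_sd]`;
#' mate 1 is the fragment start, mate 2 the reverse complement of the
#' fragment end. Substitution errors are i.i.d.; qualities are constant
#' high ("I"). Identical seeds give byte-identical FASTQ via
#' [write_fastq_pair()].
#'
#' @param genome a `host_genome`.
#' @param cfg a `read_sim_config`.
#' @return a `read_pairs` data frame.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(genome, "host_genome"), inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  rl <- cfg$read_length_bp
  n <- as.integer(floor(cfg$coverage_x * genome$length_bp / (2 * rl)))
  if (n < 1L) stop("config error: no read pairs to simulate", call. = FALSE)
  lo <- rl
  hi <- cfg$insert_mean_bp + 6 * cfg$insert_sd_bp
  isize <- round(rnorm(n, cfg$insert_mean_bp, cfg$insert_sd_bp))
  bad <- which(isize < lo | isize > hi)
  while (length(bad)) {
    isize[bad] <- round(rnorm(length(bad), cfg$insert_mean_bp, cfg$insert_sd_bp))
    bad <- bad[isize[bad] < lo | isize[bad] > hi]
  }
  isize <- as.integer(isize)
  clens <- nchar(genome$sequences)
  if (any(max(isize) > clens))
    isize <- pmin(isize, min(clens))
  ctg <- if (length(clens) == 1L) rep(1L, n) else
    sample.int(length(clens), n, replace = TRUE, prob = clens / sum(clens))
  start <- as.integer(floor(runif(n) * (clens[ctg] - isize + 1)))  # 0-based
  seq1 <- character(n); seq2 <- character(n)
  for (ci in seq_along(clens)) {
    sel <- which(ctg == ci)
    if (!length(sel)) next
    s <- genome$sequences[[ci]]
    seq1[sel] <- substring(s, start[sel] + 1L, start[sel] + rl)
    ends <- start[sel] + isize[sel]
    seq2[sel] <- revcomp(substring(s, ends - rl + 1L, ends))
  }
  seq1 <- .inject_errors(seq1, cfg$per_base_error_rate)
  seq2 <- .inject_errors(seq2, cfg$per_base_error_rate)
  qual <- strrep("I", rl)
  out <- data.frame(name = sprintf("rp%07d", seq_len(n)),
                    seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Plate-assay simulation settings
#'
#' Defaults mirror a routine reporter titration: seeding densities 500 to
#' 50,000 cells/well, 4 replicates, and 10% multiplicative (log-normal)
#' well-to-well noise.
#'
#' @param cell_titration strictly increasing positive cell counts per well.
#' @param slope_rlu_per_cell bioluminescence per cell (RLU/cell).
#' @param cocult_fold multiplicative RLU effect of co-culture (>= 0);
#'   DNA is unaffected (the co-culture artefact: signal rises, cell number
#'   does not).
#' @param noise_cv coefficient of variation of mean-one log-normal noise.
#' @param replicates replicate wells per condition (>= 2).
#' @param seed RNG seed.
#' @return a `plate_sim_config` list.
#' @export
plate_sim_config <- function(cell_titration = c(500L, 1000L, 2000L, 5000L,
                                                10000L, 20000L, 50000L),
                             slope_rlu_per_cell = 0.02, cocult_fold = 1,
                             noise_cv = 0.1, replicates = 4L, seed = 1L) {
  if (any(cell_titration <= 0) || is.unsorted(cell_titration, strictly = TRUE))
    stop("config error: cell counts must be positive and strictly increasing",
         call. = FALSE)
  if (replicates < 2L)
    stop("config error: replicates must be >= 2", call. = FALSE)
  if (cocult_fold < 0)
    stop("config error: cocult_fold must be >= 0", call. = FALSE)
  structure(list(cell_titration = as.integer(cell_titration),
                 slope_rlu_per_cell = slope_rlu_per_cell,
                 cocult_fold = cocult_fold, noise_cv = noise_cv,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "plate_sim_config")
}

# mean-one multiplicative log-normal noise
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a mono- versus co-culture plate assay
#'
#' Mono-culture RLU is `slope * cells * noise`; co-culture RLU carries the
#' additional `cocult_fold` factor. DNA is proportional to seeded cells in
#' both arms (co-culture changes signal, not cell number).
#'
#' @param cfg a `plate_sim_config`.
#' @param dna_per_cell DNA units per cell (default 6.6, pg-scale).
#' @return data frame with columns `condition` ("mono"/"cocult"),
#'   `cells_seeded`, `replicate`, `RLU`, `DNA`.
#' @export
simulate_plate <- function(cfg, dna_per_cell = 6.6) {
  stopifnot(inherits(cfg, "plate_sim_config"))
  set.seed(cfg$seed)
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      cells_seeded = cfg$cell_titration,
                      condition = c("mono", "cocult"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "cells_seeded", "replicate")]
  n <- nrow(grid)
  fold <- ifelse(grid$condition == "cocult", cfg$cocult_fold, 1)
  grid$RLU <- cfg$slope_rlu_per_cell * grid$cells_seeded * fold *
    .ln_noise(n, cfg$noise_cv)
  grid$DNA <- dna_per_cell * grid$cells_seeded * .ln_noise(n, cfg$noise_cv)
  rownames(grid) <- NULL
  grid
}
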