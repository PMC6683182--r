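mk_junctions <- function(bp, side = "left", orient = "+", contig = "chr1",
                         mh = 0L) {
  n <- length(bp)
  data.frame(name = sprintf("r%d", seq_len(n)), mate = 1L,
             host_contig = contig, host_bp = as.integer(bp),
             side = rep_len(side, n), tg_orient = rep_len(orient, n),
             tg_bp = 0L, host_overhang = 50L, tg_overhang = 50L,
             microhomology = rep_len(as.integer(mh), n), gap_bp = 0L,
             mismatches = 0L, stringsAsFactors = FALSE)
}

mk_pairs <- function(lo, hi, contig = "chr1") {
  data.frame(name = sprintf("p%d", seq_along(lo)), host_contig = contig,
             interval_lo = lo, interval_hi = hi, host_strand = "+",
             tg_start = 0, tg_strand = "+", stringsAsFactors = FALSE)
}

test_that("junction clustering follows single linkage with a median position", {
  expect_equal(nrow(cluster_junctions(NULL)), 0L)
  cl <- cluster_junctions(mk_junctions(c(1000L, 1003L, 1008L)),
                          site_call_config(cluster_window_bp = 10L))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$position, 1003L)
  expect_equal(cl$split_support, 3L)
  cl2 <- cluster_junctions(mk_junctions(c(1000L, 1020L)),
                           site_call_config(cluster_window_bp = 10L))
  expect_equal(nrow(cl2), 2L)  # 20 bp apart > 10 bp window
})

test_that("head and tail junctions of one insertion merge into a single site", {
  jn <- rbind(mk_junctions(c(5000L, 5000L, 5001L), side = "left"),
              mk_junctions(c(4998L, 5000L), side = "right"))
  cl <- cluster_junctions(jn)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$split_support, 5L)
  expect_identical(cl$sides, "left+right")
})

test_that("discordant pairs corroborate sites inside their implied interval", {
  prov <- cluster_junctions(mk_junctions(rep(500000L, 2L)))
  pairs <- mk_pairs(499700, 500000)  # site at the interval's right edge
  sites <- corroborate_sites(prov, pairs,
                             site_call_config(cluster_window_bp = 10L))
  expect_equal(sites$discordant_support, 1L)
  expect_true(sites$corroborated)
})

test_that("support thresholds drop weak sites but keep the accounting", {
  cfg <- site_call_config(min_split_support = 2L, min_disc_support = 2L)
  prov <- cluster_junctions(mk_junctions(1000L), cfg)  # 1 split read
  sites <- corroborate_sites(prov, NULL, cfg)
  expect_equal(nrow(sites), 0L)
  expect_equal(attr(sites, "dropped")$split_read_support, 1L)
  # one lone pair founds nothing (1 < min_disc_support)
  sites2 <- corroborate_sites(cluster_junctions(NULL, cfg),
                              mk_pairs(100, 400), cfg)
  expect_equal(nrow(sites2), 0L)
  # two overlapping unassigned pairs found a discordant-only site
  sites3 <- corroborate_sites(cluster_junctions(NULL, cfg),
                              mk_pairs(c(100, 150), c(400, 450)), cfg)
  expect_equal(nrow(sites3), 1L)
  expect_equal(sites3$discordant_support, 2L)
  expect_false(sites3$corroborated)
})

test_that("split-read membership is conserved across emitted and dropped sites", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    jn <- mk_junctions(sort(sample.int(5000L, n, replace = TRUE)),
                       side = sample(c("left", "right"), n, replace = TRUE))
    cfg <- site_call_config(cluster_window_bp = sample(0:30, 1))
    sites <- corroborate_sites(cluster_junctions(jn, cfg), NULL, cfg)
    total <- sum(sites$split_read_support) +
      sum(attr(sites, "dropped")$split_read_support)
    expect_equal(total, n)
  }
})

test_that("widening the cluster window never increases the site count", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    jn <- mk_junctions(sort(sample.int(3000L, n, replace = TRUE)))
    counts <- vapply(c(0L, 5L, 10L, 25L, 60L, 200L), function(w) {
      nrow(cluster_junctions(jn, site_call_config(cluster_window_bp = w)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("site outputs write BED6 breakpoints and a link table", {
  bed <- tempfile(fileext = ".bed"); link <- tempfile(fileext = ".tsv")
  empty <- corroborate_sites(cluster_junctions(NULL), NULL)
  write_site_outputs(empty, bed, link)
  expect_equal(file.size(bed), 0)
  expect_identical(readLines(link),
                   "host_contig\thost_pos\ttransgene_name\ttransgene_pos\tsupport")
  jn <- rbind(mk_junctions(rep(1000L, 3L), side = "left"),
              mk_junctions(rep(2000L, 2L), side = "right"))
  sites <- corroborate_sites(cluster_junctions(jn), NULL)
  write_site_outputs(sites, bed, link, transgene_name = "luc")
  b <- read_bed(bed)
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(1000L, 2000L))       # 0-based breakpoints
  expect_equal(b$end, b$start + 1L)
  expect_equal(b$score, c(3, 2))
  out <- capture.output(print(sites))
  expect_true(any(grepl("1001", out)))          # report view is 1-based
  unlink(c(bed, link))
})

test_that("simulated insertions are recovered exactly, with no false sites", {
  # parameter-recovery property at reduced scale: several seeds, two
  # insertions >= 10 kb apart, error up to 0.5%
  tg <- toy_transgene()
  for (sd in 1:4) {
    plan <- insertion_plan(rep("chr1", 2L), c(12000L, 28000L),
                           strand = c("+", "-"))
    gs <- make_genome_with_insertions(40000L, 1L, tg, plan, seed = sd)
    rp <- simulate_reads(gs$inserted,
                         read_sim_config(coverage_x = 20,
                                         per_base_error_rate = 0.005,
                                         seed = sd + 50L))
    sites <- run_insertion_pipeline(rp, gs$clean, tg)$sites
    expect_equal(nrow(sites), 2L)
    expect_true(all(abs(sort(sites$position) - sort(gs$truth$pos0)) <= 5L))
    expect_identical(sites$tg_orient[order(sites$position)], c("+", "-"))
  }
})
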