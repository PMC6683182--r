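test_that("an empty insertion plan leaves the genome unchanged", {
  tg <- toy_transgene()
  gs <- make_genome_with_insertions(5000L, 1L, tg, insertion_plan(
    character(0), integer(0)), seed = 1L)
  expect_identical(gs$clean$sequences, gs$inserted$sequences)
  expect_identical(nrow(gs$truth), 0L)
})

test_that("splicing places the cassette at the planned coordinate", {
  tg <- toy_transgene(len = 600L)
  gs <- make_genome_with_insertions(20000L, 1L, tg,
                                    insertion_plan("chr1", 5000L), seed = 2L)
  ins <- gs$inserted$sequences[["chr1"]]
  expect_equal(nchar(ins), 20000L + 600L)
  expect_identical(substr(ins, 5001L, 5600L), tg$sequence)
  expect_identical(substr(ins, 1L, 5000L),
                   substr(gs$clean$sequences[["chr1"]], 1L, 5000L))
  expect_identical(substr(ins, 5601L, 20600L),
                   substr(gs$clean$sequences[["chr1"]], 5001L, 20000L))
})

test_that("minus-strand events splice the independent reverse complement", {
  tg <- toy_transgene(len = 400L)
  gs <- make_genome_with_insertions(10000L, 1L, tg,
                                    insertion_plan("chr1", 4000L, strand = "-"),
                                    seed = 3L)
  ins <- gs$inserted$sequences[["chr1"]]
  expect_identical(substr(ins, 4001L, 4400L), bio_revcomp(tg$sequence))
})

test_that("multiple copies concatenate head-to-tail and length is conserved", {
  tg <- toy_transgene(len = 300L)
  for (seed in 1:5) {
    n_ev <- sample(0:3, 1)
    plan <- if (n_ev) insertion_plan(rep("chr1", n_ev),
                                     sort(sample(seq(500L, 7500L, by = 700L), n_ev)),
                                     copies = sample(1:3, n_ev, replace = TRUE))
            else insertion_plan(character(0), integer(0))
    gs <- make_genome_with_insertions(8000L, 1L, tg, plan, seed = seed)
    expect_equal(gs$inserted$length_bp,
                 gs$clean$length_bp + sum(plan$copies) * 300L)
  }
  gs <- make_genome_with_insertions(5000L, 1L, tg,
                                    insertion_plan("chr1", 2000L, copies = 2L),
                                    seed = 9L)
  expect_identical(substr(gs$inserted$sequences[["chr1"]], 2001L, 2600L),
                   strrep(tg$sequence, 2L))
})

test_that("invalid plans and sequences are rejected", {
  tg <- toy_transgene()
  expect_error(make_genome_with_insertions(5000L, 1L, tg,
                                           insertion_plan("chr1", 6000L),
                                           seed = 1L), "invalid-plan")
  expect_error(insertion_plan("chr1", 10L, strand = "x"), "invalid-plan")
  expect_error(transgene_construct("bad", "ACGTN", c(0L, 2L)),
               "invalid-sequence")
})

test_that("read-pair count follows the coverage formula", {
  tg <- toy_transgene()
  gs <- make_genome_with_insertions(1e5, 1L, tg,
                                    insertion_plan(character(0), integer(0)),
                                    seed = 4L)
  cfg <- read_sim_config(read_length_bp = 150L, coverage_x = 30,
                         per_base_error_rate = 0, seed = 1L)
  rp <- simulate_reads(gs$clean, cfg)
  expect_equal(nrow(rp), floor(30 * 1e5 / (2 * 150)))
})

test_that("zero-error reads are exact substrings of the genome", {
  tg <- toy_transgene()
  gs <- make_genome_with_insertions(8000L, 1L, tg,
                                    insertion_plan("chr1", 4000L), seed = 7L)
  g <- gs$inserted$sequences[["chr1"]]
  rp <- simulate_reads(gs$inserted,
                       read_sim_config(coverage_x = 5,
                                       per_base_error_rate = 0, seed = 8L))
  for (i in seq_len(nrow(rp))) {
    expect_true(length(occ0(rp$seq1[i], g)) >= 1L)
    expect_true(length(occ0(bio_revcomp(rp$seq2[i]), g)) >= 1L)
  }
})

test_that("read simulation is byte-identical under a fixed seed", {
  tg <- toy_transgene()
  gs <- make_genome_with_insertions(20000L, 1L, tg,
                                    insertion_plan("chr1", 9000L), seed = 11L)
  cfg <- read_sim_config(coverage_x = 3, per_base_error_rate = 0.01,
                         seed = 12L)
  f <- replicate(4, tempfile(fileext = ".fq"))
  write_fastq_pair(simulate_reads(gs$inserted, cfg), f[1], f[2])
  write_fastq_pair(simulate_reads(gs$inserted, cfg), f[3], f[4])
  expect_identical(readBin(f[1], "raw", file.size(f[1])),
                   readBin(f[3], "raw", file.size(f[3])))
  expect_identical(readBin(f[2], "raw", file.size(f[2])),
                   readBin(f[4], "raw", file.size(f[4])))
  unlink(f)
})

test_that("plate simulation reproduces configured signal exactly without noise", {
  cfg <- plate_sim_config(slope_rlu_per_cell = 0.0272, cocult_fold = 1,
                          noise_cv = 0, replicates = 2L, seed = 1L)
  p <- simulate_plate(cfg)
  mono <- p[p$condition == "mono", c("cells_seeded", "replicate", "RLU", "DNA")]
  co <- p[p$condition == "cocult", c("cells_seeded", "replicate", "RLU", "DNA")]
  rownames(mono) <- rownames(co) <- NULL
  expect_identical(mono, co)
  expect_equal(p$RLU[p$cells_seeded == 10000 & p$condition == "mono"],
               rep(272, 2))
})

test_that("co-culture fold applies to RLU at every titration point, not DNA", {
  cfg <- plate_sim_config(slope_rlu_per_cell = 0.02, cocult_fold = 7,
                          noise_cv = 0, replicates = 2L, seed = 2L)
  p <- simulate_plate(cfg)
  mono <- p[p$condition == "mono", ]
  co <- p[p$condition == "cocult", ]
  expect_equal(co$RLU / mono$RLU, rep(7, nrow(mono)))
  expect_equal(co$DNA, mono$DNA)
})

test_that("simulator configs validate their inputs", {
  expect_error(read_sim_config(coverage_x = 0), "config error")
  expect_error(read_sim_config(insert_mean_bp = 100, read_length_bp = 150),
               "config error")
  expect_error(plate_sim_config(cell_titration = c(100, 100)), "config error")
  expect_error(plate_sim_config(replicates = 1L), "config error")
})
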