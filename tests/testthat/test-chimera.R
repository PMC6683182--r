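test_that("k-mer lookup matches an exhaustive scan, both strands", {
  toy <- toy_pipeline()
  idx <- toy$res$index
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  km <- substr(tgseq, 1L, 15L)
  expect_identical(occ0(km, host), integer(0))  # repeat-free toy
  hits <- query_index(idx, km)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 0L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$ref, "toy_tg")
  rc_hits <- query_index(idx, bio_revcomp(km))
  expect_equal(rc_hits$pos, 0L)
  expect_identical(rc_hits$strand, "-")
  absent <- strrep("A", 15L)
  while (length(occ0(absent, host)) || length(occ0(absent, tgseq)))
    absent <- paste0(substr(absent, 2L, 15L), "C")
  expect_equal(nrow(query_index(idx, absent)), 0L)
})

test_that("k longer than the shortest reference is a config error", {
  host <- host_genome("h", c(chr1 = strrep("ACGT", 100L)))
  tg <- transgene_construct("t", strrep("GATTACA", 4L), c(0L, 28L))
  expect_error(build_index(host, tg, k = 30L), "longer than")
})

test_that("an error-free host read aligns as one full-length segment", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  seg <- align_read(substr(host, 501L, 650L), toy$res$index)
  expect_equal(nrow(seg), 1L)
  expect_true(seg$full_length)
  expect_equal(seg$mismatches, 0L)
  expect_equal(c(seg$read_start, seg$read_end), c(0L, 150L))
  expect_equal(seg$ref_start, 500)
})

test_that("a 60/90 chimeric read splits at the constructed cut point", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  hp <- find_clean_host_pos(host, tgseq, 60L, 90L)
  rd <- make_clean_split_read(host, tgseq, hp, 60L, 90L)
  cfg0 <- chimera_config(max_mismatch_per_segment = 0L)
  seg <- align_read(rd, toy$res$index, cfg0)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$read_start, c(0L, 60L))
  expect_equal(seg$read_end, c(60L, 150L))
  expect_identical(seg$ref, c("chr1", "toy_tg"))
  segs <- align_read_pairs(data.frame(name = "r", seq1 = rd, qual1 = "",
                                      seq2 = substr(host, 1, 150), qual2 = ""),
                           toy$res$index, cfg0)
  jn <- find_split_junctions(segs, toy$res$index, cfg0)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$host_bp, hp + 60L)
  expect_equal(c(jn$host_overhang, jn$tg_overhang), c(60L, 90L))
})

test_that("substitutions within the budget keep the segmentation and are counted", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  hp <- find_clean_host_pos(host, tgseq, 60L, 90L)
  rd <- make_clean_split_read(host, tgseq, hp, 60L, 90L)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  for (p in c(21L, 41L)) substr(rd, p, p) <- flip(substr(rd, p, p))
  seg <- align_read(rd, toy$res$index, chimera_config())
  h <- seg[seg$ref == "chr1" & seg$read_start == 0L, ]
  expect_equal(nrow(h), 1L)
  expect_gte(h$read_end, 60L)
  expect_equal(h$mismatches, 2L)
  segs <- align_read_pairs(data.frame(name = "r", seq1 = rd, qual1 = "",
                                      seq2 = substr(host, 1, 150), qual2 = ""),
                           toy$res$index, chimera_config())
  jn <- find_split_junctions(segs, toy$res$index, chimera_config())
  expect_equal(jn$host_bp, hp + 60L)
})

test_that("the overhang filter boundary sits exactly at the configured minimum", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  cfg <- chimera_config(min_overhang_bp = 20L, max_mismatch_per_segment = 0L)
  mk <- function(hlen) {
    hp <- find_clean_host_pos(host, tgseq, hlen, 150L - hlen, start = 2000L)
    rd <- make_clean_split_read(host, tgseq, hp, hlen, 150L - hlen)
    segs <- align_read_pairs(data.frame(name = "r", seq1 = rd, qual1 = "",
                                        seq2 = substr(host, 1, 150),
                                        qual2 = ""), toy$res$index, cfg)
    find_split_junctions(segs, toy$res$index, cfg)
  }
  expect_equal(nrow(mk(19L)), 0L)   # 19 bp host side: filtered
  expect_equal(nrow(mk(20L)), 1L)   # 20 bp: retained ("at least 20")
  expect_equal(nrow(mk(130L)), 1L)  # 20 bp transgene side: retained
  expect_equal(nrow(mk(131L)), 0L)  # 19 bp transgene side: filtered
})

test_that("microhomology is resolved to the leftmost compatible host coordinate", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  p <- 4000L; h <- 4L
  # force h bases of microhomology: host bases after the cut equal the
  # transgene start
  substr(host, p + 1L, p + h) <- substr(tgseq, 1L, h)
  # and break the run cleanly at both ends
  stopifnot(substr(host, p + h + 1L, p + h + 1L) !=
              substr(tgseq, h + 1L, h + 1L))
  hg <- host_genome("edited", c(chr1 = host))
  idx <- build_index(hg, toy$tg)
  rd <- paste0(substr(host, p - 59L, p), substr(tgseq, 1L, 90L))
  segs <- align_read_pairs(data.frame(name = "r", seq1 = rd, qual1 = "",
                                      seq2 = substr(host, 1, 150), qual2 = ""),
                           idx, chimera_config())
  jn <- find_split_junctions(segs, idx, chimera_config(),
                             pairs = data.frame(name = "r", seq1 = rd,
                                                seq2 = substr(host, 1, 150)))
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$host_bp, p)          # leftmost of the ambiguous run
  expect_equal(jn$microhomology, h)
})

test_that("split finder equals the brute-force all-cut-points oracle on toys", {
  toy <- toy_pipeline()
  host <- toy$gs$clean$sequences[["chr1"]]
  tgseq <- toy$tg$sequence
  res <- toy$res
  jn <- find_split_junctions(res$segments, res$index, chimera_config(),
                             pairs = toy$rp)
  impl <- split(jn$host_bp, paste(jn$name, jn$mate))
  seqs <- c(structure(toy$rp$seq1, names = paste(toy$rp$name, 1L)),
            structure(toy$rp$seq2, names = paste(toy$rp$name, 2L)))
  checked <- 0L
  for (key in names(seqs)) {
    expected <- oracle_junction_keys(seqs[[key]], host, tgseq, 20L)
    got <- sort(unique(impl[[key]]))
    if (is.null(got)) got <- integer(0)
    expect_identical(got, expected)
    checked <- checked + length(expected)
  }
  expect_gte(checked, 10L)  # the fixture must actually exercise junctions
})

test_that("raising the overhang threshold never increases the junction count", {
  toy <- toy_pipeline()
  counts <- vapply(c(10L, 20L, 30L, 45L, 60L), function(m) {
    cfg <- chimera_config(min_overhang_bp = m)
    nrow(find_split_junctions(toy$res$segments, toy$res$index, cfg,
                              pairs = toy$rp))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_gt(counts[1], 0L)
})

test_that("junction keys are invariant under reverse-complementing every read", {
  toy <- toy_pipeline()
  rp <- toy$rp
  rp_rc <- rp
  rp_rc$seq1 <- revcomp(rp$seq1)
  rp_rc$seq2 <- revcomp(rp$seq2)
  idx <- toy$res$index
  seg_rc <- align_read_pairs(rp_rc, idx, chimera_config())
  jn_rc <- find_split_junctions(seg_rc, idx, chimera_config(), pairs = rp_rc)
  jn <- find_split_junctions(toy$res$segments, idx, chimera_config(),
                             pairs = rp)
  key <- function(j) sort(paste(j$host_bp, j$tg_bp))
  expect_identical(key(jn_rc), key(jn))
})

test_that("discordant pairs require one full-length mate on each reference", {
  toy <- toy_pipeline()
  res <- toy$res
  dp <- res$pairs
  expect_gt(nrow(dp), 0L)
  # both-mates-host pairs are absent
  seg <- res$segments
  fl <- seg[seg$full_length, ]
  host_only <- names(which(tapply(fl$ref != "toy_tg", fl$name, all)))
  expect_length(intersect(dp$name, host_only), 0L)
  # the implied interval brackets the planted insertion
  truth <- toy$gs$truth$pos0
  w <- 10L
  for (i in seq_len(nrow(dp))) {
    expect_true(any(truth >= dp$interval_lo[i] - w &
                    truth < dp$interval_hi[i] + w))
  }
  # split-read mates are handled by the junction finder, not here
  jn <- find_split_junctions(seg, res$index, chimera_config(), pairs = toy$rp)
  expect_length(intersect(dp$name, jn$name), 0L)
})
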