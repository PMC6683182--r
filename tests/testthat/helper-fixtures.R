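# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk except the
# packaged extdata tables.

# independent reverse complement (Biostrings), used as the oracle against
# the package's own revcomp and minus-strand splicing
bio_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# small random transgene for toy genomes (distinct from the packaged one so
# tests do not depend on its internals)
toy_transgene <- function(len = 600L, seed = 99L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  transgene_construct("toy_tg", s, reporter_span = c(0L, len))
}

# 0-based occurrences of pattern in subject (exact)
occ0 <- function(p, s) {
  h <- gregexpr(p, s, fixed = TRUE)[[1]]
  if (h[1] == -1L) integer(0) else as.integer(h) - 1L
}

# Brute-force split-read junction finder: enumerates every cut point of the
# read (and of its reverse complement) and keeps cuts whose two parts match
# host and transgene exactly. Mirrors the production conventions: a
# full-length placement suppresses junctions, retention requires
# min_overhang on both sides of some valid cut, and the reported host
# breakpoint is the leftmost compatible coordinate. Returns host
# breakpoints (possibly several orientations per read).
oracle_junction_keys <- function(read, host_seq, tg_seq, min_overhang = 20L) {
  L <- nchar(read)
  full <- function(r) {
    length(occ0(r, host_seq)) || length(occ0(r, tg_seq)) ||
      length(occ0(bio_revcomp(r), host_seq)) ||
      length(occ0(bio_revcomp(r), tg_seq))
  }
  if (full(read)) return(integer(0))
  keys <- integer(0)
  for (R in unique(c(read, bio_revcomp(read)))) {
    # host-prefix layout
    valid <- integer(0); anchors <- integer(0)
    for (cc in seq_len(L - 1L)) {
      pre <- substr(R, 1L, cc)
      suf <- substr(R, cc + 1L, L)
      hp <- occ0(pre, host_seq)
      ts <- c(occ0(suf, tg_seq), occ0(suf, bio_revcomp(tg_seq)))
      if (length(hp) == 1L && length(ts) >= 1L) {
        valid <- c(valid, cc); anchors <- c(anchors, hp)
      }
    }
    if (length(valid) && max(valid) >= min_overhang &&
        (L - min(valid)) >= min_overhang) {
      i <- which.min(valid)
      keys <- c(keys, anchors[i] + valid[i])
    }
    # host-suffix layout
    valid <- integer(0); anchors <- integer(0)
    for (cc in seq_len(L - 1L)) {
      pre <- substr(R, 1L, cc)
      suf <- substr(R, cc + 1L, L)
      hs <- occ0(suf, host_seq)
      tp <- c(occ0(pre, tg_seq), occ0(pre, bio_revcomp(tg_seq)))
      if (length(hs) == 1L && length(tp) >= 1L) {
        valid <- c(valid, cc); anchors <- c(anchors, hs)
      }
    }
    if (length(valid) && (L - min(valid)) >= min_overhang &&
        max(valid) >= min_overhang) {
      i <- which.min(valid)
      keys <- c(keys, anchors[i])
    }
  }
  sort(unique(keys))
}

# construct a chimeric read host[hp, hp+hlen) + transgene[0, tlen) from
# given sequences, verifying there is no accidental microhomology at the
# junction so that segment lengths equal the construction exactly
make_clean_split_read <- function(host_seq, tg_seq, hp, hlen, tlen) {
  rd <- paste0(substr(host_seq, hp + 1L, hp + hlen),
               substr(tg_seq, 1L, tlen))
  # no accidental extension: host base after the junction must differ from
  # the transgene start, and the transgene's base "before" its start from
  # the host boundary base
  stopifnot(substr(host_seq, hp + hlen + 1L, hp + hlen + 1L) !=
              substr(tg_seq, 1L, 1L))
  rd
}

# locate a host position where a clean (no-microhomology) junction read can
# be constructed
find_clean_host_pos <- function(host_seq, tg_seq, hlen, tlen,
                                start = 1000L) {
  p <- start
  repeat {
    if (substr(host_seq, p + hlen + 1L, p + hlen + 1L) !=
        substr(tg_seq, 1L, 1L))
      return(p)
    p <- p + 1L
  }
}

# small complete pipeline fixture reused across tests (cached per session)
.toy_cache <- new.env()
toy_pipeline <- function() {
  if (!is.null(.toy_cache$res)) return(.toy_cache$res)
  tg <- toy_transgene()
  plan <- insertion_plan(rep("chr1", 2L), c(3000L, 6500L),
                         strand = c("+", "-"))
  gs <- make_genome_with_insertions(10000L, 1L, tg, plan, seed = 5L)
  rp <- simulate_reads(gs$inserted,
                       read_sim_config(coverage_x = 12,
                                       per_base_error_rate = 0, seed = 6L))
  res <- run_insertion_pipeline(rp, gs$clean, tg)
  out <- list(tg = tg, gs = gs, rp = rp, res = res)
  .toy_cache$res <- out
  out
}
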