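# Split-read / discordant-pair evidence extraction against the dual
# reference (host contigs + transgene). Alignment is ungapped
# seed-and-extend (substitutions only) over an exact k-mer index; the
# junction filter applies the minimum-overhang retention rule on both the
# host and the transgene side of every chimeric read.

#' Evidence-calling settings
#'
#' `min_overhang_bp` is the retention rule for chimeric reads: a junction
#' is kept only when at least this many bases align to the host and to the
#' transgene (default 20). `insert_mean_bp`/`insert_sd_bp` window the host
#' interval implied by a discordant pair.
#'
#' @param min_overhang_bp minimum aligned bases on each side of a junction.
#' @param seed_kmer k-mer size for the index (default 15).
#' @param max_mismatch_per_segment substitution budget per aligned segment.
#' @param insert_mean_bp,insert_sd_bp library insert-size model.
#' @param max_gap_bp tolerated unaligned (untemplated) bases between the
#'   two partner segments on a read.
#' @param max_candidates_per_side reads with more end-anchored candidate
#'   placements than this are dropped as ambiguous.
#' @return a `chimera_config` list.
#' @export
chimera_config <- function(min_overhang_bp = 20L, seed_kmer = 15L,
                           max_mismatch_per_segment = 2L,
                           insert_mean_bp = 350, insert_sd_bp = 50,
                           max_gap_bp = 2L, max_candidates_per_side = 4L) {
  if (min_overhang_bp < 1L) stop("config error: min_overhang_bp >= 1", call. = FALSE)
  if (max_mismatch_per_segment < 0L) stop("config error: max_mismatch >= 0", call. = FALSE)
  structure(list(min_overhang_bp = as.integer(min_overhang_bp),
                 seed_kmer = as.integer(seed_kmer),
                 max_mismatch_per_segment = as.integer(max_mismatch_per_segment),
                 insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
                 max_gap_bp = as.integer(max_gap_bp),
                 max_candidates_per_side = as.integer(max_candidates_per_side)),
            class = "chimera_config")
}

#' Build an exact k-mer index over host + transgene
#'
#' Host contigs are indexed first, then the transgene, so equal-scoring
#' placements break ties toward the host and then the lowest coordinate.
#'
#' @param host a `host_genome` (the clean reference).
#' @param transgene a `transgene_construct`.
#' @param k k-mer size (>= 8, no longer than the shortest reference).
#' @return a `kmer_index`.
#' @export
build_index <- function(host, transgene, k = 15L) {
  stopifnot(inherits(host, "host_genome"),
            inherits(transgene, "transgene_construct"))
  refs <- c(host$sequences, structure(transgene$sequence,
                                      names = transgene$name))
  if (anyDuplicated(names(refs)))
    stop("config error: transgene name clashes with a host contig", call. = FALSE)
  ptr <- .cpp_build_index(refs, as.integer(k))
  info <- .cpp_index_info(ptr)
  structure(list(ptr = ptr, k = as.integer(k),
                 ref_names = info$names, ref_lengths = info$lengths,
                 ref_seqs = refs, transgene_ref = transgene$name),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d reference(s) (%s bp), transgene '%s'\n",
              x$k, length(x$ref_names),
              format(sum(x$ref_lengths), big.mark = ","), x$transgene_ref))
  invisible(x)
}

#' Exact-match k-mer lookup
#'
#' Returns all occurrences of `kmer` across the indexed references,
#' including reverse-complement hits (reported with strand "-").
#'
#' @param index a `kmer_index`.
#' @param kmer string of length `index$k`.
#' @return data frame `ref`, `pos` (0-based), `strand`.
#' @export
query_index <- function(index, kmer) {
  hits <- .cpp_query_index(index$ptr, toupper(kmer))
  hits$ref <- index$ref_names[hits$ref]
  hits[order(hits$ref, hits$pos, hits$strand), , drop = FALSE]
}

.align_batch <- function(seqs, index, cfg) {
  res <- .cpp_align_reads(index$ptr, seqs, cfg$max_mismatch_per_segment,
                          cfg$max_candidates_per_side)
  seg <- res$segments
  seg$ref <- index$ref_names[seg$ref]
  seg$ref_end <- seg$ref_start + (seg$read_end - seg$read_start)
  seg$full_length <- seg$full_length == 1L
  attr(seg, "n_ambiguous") <- res$n_ambiguous
  attr(seg, "ambiguous_reads") <- res$ambiguous_reads
  seg
}

#' Align one read against the dual reference
#'
#' Greedy seed-and-extend, ungapped: every seed position anchors candidate
#' diagonals which are extended in both directions within the mismatch
#' budget (terminal mismatches trimmed). A full-length single-reference
#' placement suppresses split segments for the read; otherwise the maximal
#' non-redundant segment set is returned, ordered by read span.
#'
#' @param seq read sequence.
#' @param index a `kmer_index`.
#' @param cfg a `chimera_config`.
#' @return data frame of alignment segments (0-based half-open `read_start`,
#'   `read_end`, `ref_start`, `ref_end`; `strand`; `mismatches`;
#'   `full_length`). Unmappable reads give zero rows.
#' @export
align_read <- function(seq, index, cfg = chimera_config()) {
  seg <- .align_batch(seq, index, cfg)
  seg <- seg[order(seg$read_start, seg$read_end), , drop = FALSE]
  seg$read <- NULL
  rownames(seg) <- NULL
  seg
}

#' Align all mates of a read-pair set
#'
#' @param pairs a `read_pairs` data frame.
#' @param index a `kmer_index`.
#' @param cfg a `chimera_config`.
#' @return data frame of segments with `name`, `mate` (1/2) and
#'   `read_length` columns prepended; ambiguous-read counts are carried in
#'   attribute `n_ambiguous`.
#' @export
align_read_pairs <- function(pairs, index, cfg = chimera_config()) {
  s1 <- .align_batch(pairs$seq1, index, cfg)
  s2 <- .align_batch(pairs$seq2, index, cfg)
  s1$mate <- 1L; s2$mate <- 2L
  s1$read_length <- nchar(pairs$seq1)[s1$read]
  s2$read_length <- nchar(pairs$seq2)[s2$read]
  seg <- rbind(s1, s2)
  seg$name <- pairs$name[seg$read]
  seg$read <- NULL
  seg <- seg[, c("name", "mate", "read_length", "read_start", "read_end",
                 "ref", "ref_start", "ref_end", "strand", "mismatches",
                 "full_length")]
  rownames(seg) <- NULL
  attr(seg, "n_ambiguous") <- attr(s1, "n_ambiguous") + attr(s2, "n_ambiguous")
  seg
}

# canonicalize a two-segment layout so the host segment is plus-strand:
# flips read coordinates (x -> L - x) of both segments when needed.
.canonicalize <- function(h, t, L) {
  if (h$strand == "-") {
    flip <- function(s) {
      rs <- L - s$read_end; re <- L - s$read_start
      s$read_start <- rs; s$read_end <- re
      s$strand <- if (s$strand == "+") "-" else "+"
      s
    }
    h <- flip(h); t <- flip(t)
  }
  list(h = h, t = t)
}

# Resolve the exact cut point within the overlap zone [b, a] of a
# canonicalized host/transgene segment pair. The budgeted extension can
# overrun the true junction through chance matches, so the cut is re-scored
# base-by-base against both references (majority vote over the zone), then
# widened to its reference-level equivalence run (true microhomology:
# adjacent cuts are equivalent iff the host and transgene claim the same
# base) and reported at the leftmost compatible host coordinate.
.resolve_cut <- function(read_seq, h, t, b, a, host_seq, tg_seq, host_prefix) {
  L <- nchar(read_seq)
  host_base <- function(c) {
    q <- h$ref_start + (c - h$read_start)
    if (q < 0 || q >= nchar(host_seq)) return(NA_character_)
    substr(host_seq, q + 1L, q + 1L)
  }
  tg_base <- function(c) {
    if (t$strand == "+") {
      q <- t$ref_start + (c - t$read_start)
      if (q < 0 || q >= nchar(tg_seq)) return(NA_character_)
      substr(tg_seq, q + 1L, q + 1L)
    } else {
      q <- t$ref_end - 1L - (c - t$read_start)
      if (q < 0 || q >= nchar(tg_seq)) return(NA_character_)
      chartr("ACGT", "TGCA", substr(tg_seq, q + 1L, q + 1L))
    }
  }
  {
    cs <- b:a
    rb <- strsplit(substr(read_seq, b + 1L, a), "")[[1]]  # bases b..a-1
    hmatch <- vapply(seq_along(rb), function(i)
      identical(rb[i], host_base(b + i - 1L)), logical(1))
    tmatch <- vapply(seq_along(rb), function(i)
      identical(rb[i], tg_base(b + i - 1L)), logical(1))
    if (host_prefix) {
      # cut c: read [b, c) scored against host, [c, a) against transgene
      pre <- c(0L, cumsum(hmatch)); suf <- c(rev(cumsum(rev(tmatch))), 0L)
    } else {
      # cut c: read [b, c) against transgene, [c, a) against host
      pre <- c(0L, cumsum(tmatch)); suf <- c(rev(cumsum(rev(hmatch))), 0L)
    }
    score <- pre + suf
    cstar <- cs[which.max(score)]
    # equivalence run: cuts c and c+1 interchangeable iff host and
    # transgene claim the same base at read position c
    eq <- vapply(seq_along(rb), function(i) {
      hb <- host_base(b + i - 1L); tb <- tg_base(b + i - 1L)
      !is.na(hb) && !is.na(tb) && hb == tb
    }, logical(1))
    cmin <- cstar
    while (cmin > b && eq[cmin - b]) cmin <- cmin - 1L
    cmax <- cstar
    while (cmax < a && eq[cmax - b + 1L]) cmax <- cmax + 1L
    attr(cmin, "mh") <- cmax - cmin
  }
  cmin
}

#' Extract split-read junctions from per-read segments
#'
#' A junction is emitted when one host segment and one transgene segment
#' partition a read end-to-end, with up to `max_gap_bp` untemplated bases
#' or any overlap (microhomology) at the join. Junctions with less than
#' `min_overhang_bp` aligned on either side are discarded. With
#' microhomology the host breakpoint is placed at the leftmost compatible
#' host coordinate; when read sequences are supplied the cut is re-scored
#' against both references so that chance matches beyond the true junction
#' do not shift the breakpoint.
#'
#' @param segments output of [align_read_pairs()].
#' @param index the `kmer_index` the segments came from.
#' @param cfg a `chimera_config`.
#' @param pairs optional `read_pairs` data frame the segments were derived
#'   from; enables reference-based breakpoint refinement.
#' @return data frame of junctions: `name`, `mate`, `host_contig`,
#'   `host_bp` (0-based), `side` ("left" if the host occupies the read
#'   prefix after canonicalization), `tg_orient`, `tg_bp`, `host_overhang`,
#'   `tg_overhang`, `microhomology`, `gap_bp`, `mismatches`.
#' @export
find_split_junctions <- function(segments, index, cfg = chimera_config(),
                                 pairs = NULL) {
  tg <- index$transgene_ref
  empty <- data.frame(name = character(0), mate = integer(0),
                      host_contig = character(0), host_bp = integer(0),
                      side = character(0), tg_orient = character(0),
                      tg_bp = integer(0), host_overhang = integer(0),
                      tg_overhang = integer(0), microhomology = integer(0),
                      gap_bp = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(segments)) return(empty)
  key <- paste(segments$name, segments$mate)
  is_tg <- segments$ref == tg
  full_keys <- unique(key[segments$full_length])
  cand <- intersect(setdiff(unique(key[is_tg]), full_keys),
                    unique(key[!is_tg]))
  if (!length(cand)) return(empty)
  seg_sub <- segments[key %in% cand, , drop = FALSE]
  seq_lookup <- NULL
  if (!is.null(pairs)) {
    seq_lookup <- c(structure(pairs$seq1, names = paste(pairs$name, 1L)),
                    structure(pairs$seq2, names = paste(pairs$name, 2L)))
    seq_lookup <- seq_lookup[names(seq_lookup) %in% cand]
  }
  tg_seq <- index$ref_seqs[[tg]]
  out <- vector("list", length(cand))
  groups <- split(seq_len(nrow(seg_sub)), paste(seg_sub$name, seg_sub$mate))
  ji <- 0L
  for (g in groups) {
    gs <- seg_sub[g, , drop = FALSE]
    L <- gs$read_length[1]
    hosts <- which(gs$ref != tg)
    tgs <- which(gs$ref == tg)
    best <- NULL
    for (hi in hosts) for (ti in tgs) {
      h <- as.list(gs[hi, ]); t <- as.list(gs[ti, ])
      # must jointly reach both read ends
      if (min(h$read_start, t$read_start) != 0L) next
      if (max(h$read_end, t$read_end) != L) next
      host_prefix <- h$read_start <= t$read_start
      if (host_prefix && (h$read_start != 0L || t$read_end != L)) next
      if (!host_prefix && (t$read_start != 0L || h$read_end != L)) next
      a <- if (host_prefix) h$read_end else t$read_end
      b <- if (host_prefix) t$read_start else h$read_start
      gap <- max(0L, b - a)
      if (gap > cfg$max_gap_bp) next
      score <- (h$read_end - h$read_start) + (t$read_end - t$read_start) -
        (h$mismatches + t$mismatches)
      if (is.null(best) || score > best$score)
        best <- list(h = h, t = t, gap = gap, mh = max(0L, a - b),
                     host_prefix = host_prefix, score = score)
    }
    if (is.null(best)) next
    flipped <- best$h$strand == "-"
    can <- .canonicalize(best$h, best$t, L)
    h <- can$h; t <- can$t
    host_prefix <- h$read_start <= t$read_start
    h_len <- h$read_end - h$read_start
    t_len <- t$read_end - t$read_start
    if (h_len < cfg$min_overhang_bp || t_len < cfg$min_overhang_bp) next
    # overlap zone [b, a]: suffix-segment start to prefix-segment end
    if (host_prefix) { b <- t$read_start; a <- h$read_end }
    else             { b <- h$read_start; a <- t$read_end }
    mh <- max(0L, a - b)
    if (b < a) {
      cut_host <- cut_tg <- b  # raw leftmost convention
      if (!is.null(seq_lookup)) {
        rd <- seq_lookup[[paste(h$name, h$mate)]]
        if (flipped) rd <- revcomp(rd)
        cut <- .resolve_cut(rd, h, t, b, a, index$ref_seqs[[h$ref]], tg_seq,
                            host_prefix)
        mh <- attr(cut, "mh")
        cut_host <- cut_tg <- as.integer(cut)
      }
    } else {
      cut_host <- if (host_prefix) a else b
      cut_tg <- if (host_prefix) b else a
    }
    host_bp <- h$ref_start + (cut_host - h$read_start)
    tg_bp <- if (t$strand == "+") t$ref_start + (cut_tg - t$read_start)
             else t$ref_end - (cut_tg - t$read_start)
    ji <- ji + 1L
    out[[ji]] <- data.frame(
      name = h$name, mate = h$mate, host_contig = h$ref,
      host_bp = as.integer(host_bp),
      side = if (host_prefix) "left" else "right",
      tg_orient = if (t$strand == h$strand) "+" else "-",
      tg_bp = as.integer(tg_bp), host_overhang = h_len, tg_overhang = t_len,
      microhomology = as.integer(mh), gap_bp = best$gap,
      mismatches = h$mismatches + t$mismatches, stringsAsFactors = FALSE)
  }
  if (!ji) return(empty)
  res <- do.call(rbind, out[seq_len(ji)])
  res <- res[order(res$host_contig, res$host_bp, res$name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract discordant read pairs
#'
#' A pair qualifies when one mate maps full-length to the transgene and the
#' other full-length to a host contig. The implied host interval extends
#' from the host mate toward its mate-facing side by
#' `insert_mean + 3 * insert_sd - read_length`.
#'
#' @param segments output of [align_read_pairs()].
#' @param index the `kmer_index`.
#' @param cfg a `chimera_config`.
#' @return data frame: `name`, `host_contig`, `interval_lo`, `interval_hi`
#'   (0-based half-open), `host_strand`, `tg_start`, `tg_strand`.
#' @export
find_discordant_pairs <- function(segments, index, cfg = chimera_config()) {
  tg <- index$transgene_ref
  empty <- data.frame(name = character(0), host_contig = character(0),
                      interval_lo = numeric(0), interval_hi = numeric(0),
                      host_strand = character(0), tg_start = numeric(0),
                      tg_strand = character(0), stringsAsFactors = FALSE)
  fl <- segments[segments$full_length, , drop = FALSE]
  if (!nrow(fl)) return(empty)
  m1 <- fl[fl$mate == 1L, , drop = FALSE]
  m2 <- fl[fl$mate == 2L, , drop = FALSE]
  common <- intersect(m1$name, m2$name)
  m1 <- m1[match(common, m1$name), , drop = FALSE]
  m2 <- m2[match(common, m2$name), , drop = FALSE]
  tg1 <- m1$ref == tg
  tg2 <- m2$ref == tg
  disc <- xor(tg1, tg2)
  if (!any(disc)) return(empty)
  hm <- rbind(m1[disc & !tg1, , drop = FALSE], m2[disc & !tg2, , drop = FALSE])
  tm <- rbind(m2[disc & !tg1, , drop = FALSE], m1[disc & !tg2, , drop = FALSE])
  D <- cfg$insert_mean_bp + 3 * cfg$insert_sd_bp - hm$read_length
  lo <- ifelse(hm$strand == "+", hm$ref_end, hm$ref_start - D)
  hi <- ifelse(hm$strand == "+", hm$ref_end + D, hm$ref_start)
  out <- data.frame(name = hm$name, host_contig = hm$ref,
                    interval_lo = pmax(0, lo), interval_hi = hi,
                    host_strand = hm$strand, tg_start = tm$ref_start,
                    tg_strand = tm$strand, stringsAsFactors = FALSE)
  out <- out[order(out$host_contig, out$interval_lo, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
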