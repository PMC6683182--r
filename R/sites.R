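# Clustering of junction evidence into insertion sites. One biological
# insertion produces two junction classes (the head and tail of the
# cassette); clusters of complementary class within the window are merged
# into a single site carrying both transgene breakpoints.

#' Site-calling settings
#'
#' @param cluster_window_bp single-linkage window for joining junction
#'   breakpoints (default 10).
#' @param min_split_support minimum split reads for a site to survive on
#'   split evidence alone (default 2).
#' @param min_disc_support minimum discordant pairs for a discordant-only
#'   site (default 2).
#' @return a `site_call_config` list.
#' @export
site_call_config <- function(cluster_window_bp = 10L, min_split_support = 2L,
                             min_disc_support = 2L) {
  if (cluster_window_bp < 0L) stop("config error: window >= 0", call. = FALSE)
  if (min_split_support < 1L || min_disc_support < 1L)
    stop("config error: support thresholds >= 1", call. = FALSE)
  structure(list(cluster_window_bp = as.integer(cluster_window_bp),
                 min_split_support = as.integer(min_split_support),
                 min_disc_support = as.integer(min_disc_support)),
            class = "site_call_config")
}

# lower of the two middles for even counts
.median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

# single-linkage grouping of sorted positions: new group when the gap to
# the previous position exceeds the window
.link_groups <- function(pos, window) {
  o <- order(pos)
  p <- pos[o]
  grp <- cumsum(c(1L, as.integer(diff(p) > window)))
  grp[order(o)]
}

#' Cluster split-read junctions into provisional sites
#'
#' Single-linkage per (contig, junction class): junctions whose host
#' breakpoints differ by at most `cluster_window_bp` join one cluster.
#' Complementary-class clusters within the window are then merged, since
#' the head and tail junction of one insertion share a coordinate. Site
#' position is the median member breakpoint (lower of two middles for even
#' counts); total membership is conserved.
#'
#' @param junctions output of [find_split_junctions()].
#' @param cfg a `site_call_config`.
#' @return `provisional_sites` data frame: `contig`, `position`,
#'   `split_support`, `sides`, `tg_orient`, `tg_breakpoints` (semicolon
#'   list of distinct member transgene coordinates).
#' @export
cluster_junctions <- function(junctions, cfg = site_call_config()) {
  empty <- data.frame(contig = character(0), position = integer(0),
                      split_support = integer(0), sides = character(0),
                      tg_orient = character(0), tg_breakpoints = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("provisional_sites", "data.frame")
  if (is.null(junctions) || !nrow(junctions)) return(empty)
  w <- cfg$cluster_window_bp
  out <- list()
  for (ctg in unique(junctions$host_contig)) {
    jc <- junctions[junctions$host_contig == ctg, , drop = FALSE]
    # per-junction insertion-point estimate: head ("left") junctions place
    # the leftmost compatible cut at the insertion point itself, tail
    # ("right") junctions at insertion point minus the microhomology, so
    # the tail estimate is corrected by +microhomology and both classes of
    # one insertion share a coordinate
    mh <- if ("microhomology" %in% names(jc)) jc$microhomology else 0L
    est <- jc$host_bp + ifelse(jc$side == "right", mh, 0L)
    # single linkage over all junction estimates; junctions of the same
    # class within the window join automatically, and complementary-class
    # junctions at the shared coordinate merge into one site
    g <- .link_groups(est, w)
    for (gi in unique(g)) {
      members <- which(g == gi)
      bps <- est[members]
      orient <- unique(jc$tg_orient[members])
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, position = as.integer(.median_lower(bps)),
        split_support = length(members),
        sides = paste(sort(unique(jc$side[members])), collapse = "+"),
        tg_orient = if (length(orient) == 1L) orient else ".",
        tg_breakpoints = paste(sort(unique(jc$tg_bp[members])), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$position), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("provisional_sites", "data.frame")
  res
}

#' Corroborate provisional sites with discordant-pair evidence
#'
#' Each discordant pair is assigned to the nearest provisional site whose
#' position lies inside the pair's implied host interval (extended by the
#' cluster window on the right). Unassignable pairs may found
#' discordant-only sites when at least `min_disc_support` of them overlap.
#' Sites below both support thresholds are dropped (retained in attribute
#' `"dropped"` for accounting); `corroborated` is true when both evidence
#' classes are present.
#'
#' @param provisional output of [cluster_junctions()].
#' @param pairs output of [find_discordant_pairs()].
#' @param cfg a `site_call_config`.
#' @return `insertion_sites` data frame: `contig`, `position`, `tg_orient`,
#'   `split_read_support`, `discordant_support`, `corroborated`,
#'   `tg_breakpoints`.
#' @export
corroborate_sites <- function(provisional, pairs, cfg = site_call_config()) {
  w <- cfg$cluster_window_bp
  prov <- as.data.frame(provisional)
  disc <- integer(nrow(prov))
  unassigned <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    assigned <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      cand <- which(prov$contig == pairs$host_contig[i] &
                    prov$position >= pairs$interval_lo[i] - w &
                    prov$position < pairs$interval_hi[i] + w)
      if (length(cand)) {
        mid <- (pairs$interval_lo[i] + pairs$interval_hi[i]) / 2
        j <- cand[order(abs(prov$position[cand] - mid),
                        prov$position[cand])][1]
        disc[j] <- disc[j] + 1L
        assigned[i] <- TRUE
      }
    }
    unassigned <- pairs[!assigned, , drop = FALSE]
  }
  sites <- data.frame(contig = prov$contig, position = prov$position,
                      tg_orient = prov$tg_orient,
                      split_read_support = prov$split_support,
                      discordant_support = disc,
                      corroborated = prov$split_support >= 1L & disc >= 1L,
                      tg_breakpoints = prov$tg_breakpoints,
                      stringsAsFactors = FALSE)
  # discordant-only sites from clusters of unassigned pairs
  if (!is.null(unassigned) && nrow(unassigned)) {
    for (ctg in unique(unassigned$host_contig)) {
      up <- unassigned[unassigned$host_contig == ctg, , drop = FALSE]
      mid <- (up$interval_lo + up$interval_hi) / 2
      span <- max(1, max(up$interval_hi - up$interval_lo))
      g <- .link_groups(mid, span)  # overlap-scale linkage
      for (gi in unique(g)) {
        m <- which(g == gi)
        if (length(m) >= cfg$min_disc_support) {
          sites <- rbind(sites, data.frame(
            contig = ctg, position = as.integer(.median_lower(mid[m])),
            tg_orient = ".", split_read_support = 0L,
            discordant_support = length(m), corroborated = FALSE,
            tg_breakpoints = "", stringsAsFactors = FALSE))
        }
      }
    }
  }
  keep <- sites$split_read_support >= cfg$min_split_support |
    sites$discordant_support >= cfg$min_disc_support
  dropped <- sites[!keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "dropped") <- dropped
  class(sites) <- c("insertion_sites", "data.frame")
  sites
}

#' @export
print.insertion_sites <- function(x, ...) {
  cat(sprintf("<insertion_sites> %d site(s)\n", nrow(x)))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$position_1based <- df$position + 1L
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Full site-calling step: cluster then corroborate
#'
#' @param junctions output of [find_split_junctions()].
#' @param pairs output of [find_discordant_pairs()].
#' @param cfg a `site_call_config`.
#' @return `insertion_sites` data frame.
#' @export
call_insertion_sites <- function(junctions, pairs,
                                 cfg = site_call_config()) {
  corroborate_sites(cluster_junctions(junctions, cfg), pairs, cfg)
}

#' Write site outputs: BED6 and a circos-style link table
#'
#' The BED uses 0-based breakpoints and total support as score. The link
#' table has one row per site transgene breakpoint
#' (`host_contig`, `host_pos`, `transgene_name`, `transgene_pos`,
#' `support`), suitable for circos-style plotting.
#'
#' @param sites an `insertion_sites` data frame.
#' @param bed_path BED6 output path.
#' @param link_path link-table TSV output path.
#' @param transgene_name name used in the link table.
#' @return invisibly, the two paths.
#' @export
write_site_outputs <- function(sites, bed_path, link_path,
                               transgene_name = "transgene") {
  total <- sites$split_read_support + sites$discordant_support
  bed <- data.frame(contig = sites$contig, start = sites$position,
                    end = sites$position + 1L,
                    name = if (nrow(sites)) sprintf("site_%d", seq_len(nrow(sites))) else character(0),
                    score = total,
                    strand = ifelse(sites$tg_orient %in% c("+", "-"),
                                    sites$tg_orient, "."),
                    stringsAsFactors = FALSE)
  write_bed(bed, bed_path)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    tbps <- strsplit(sites$tg_breakpoints[i], ";", fixed = TRUE)[[1]]
    if (!length(tbps)) tbps <- NA_character_
    rows[[i]] <- data.frame(host_contig = sites$contig[i],
                            host_pos = sites$position[i],
                            transgene_name = transgene_name,
                            transgene_pos = tbps, support = total[i],
                            stringsAsFactors = FALSE)
  }
  link <- if (length(rows)) do.call(rbind, rows) else
    data.frame(host_contig = character(0), host_pos = integer(0),
               transgene_name = character(0), transgene_pos = character(0),
               support = integer(0), stringsAsFactors = FALSE)
  write.table(link, link_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed_path, link_path))
}

#' Run the full insertion-detection pipeline on a read set
#'
#' Builds the dual-reference index, aligns all mates, extracts split-read
#' junctions and discordant pairs, and calls corroborated insertion sites.
#'
#' @param pairs a `read_pairs` data frame.
#' @param host the clean `host_genome` reference.
#' @param transgene a `transgene_construct`.
#' @param chim_cfg a `chimera_config`.
#' @param site_cfg a `site_call_config`.
#' @return list with `index`, `segments`, `junctions`, `pairs` (discordant)
#'   and `sites`.
#' @export
run_insertion_pipeline <- function(pairs, host, transgene,
                                   chim_cfg = chimera_config(),
                                   site_cfg = site_call_config()) {
  idx <- build_index(host, transgene, k = chim_cfg$seed_kmer)
  lt_log(sprintf("aligning %d read pairs against %d reference(s)",
                 nrow(pairs), length(idx$ref_names)), level = "debug")
  seg <- align_read_pairs(pairs, idx, chim_cfg)
  jn <- find_split_junctions(seg, idx, chim_cfg, pairs = pairs)
  dp <- find_discordant_pairs(seg, idx, chim_cfg)
  sites <- call_insertion_sites(jn, dp, site_cfg)
  lt_log(sprintf("%d junction(s), %d discordant pair(s) -> %d site(s)",
                 nrow(jn), nrow(dp), nrow(sites)), level = "debug")
  list(index = idx, segments = seg, junctions = jn, pairs = dp, sites = sites)
}
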