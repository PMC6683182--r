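# In-silico PCR: primer binding-site search (mismatch budget with an exact
# 3'-terminal anchor, reflecting extension chemistry) and amplicon
# prediction from facing primer hits. No melting-temperature model:
# annealing temperatures from the primer tables are carried as metadata.

#' Construct a primer
#'
#' @param name primer (pair) name.
#' @param sequence 5'->3' ACGT sequence, length >= 10.
#' @param anneal_c intended annealing temperature (deg C, metadata).
#' @param conc_nm reaction concentration (nM, metadata).
#' @return a `primer` object.
#' @export
primer <- function(name, sequence, anneal_c = NA_real_, conc_nm = NA_real_) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 10 || !grepl("^[ACGT]+$", sequence))
    stop("invalid primer: ACGT only, length >= 10", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 anneal_c = anneal_c, conc_nm = conc_nm),
            class = "primer")
}

#' Read a primer-pair table
#'
#' TSV with columns `name`, `seq_fwd`, `seq_rev`, `anneal_C`, `conc_nM`,
#' `expected_bp`. The packaged tables `primers_standard_pcr.tsv` and
#' `primers_qpcr.tsv` carry the published reporter-validation primer pairs
#' with their annealing temperatures, concentrations and expected amplicon
#' sizes.
#'
#' @param path TSV path.
#' @return data frame of primer pairs.
#' @export
read_primer_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "seq_fwd", "seq_rev")
  if (!all(need %in% names(df)))
    stop("primer table must have columns name, seq_fwd, seq_rev", call. = FALSE)
  df
}

# mismatch counts of `p` against every window of `chars`; N never matches
.window_mismatches <- function(p, chars) {
  k <- nchar(p)
  n <- length(chars) - k + 1L
  if (n < 1L) return(integer(0))
  pj <- strsplit(p, "")[[1]]
  mm <- integer(n)
  for (j in seq_len(k))
    mm <- mm + (chars[j:(n + j - 1L)] != pj[j])
  mm
}

.scan_plus <- function(p, chars, max_mismatch, three_prime_exact) {
  k <- nchar(p)
  mm <- .window_mismatches(p, chars)
  if (!length(mm)) return(data.frame(pos = integer(0), mismatches = integer(0)))
  ok <- mm <= max_mismatch
  if (three_prime_exact > 0L && any(ok)) {
    tpe <- min(three_prime_exact, k)
    p3 <- substring(p, k - tpe + 1L, k)
    mm3 <- .window_mismatches(p3, chars)
    # 3' end of a plus-strand hit at pos i sits at window i + k - tpe
    idx <- which(ok)
    ok[idx] <- mm3[idx + (k - tpe)] == 0L
  }
  data.frame(pos = which(ok) - 1L, mismatches = mm[ok],
             stringsAsFactors = FALSE)
}

#' Find primer binding sites on a template
#'
#' Plus-strand hits are windows matching the primer with at most
#' `max_mismatch` substitutions and zero mismatches in the 3'-terminal
#' `three_prime_exact` bases; minus-strand hits are computed on the
#' reverse complement and reported in plus-strand coordinates (`pos` is
#' the leftmost base of the binding footprint).
#'
#' @param pr a `primer` (or bare sequence string).
#' @param template template sequence (ACGT; N tolerated, never matches).
#' @param max_mismatch substitution budget (default 0).
#' @param three_prime_exact number of 3'-terminal bases that must match
#'   exactly (default 3).
#' @return data frame `pos` (0-based), `strand`, `mismatches`, sorted by
#'   position. Empty when the primer is longer than the template.
#' @export
find_binding_sites <- function(pr, template, max_mismatch = 0L,
                               three_prime_exact = 3L) {
  if (is.character(pr)) pr <- primer("primer", pr)
  template <- toupper(template)
  p <- pr$sequence
  k <- nchar(p)
  tl <- nchar(template)
  empty <- data.frame(pos = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (k > tl) return(empty)
  chars <- strsplit(template, "")[[1]]
  plus <- .scan_plus(p, chars, max_mismatch, three_prime_exact)
  rchars <- strsplit(revcomp(template), "")[[1]]
  minus <- .scan_plus(p, rchars, max_mismatch, three_prime_exact)
  out <- rbind(
    if (nrow(plus)) data.frame(pos = plus$pos, strand = "+",
                               mismatches = plus$mismatches,
                               stringsAsFactors = FALSE),
    if (nrow(minus)) data.frame(pos = tl - minus$pos - k, strand = "-",
                                mismatches = minus$mismatches,
                                stringsAsFactors = FALSE))
  if (is.null(out)) return(empty)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict amplicons for a facing primer pair
#'
#' For every plus-strand forward hit and every minus-strand reverse hit
#' downstream of it within `max_len`, emits one amplicon spanning from the
#' forward primer's 5' end to the plus-strand position of the reverse
#' primer's 5' end (exclusive).
#'
#' @param fwd,rev `primer` objects (or bare sequences).
#' @param template template sequence, optionally named (name used in
#'   output).
#' @param max_len maximum amplicon length reported (default 5000).
#' @param max_mismatch,three_prime_exact binding-site rules, see
#'   [find_binding_sites()].
#' @return data frame `template`, `start`, `end` (0-based half-open),
#'   `length_bp`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   (template, start, length).
#' @export
predict_amplicons <- function(fwd, rev, template, max_len = 5000L,
                              max_mismatch = 0L, three_prime_exact = 3L) {
  if (is.character(fwd)) fwd <- primer("fwd", fwd)
  if (is.character(rev)) rev <- primer("rev", rev)
  tname <- if (!is.null(names(template))) names(template)[1] else "template"
  template <- unname(template[1])
  fh <- find_binding_sites(fwd, template, max_mismatch, three_prime_exact)
  rh <- find_binding_sites(rev, template, max_mismatch, three_prime_exact)
  lf <- nchar(fwd$sequence); lr <- nchar(rev$sequence)
  out <- list()
  # a primer pair amplifies in either written orientation: fwd on plus
  # facing rev on minus, or rev on plus facing fwd on minus
  enumerate <- function(left, llen, right, rlen, swap) {
    left <- left[left$strand == "+", , drop = FALSE]
    right <- right[right$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
      s <- left$pos[i]
      e <- right$pos[j] + rlen   # right primer 5' end, plus-strand exclusive
      len <- e - s
      if (len < llen + rlen || len > max_len) next
      out[[length(out) + 1L]] <<- data.frame(
        template = tname, start = s, end = e, length_bp = len,
        fwd_mismatches = if (swap) right$mismatches[j] else left$mismatches[i],
        rev_mismatches = if (swap) left$mismatches[i] else right$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  enumerate(fh, lf, rh, lr, swap = FALSE)
  enumerate(rh, lr, fh, lf, swap = TRUE)
  if (!length(out))
    return(data.frame(template = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  res <- res[order(res$template, res$start, res$length_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}
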