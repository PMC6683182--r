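# Reporter calibration and stability statistics: bioluminescence-per-cell
# slopes (OLS with intercept), DNA-normalized mono- vs co-culture fold
# change with a Welch test on log-normalized signal, and delta-delta-Ct
# relative expression against a housekeeping gene.

#' Fit a bioluminescence-per-cell calibration line
#'
#' Ordinary least squares of RLU on seeded cell number, with intercept.
#' `slope_sd` is the standard error of the slope.
#'
#' @param cells seeded cell numbers, or a data frame with columns
#'   `cells_seeded` and `RLU`.
#' @param rlu RLU measurements (omit when `cells` is a data frame).
#' @return a `calibration_fit` with `slope`, `slope_sd`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_calibration <- function(cells, rlu = NULL) {
  if (is.data.frame(cells)) {
    stopifnot(all(c("cells_seeded", "RLU") %in% names(cells)))
    rlu <- cells$RLU
    cells <- cells$cells_seeded
  }
  if (length(unique(cells)) < 3)
    stop("insufficient-data error: need >= 3 distinct cell counts",
         call. = FALSE)
  fit <- lm(rlu ~ cells)
  # noiseless titrations are a legitimate input (exact-recovery checks);
  # keep summary.lm quiet about the perfect fit
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(slope = unname(coef(fit)[2]),
                 slope_sd = unname(sm$coefficients[2, 2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_points = length(cells), fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.4g +/- %.4g RLU/cell, intercept %.4g, r^2 %.4f, n = %d\n",
              x$slope, x$slope_sd, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, cells, ...) {
  object$intercept + object$slope * cells
}

#' Ratio of two calibration slopes (relative per-cell intensity)
#'
#' @param a,b `calibration_fit` objects.
#' @return `a$slope / b$slope`.
#' @export
slope_ratio <- function(a, b) {
  stopifnot(inherits(a, "calibration_fit"), inherits(b, "calibration_fit"))
  if (b$slope <= 0)
    stop("degenerate-input error: nonpositive denominator slope", call. = FALSE)
  a$slope / b$slope
}

#' Assess reporter stability between mono- and co-culture arms
#'
#' Fold changes are ratios of arm means; the DNA-normalized fold
#' (`fold_change_rlu / fold_change_dna`) removes cell-number differences.
#' The p-value is a Welch unequal-variance t-test on per-replicate
#' `log(RLU / DNA)`. Verdict is "unstable" only when the normalized fold
#' is outside `[1/threshold, threshold]` and `p < alpha`; a reporter whose
#' normalized signal moves less than `threshold`-fold is called stable
#' regardless of significance.
#'
#' @param mono,cocult data frames with columns `RLU` and `DNA`, one row
#'   per replicate (>= 2 each), at a matched time point and cell number.
#' @param threshold fold-change threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @return a `stability_report`: `fold_change_rlu`, `fold_change_dna`,
#'   `normalized_fold`, `p_value`, `verdict`.
#' @export
assess_stability <- function(mono, cocult, threshold = 2, alpha = 0.05) {
  stopifnot(all(c("RLU", "DNA") %in% names(mono)),
            all(c("RLU", "DNA") %in% names(cocult)))
  if (nrow(mono) < 2 || nrow(cocult) < 2)
    stop("insufficient-data error: need >= 2 replicates per arm", call. = FALSE)
  if (mean(mono$RLU) <= 0 || mean(mono$DNA) <= 0 || mean(cocult$DNA) <= 0)
    stop("degenerate-input error: nonpositive arm mean", call. = FALSE)
  fr <- mean(cocult$RLU) / mean(mono$RLU)
  fd <- mean(cocult$DNA) / mean(mono$DNA)
  nf <- fr / fd
  tt <- t.test(log(cocult$RLU / cocult$DNA), log(mono$RLU / mono$DNA),
               var.equal = FALSE)
  verdict <- if ((nf > threshold || nf < 1 / threshold) &&
                 tt$p.value < alpha) "unstable" else "stable"
  structure(list(fold_change_rlu = fr, fold_change_dna = fd,
                 normalized_fold = nf, p_value = tt$p.value,
                 verdict = verdict, threshold = threshold, alpha = alpha),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> RLU fold %.2f, DNA fold %.2f, normalized %.2f (p = %.3g) -> %s\n",
              x$fold_change_rlu, x$fold_change_dna, x$normalized_fold,
              x$p_value, x$verdict))
  invisible(x)
}

#' Delta-delta-Ct relative expression
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; then
#' `ddCt = mean(dCt_treated) - mean(dCt_control)` and the returned fold
#' expression is `2^(-ddCt)`.
#'
#' @param treated,control data frames with columns `ct_target` and
#'   `ct_housekeeping`, one row per sample; all Ct values must lie in
#'   (0, 45).
#' @return fold expression (bare numeric).
#' @export
delta_delta_ct <- function(treated, control) {
  chk <- function(df, arm) {
    stopifnot(all(c("ct_target", "ct_housekeeping") %in% names(df)))
    if (nrow(df) < 1)
      stop("insufficient-data error: empty ", arm, " arm", call. = FALSE)
    ct <- c(df$ct_target, df$ct_housekeeping)
    if (any(ct <= 0 | ct >= 45))
      stop("invalid-measurement error: Ct outside (0, 45)", call. = FALSE)
  }
  chk(treated, "treated"); chk(control, "control")
  ddct <- mean(treated$ct_target - treated$ct_housekeeping) -
    mean(control$ct_target - control$ct_housekeeping)
  2^(-ddct)
}
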