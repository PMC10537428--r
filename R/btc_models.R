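# Linearized breakthrough-curve models: Bohart-Adams, Thomas, Yoon-Nelson,
# single-depth BDST, plus multi-depth BDST scale-up, error statistics and
# model ranking.
#
# Linearizations (c = C_t/C0, v = F/A in cm/min, Z in cm):
#   Bohart-Adams : ln c            =  k_BA C0 t - k_BA N_o Z / v
#   Thomas       : ln(1/c - 1)     =  k_T q_e W / F - k_T C0 t
#   Yoon-Nelson  : ln(c/(1 - c))   =  k_YN t - k_YN t_05
#   BDST         : t = Q_o Z/(C0 v) - (1/(k_BDST C0)) ln(1/c - 1)
# Thomas and Yoon-Nelson regress the same response up to sign, and BDST is
# the inverse regression of the same line, so on shared data the three R^2
# coincide exactly; the fitted parameters differ once R^2 < 1 because the
# inverse regression has slope r^2/b.
#
# Percent error E compares each model's capacity/midpoint parameter with its
# experimental counterpart: q_e vs the integral EBC, t_05 vs the observed
# midpoint crossing, N_o and Q_o vs EBC W / V_M.

# equilibrium capacity: uptake integral at the last exhausted sample
.ebc <- function(curve) {
  kin <- to_kinetic_curve(curve)
  idx <- which(curve$c_ratio >= 0.99)
  kin$q_t[if (length(idx)) idx[length(idx)] else length(kin$q_t)]
}

.new_btc_fit <- function(model, params, r2, E_pct, n_used, n_dropped,
                         experimental) {
  structure(list(model = model, params = params, r2 = r2, E_pct = E_pct,
                 n_used = n_used, n_dropped = n_dropped,
                 experimental = experimental),
            class = "btc_fit")
}

#' @export
print.btc_fit <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("Breakthrough-model fit: %s  (R2 = %.4f, E = %.3f%%, n = %d)\n",
              x$model, x$r2, x$E_pct, x$n_used))
  cat("  ", paste(names(p), signif(p, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# points of the curve usable inside a c_ratio window, with a guard on how
# the logarithms are taken
.window_points <- function(curve, window, open_unit) {
  cr <- curve$c_ratio
  use <- cr > window[1L] & cr < window[2L]
  if (open_unit) use <- use & cr < 1
  use <- use & cr > 0
  use
}

#' Fit the Bohart-Adams model to a breakthrough curve
#'
#' OLS of `ln(c_ratio)` on `t`; slope = `k_BA C0`, intercept =
#' `-k_BA N_o Z / v`.  By default the whole available front is used
#' (`window = c(0.001, 0.999)`), which is what gives this early-front model
#' its characteristically poor fit on full sigmoidal data; restrict the
#' window (e.g. `c(0.001, 0.15)`) for a faithful early-front fit.
#'
#' @param curve a [breakthrough_curve()].
#' @param window inclusive c_ratio range of points entering the regression.
#' @return a `btc_fit` with params `k_BA` (mL/(mg min)) and `N_o` (mg/mL),
#'   the regression `r2`, percent error `E_pct` of `N_o` against the
#'   experimental `EBC W / V_M`, and point counts.
#' @export
fit_bohart_adams <- function(curve, window = c(0.001, 0.999)) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  use <- .window_points(curve, window, open_unit = FALSE)
  if (sum(use) < 3L)
    stop("insufficient data for Bohart-Adams fit: ", sum(use),
         " points in window")
  o <- .ols(curve$t[use], log(curve$c_ratio[use]))
  if (o$slope <= 0)
    stop("degenerate Bohart-Adams fit: non-positive slope")
  v <- curve$F / curve$bed$A                  # cm/min
  Zcm <- curve$bed$Z / UM_PER_CM
  k_BA <- o$slope / curve$C0
  N_o <- -o$intercept * v / (k_BA * Zcm)
  N_o_exp <- .ebc(curve) * curve$bed$W / curve$bed$V_M
  .new_btc_fit("bohart_adams", list(k_BA = k_BA, N_o = N_o), o$r2,
               error_percent(N_o_exp, N_o), o$n, sum(!use),
               experimental = list(N_o_exp = N_o_exp))
}

#' Fit the Thomas model to a breakthrough curve
#'
#' OLS of `ln(C0/C_t - 1)` on `t`; slope = `-k_T C0`, intercept =
#' `k_T q_e W / F`.
#'
#' @inheritParams fit_bohart_adams
#' @return a `btc_fit` with params `k_T` (mL/(mg min)) and `q_e` (mg/g);
#'   `E_pct` compares `q_e` with the integral EBC.
#' @export
fit_thomas <- function(curve, window = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  use <- .window_points(curve, window, open_unit = TRUE)
  if (sum(use) < 3L)
    stop("insufficient data for Thomas fit: ", sum(use), " points in window")
  cr <- curve$c_ratio[use]
  o <- .ols(curve$t[use], log(1 / cr - 1))
  if (o$slope >= 0)
    stop("degenerate Thomas fit: non-negative slope")
  k_T <- -o$slope / curve$C0
  q_e <- o$intercept * curve$F / (k_T * curve$bed$W)
  q_exp <- .ebc(curve)
  .new_btc_fit("thomas", list(k_T = k_T, q_e = q_e), o$r2,
               error_percent(q_exp, q_e), o$n, sum(!use),
               experimental = list(q_e_exp = q_exp))
}

#' Fit the Yoon-Nelson model to a breakthrough curve
#'
#' OLS of `ln(C_t/(C0 - C_t))` on `t`; slope = `k_YN`, intercept =
#' `-k_YN t_05`.
#'
#' @inheritParams fit_bohart_adams
#' @return a `btc_fit` with params `k_YN` (1/min) and `t_05` (min);
#'   `E_pct` compares `t_05` with the observed 50% crossing time.
#' @export
fit_yoon_nelson <- function(curve, window = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  use <- .window_points(curve, window, open_unit = TRUE)
  if (sum(use) < 3L)
    stop("insufficient data for Yoon-Nelson fit: ", sum(use),
         " points in window")
  cr <- curve$c_ratio[use]
  o <- .ols(curve$t[use], log(cr / (1 - cr)))
  if (o$slope <= 0)
    stop("degenerate Yoon-Nelson fit: non-positive slope")
  t_05 <- -o$intercept / o$slope
  t_05_exp <- breakthrough_time(curve, 0.5)
  .new_btc_fit("yoon_nelson", list(k_YN = o$slope, t_05 = t_05), o$r2,
               error_percent(t_05_exp, t_05), o$n, sum(!use),
               experimental = list(t_05_exp = t_05_exp))
}

#' Fit the single-depth BDST model to a breakthrough curve
#'
#' The bed-depth/service-time form regresses service time on
#' `ln(C0/C_t - 1)`: slope = `-1/(k_BDST C0)`, intercept = `Q_o Z/(C0 v)`.
#' This is the inverse regression of the Thomas line, so its R^2 equals the
#' Thomas/Yoon-Nelson R^2 exactly, while the parameters differ on noisy
#' data.
#'
#' @inheritParams fit_bohart_adams
#' @return a `btc_fit` with params `k_BDST` (mL/(mg min)) and `Q_o` (mg/mL
#'   of bed); `E_pct` compares `Q_o` with the experimental `EBC W / V_M`.
#' @export
fit_bdst <- function(curve, window = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  use <- .window_points(curve, window, open_unit = TRUE)
  if (sum(use) < 3L)
    stop("insufficient data for BDST fit: ", sum(use), " points in window")
  cr <- curve$c_ratio[use]
  o <- .ols(log(1 / cr - 1), curve$t[use])
  if (o$slope >= 0)
    stop("degenerate BDST fit: non-negative slope")
  v <- curve$F / curve$bed$A
  Zcm <- curve$bed$Z / UM_PER_CM
  k_BDST <- -1 / (o$slope * curve$C0)
  Q_o <- o$intercept * curve$C0 * v / Zcm
  Q_o_exp <- .ebc(curve) * curve$bed$W / curve$bed$V_M
  .new_btc_fit("bdst", list(k_BDST = k_BDST, Q_o = Q_o), o$r2,
               error_percent(Q_o_exp, Q_o), o$n, sum(!use),
               experimental = list(Q_o_exp = Q_o_exp))
}

#' BDST scale-up across bed depths
#'
#' Regresses the service time at a target breakthrough fraction on bed
#' height Z across beds that differ only in depth, yielding the BDST line
#' `t = a Z + b` used for column scale-up.  Accepts either fitted curves
#' (each a [breakthrough_curve()]) or a precomputed data frame of
#' `(Z, t)` pairs.
#'
#' @param curves list of >= 2 [breakthrough_curve()] at different depths.
#' @param target_fraction breakthrough fraction defining the service time,
#'   default 0.1.
#' @return list with `a` (slope, min/um), `b` (intercept, min), `r2`,
#'   `k_BDST` (from the intercept via
#'   `b = -(1/(k_BDST C0)) ln(C0/C_t - 1)`), `Q_o` (from the slope via
#'   `a = Q_o/(C0 v)` per cm of bed), and `predict(Z)` giving the service
#'   time at a new depth (um).
#' @export
bdst_scaleup <- function(curves, target_fraction = 0.1) {
  if (length(curves) < 2L)
    stop("insufficient data: BDST scale-up needs >= 2 bed depths")
  stopifnot(all(vapply(curves, inherits, TRUE, "breakthrough_curve")))
  Z <- vapply(curves, function(cv) cv$bed$Z, 0)
  if (length(unique(Z)) < 2L)
    stop("degenerate regression: all beds have the same depth")
  C0 <- unique(vapply(curves, function(cv) cv$C0, 0))
  v <- unique(vapply(curves, function(cv) cv$F / cv$bed$A, 0))
  if (length(C0) != 1L || length(v) != 1L)
    stop("beds must differ only in depth (same C0 and linear velocity)")
  tsv <- vapply(curves, breakthrough_time, 0, fraction = target_fraction)
  n <- length(Z)
  fit <- stats::lm.fit(cbind(1, Z), tsv)
  a <- fit$coefficients[[2L]]; b <- fit$coefficients[[1L]]
  r <- if (n > 2L) suppressWarnings(stats::cor(Z, tsv)) else 1
  # a is min/um of bed; per-cm slope recovers the volumetric capacity
  Q_o <- a * UM_PER_CM * C0 * v
  k_BDST <- if (abs(b) > .Machine$double.eps)
    -log(1 / target_fraction - 1) / (b * C0) else NA_real_
  list(a = a, b = b, r2 = if (is.na(r)) 1 else r^2, Q_o = Q_o,
       k_BDST = k_BDST, target_fraction = target_fraction,
       predict = function(Z_new) a * Z_new + b)
}

#' Percent error between an experimental and a model-calculated value
#'
#' `E = 100 |x_exp - x_cal| / x_cal` -- the calculated value is the
#' reference denominator (the convention under which breakthrough-model
#' error tables are built; see the vignette for the verification against
#' published values).
#'
#' @param x_exp experimental value.
#' @param x_cal model-calculated value (non-zero).
#' @return percent error, >= 0.
#' @export
error_percent <- function(x_exp, x_cal) {
  if (any(x_cal == 0)) stop("calculated value is zero; percent error undefined")
  100 * abs(x_exp - x_cal) / abs(x_cal)
}

#' Rank breakthrough-model fits by percent error
#'
#' Sorted ascending by `E_pct` (best first); ties broken by descending R^2.
#'
#' @param fits list of `btc_fit` objects on the same curve.
#' @return `data.frame` with columns `model`, `E_pct`, `r2` in rank order.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2L) stop("need >= 2 fits to rank")
  stopifnot(all(vapply(fits, inherits, TRUE, "btc_fit")))
  df <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    E_pct = vapply(fits, `[[`, 0, "E_pct"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    stringsAsFactors = FALSE)
  df[order(df$E_pct, -df$r2), , drop = FALSE]
}

#' Predict a breakthrough curve from a fitted model
#'
#' Evaluates the fitted model's closed form at the given times; values are
#' clipped to `[0, 1]`.  For prediction, Thomas/Yoon-Nelson/BDST are the
#' logistic front; Bohart-Adams is the early-front exponential and needs the
#' operating conditions of a reference curve.
#'
#' @param fit a `btc_fit`.
#' @param times times, min.
#' @param curve the curve the fit came from (required for `bohart_adams`
#'   and `bdst`, whose closed forms involve C0, Z and v).
#' @return numeric vector of predicted `c_ratio` in `[0, 1]`.
#' @export
predict_curve <- function(fit, times, curve = NULL) {
  stopifnot(inherits(fit, "btc_fit"))
  p <- fit$params
  need_curve <- fit$model %in% c("bohart_adams", "bdst")
  if (need_curve && is.null(curve))
    stop("predict_curve needs the source curve for model '", fit$model, "'")
  out <- switch(fit$model,
    yoon_nelson = 1 / (1 + exp(p$k_YN * (p$t_05 - times))),
    thomas = {
      if (is.null(curve))
        stop("predict_curve needs the source curve for model 'thomas'")
      k <- p$k_T * curve$C0
      t05 <- p$q_e * curve$bed$W / (curve$C0 * curve$F)
      1 / (1 + exp(k * (t05 - times)))
    },
    bohart_adams = {
      v <- curve$F / curve$bed$A
      Zcm <- curve$bed$Z / UM_PER_CM
      exp(p$k_BA * curve$C0 * times - p$k_BA * p$N_o * Zcm / v)
    },
    bdst = {
      v <- curve$F / curve$bed$A
      Zcm <- curve$bed$Z / UM_PER_CM
      k <- p$k_BDST * curve$C0
      t05 <- p$Q_o * Zcm / (curve$C0 * v)
      1 / (1 + exp(k * (t05 - times)))
    },
    stop("unknown model: ", fit$model))
  pmax(0, pmin(1, out))
}
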