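# Performance-indicator panel computed from a breakthrough curve.
#
# All indicators are evaluated at the conventional 10% breakthrough point
# (t_b, where C/C0 = 0.1) and 90% exhaustion point (t_e):
#   V_b  = F t_b                     volume loaded at breakthrough, mL
#   BV   = V_b / V_M                 bed volumes processed
#   DBC  = C0 V_b / W                dynamic binding capacity, mg/g
#   EBC  = uptake integral at bed exhaustion, mg/g
#   MAER = W / V_b                   adsorbent exhaustion rate, g/mL
#   HMTZ = Z (t_e - t_b) / t_e       mass-transfer-zone length, um
#   MBU  = 100 DBC / EBC             bed utilization, %
#   P    = DBC / t_b                 productivity, mg/(min g)
#   tau  = eps V_M / F               hydraulic residence time, min
#   J    = V / (A t)                 permeation flux, L/(m^2 h)
# The DBC product form assumes negligible breakthrough before t_b (sharp
# front); the uptake-integral route is available via `dbc_method`.

# mL/(cm^2 min) -> L/(m^2 h)
.FLUX_CONV <- 600

#' Time at which a breakthrough curve crosses a given fraction
#'
#' The default method fits the two-parameter logistic front
#' c(t) = 1/(1 + exp(k (t* - t))) to the observed curve by nonlinear least
#' squares (started from the linearized Yoon-Nelson regression) and inverts
#' it at `fraction`; `method = "interpolate"` instead interpolates linearly
#' between the two samples bracketing the first crossing.  If the nonlinear
#' fit fails to converge the linearized estimate is used.
#'
#' @param curve a [breakthrough_curve()].
#' @param fraction target C/C0 in (0, 1).
#' @param method `"logistic"` (default) or `"interpolate"`.
#' @return crossing time, min.
#' @export
breakthrough_time <- function(curve, fraction,
                              method = c("logistic", "interpolate")) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  method <- match.arg(method)
  cmax <- max(curve$c_ratio)
  if (cmax < fraction)
    stop(sprintf(
      "curve never reaches c_ratio = %g (max observed = %g)", fraction, cmax))
  if (method == "interpolate") {
    i <- which(curve$c_ratio >= fraction)[1L]
    if (i == 1L) return(curve$t[1L])
    t0 <- curve$t[i - 1L]; t1 <- curve$t[i]
    c0 <- curve$c_ratio[i - 1L]; c1 <- curve$c_ratio[i]
    return(t0 + (fraction - c0) / (c1 - c0) * (t1 - t0))
  }
  fit <- .fit_logistic_front(curve)
  fit$t_05 - log(1 / fraction - 1) / fit$k
}

# logistic front (k, t_05) by nls with linearized start; fall back to the
# linearized estimate when nls cannot improve it
.fit_logistic_front <- function(curve) {
  cr <- curve$c_ratio
  use <- cr > 0.01 & cr < 0.99
  if (sum(use) >= 3L) {
    y <- log(cr[use] / (1 - cr[use]))
    lin <- stats::lm.fit(cbind(1, curve$t[use]), y)
    k0 <- lin$coefficients[[2L]]
    t0 <- -lin$coefficients[[1L]] / k0
  } else {
    # nearly-step front: centre at first crossing of 0.5, steep slope
    i <- which(cr >= 0.5)[1L]
    t0 <- curve$t[max(i, 1L)]
    k0 <- 10 / max(diff(range(curve$t)) / length(curve$t), 1e-6)
  }
  if (!is.finite(k0) || k0 <= 0)
    stop("curve front is not rising; cannot locate breakthrough")
  dat <- data.frame(t = curve$t, c = pmin(cr, 1))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(c ~ 1 / (1 + exp(k * (t05 - t))), data = dat,
                 start = list(k = k0, t05 = t0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(k = k0, t_05 = t0))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0) return(list(k = k0, t_05 = t0))
  list(k = cf[["k"]], t_05 = cf[["t05"]])
}

#' Performance-indicator panel for a breakthrough experiment
#'
#' Computes the full indicator panel (see the package vignette for the
#' formulas and their assumptions).  The equilibrium binding capacity EBC is
#' the uptake integral evaluated at the last sample with `c_ratio >= 0.99`
#' (bed exhaustion); if the curve never reaches 0.99, EBC, MBU and the
#' exhaustion flag are computed at the final sample and `exhausted` is
#' `FALSE`.
#'
#' @param curve a [breakthrough_curve()].
#' @param fractions breakthrough/exhaustion fraction pair, default `c(0.1, 0.9)`.
#' @param method passed to [breakthrough_time()].
#' @param dbc_method `"product"` (C0 V_b / W, default) or `"integral"`
#'   (uptake integral at t_b).
#' @return object of class `performance_indicators`; a list with fields
#'   `t_b`, `t_e`, `V_b`, `BV`, `DBC`, `EBC`, `MAER`, `HMTZ`, `MBU`, `P`,
#'   `tau_res`, `J`, `exhausted`, plus the condition metadata `Z`, `C0`,
#'   `F`, `W`, `label`.
#' @export
performance_indicators <- function(curve, fractions = c(0.1, 0.9),
                                   method = c("logistic", "interpolate"),
                                   dbc_method = c("product", "integral")) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  stopifnot(length(fractions) == 2L, fractions[1L] < fractions[2L],
            all(fractions > 0), all(fractions < 1))
  method <- match.arg(method)
  dbc_method <- match.arg(dbc_method)
  t_b <- breakthrough_time(curve, fractions[1L], method)
  t_e <- breakthrough_time(curve, fractions[2L], method)

  kin <- to_kinetic_curve(curve)
  exh_idx <- which(curve$c_ratio >= 0.99)
  exhausted <- length(exh_idx) > 0L
  ebc_idx <- if (exhausted) exh_idx[length(exh_idx)] else length(curve$t)
  EBC <- kin$q_t[ebc_idx]

  DBC <- if (dbc_method == "product") curve$C0 * curve$F * t_b / curve$bed$W
         else stats::approx(kin$t, kin$q_t, xout = t_b, rule = 2)$y

  ind <- .assemble_indicators(t_b = t_b, t_e = t_e, C0 = curve$C0,
                              F_mL = curve$F, bed = curve$bed, EBC = EBC,
                              DBC = DBC, label = curve$label)
  ind$exhausted <- exhausted
  ind$J <- curve$F / curve$bed$A * .FLUX_CONV
  ind
}

#' Indicator panel from tabulated breakthrough times
#'
#' Computes every indicator derivable from the 10%/90% breakthrough times
#' and the operating conditions alone -- the form in which published
#' breakthrough studies report their raw results.  EBC (hence MBU) must be
#' supplied if wanted, since it requires the full curve.
#'
#' @param t_b,t_e 10% and 90% breakthrough times, min (`t_b <= t_e`).
#' @param C0 inlet concentration, mg/mL.
#' @param F_mL flow rate, mL/min.
#' @param bed a [bed_spec()].
#' @param EBC equilibrium binding capacity, mg/g (optional).
#' @param label condition tag.
#' @return a `performance_indicators` object (MBU is `NA` without `EBC`).
#' @export
indicators_from_times <- function(t_b, t_e, C0, F_mL, bed, EBC = NA_real_,
                                  label = "") {
  stopifnot(t_b > 0, t_e >= t_b, C0 > 0, F_mL > 0, inherits(bed, "bed_spec"))
  V_b <- F_mL * t_b
  DBC <- C0 * V_b / bed$W
  ind <- .assemble_indicators(t_b = t_b, t_e = t_e, C0 = C0, F_mL = F_mL,
                              bed = bed, EBC = EBC, DBC = DBC, label = label)
  ind$exhausted <- NA
  ind$J <- F_mL / bed$A * .FLUX_CONV
  ind
}

.assemble_indicators <- function(t_b, t_e, C0, F_mL, bed, EBC, DBC, label) {
  V_b <- F_mL * t_b
  structure(list(
    t_b = t_b, t_e = t_e,
    V_b = V_b,
    BV = V_b / bed$V_M,
    DBC = DBC,
    EBC = EBC,
    MAER = bed$W / V_b,
    HMTZ = bed$Z * (t_e - t_b) / t_e,
    MBU = 100 * DBC / EBC,
    P = DBC / t_b,
    tau_res = bed$epsilon * bed$V_M / F_mL,
    J = NA_real_,
    exhausted = NA,
    Z = bed$Z, C0 = C0, F = F_mL, W = bed$W, label = as.character(label)),
    class = "performance_indicators")
}

#' @export
print.performance_indicators <- function(x, ...) {
  cat(sprintf("Breakthrough indicators%s:\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  t_b = %.3f min, t_e = %.3f min, V_b = %.3f mL, BV = %.2f\n",
              x$t_b, x$t_e, x$V_b, x$BV))
  cat(sprintf("  DBC = %.2f mg/g, EBC = %.2f mg/g, MBU = %.2f %%\n",
              x$DBC, x$EBC, x$MBU))
  cat(sprintf("  MAER = %.3g g/mL, HMTZ = %.2f um, P = %.2f mg/(min g)\n",
              x$MAER, x$HMTZ, x$P))
  cat(sprintf("  tau_res = %.4g min, J = %.4g L/(m^2 h)\n", x$tau_res, x$J))
  invisible(x)
}

#' Total bound protein mass and percent increase between experiments
#'
#' `total_bound_mass()` is DBC times adsorptive mass (mg of protein bound at
#' breakthrough); `percent_increase()` compares two experiments as
#' `100 (m2/m1 - 1)`.
#'
#' @param ind a `performance_indicators` object (or a DBC value in mg/g).
#' @param W adsorptive mass, g; defaults to the mass recorded in `ind`.
#' @return bound mass, mg.
#' @export
total_bound_mass <- function(ind, W = NULL) {
  if (inherits(ind, "performance_indicators")) {
    dbc <- ind$DBC
    if (is.null(W)) W <- ind$W
  } else {
    dbc <- ind
    if (is.null(W)) stop("W must be given when passing a bare DBC value")
  }
  if (!is.finite(dbc)) stop("DBC is not available")
  dbc * W
}

#' @rdname total_bound_mass
#' @param m1,m2 bound masses (mg) of the reference and comparison experiment.
#' @export
percent_increase <- function(m1, m2) 100 * (m2 / m1 - 1)
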