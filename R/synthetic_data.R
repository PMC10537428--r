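# Synthetic breakthrough-curve generator with known ground truth.
#
# Curves are generated from the closed forms of the breakthrough models so
# that every downstream fit can be validated by parameter recovery:
#   Yoon-Nelson / Thomas : logistic front  c(t) = 1 / (1 + exp(k (t* - t)))
#       with (k, t*) = (k_YN, t_05) or (k_T C0, q_e W / (C0 F))
#   Bohart-Adams         : exponential early front
#       c(t) = exp(k_BA C0 t - k_BA N_o Z / v), clamped at 1 (the BA form is
#       only physical before exhaustion)
# Additive Gaussian noise on c_ratio is truncated to [0, 1.05], matching the
# overshoot tolerance of breakthrough_curve().

# run expr with a private RNG stream; leaves the caller's RNG untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic breakthrough experiment
#'
#' @param model one of `"yoon_nelson"`, `"thomas"`, `"bohart_adams"`.
#' @param params named list of model parameters:
#'   * yoon_nelson: `k_YN` (1/min), `t_05` (min)
#'   * thomas: `k_T` (mL/mg min), `q_e` (mg/g)
#'   * bohart_adams: `k_BA` (mL/mg min), `N_o` (mg/mL)
#' @param C0 inlet concentration, mg/mL.
#' @param F_mL flow rate, mL/min.
#' @param bed a [bed_spec()].
#' @param t_start,t_stop,t_step sampling grid, min.  If `t_stop`/`t_step`
#'   are `NULL` they default so that the grid spans the whole front plus its
#'   saturated tail (`t_05 + 12/k`) and at least 30 samples fall within the
#'   5--95% breakthrough window.
#' @param noise_sd additive Gaussian noise s.d. on `c_ratio` (>= 0).
#' @param seed integer seed; identical seeds give bit-identical curves.
#' @param label condition tag propagated to the generated curve.
#'
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model, params, C0, F_mL, bed,
                           t_start = 0, t_stop = NULL, t_step = NULL,
                           noise_sd = 0, seed = NULL, label = "") {
  model <- match.arg(model, c("yoon_nelson", "thomas", "bohart_adams"))
  stopifnot(inherits(bed, "bed_spec"), C0 > 0, F_mL > 0, noise_sd >= 0)
  need <- switch(model,
                 yoon_nelson = c("k_YN", "t_05"),
                 thomas = c("k_T", "q_e"),
                 bohart_adams = c("k_BA", "N_o"))
  missing_p <- setdiff(need, names(params))
  if (length(missing_p))
    stop("model '", model, "' needs parameter(s): ",
         paste(missing_p, collapse = ", "))
  if (any(unlist(params[need]) <= 0))
    stop("all rate/capacity parameters must be > 0")
  spec <- structure(
    list(model = model, params = params[need], C0 = C0, F = F_mL, bed = bed,
         t_start = t_start, t_stop = t_stop, t_step = t_step,
         noise_sd = noise_sd, seed = seed, label = as.character(label)),
    class = "synthetic_spec")
  # resolve the default grid now so the spec is fully explicit
  lg <- .logistic_equiv(spec)
  if (is.null(spec$t_stop)) spec$t_stop <- lg$t_05 + 12 / lg$k
  if (is.null(spec$t_step)) {
    front <- 2 * log(19) / lg$k        # 5% -> 95% width of the logistic
    spec$t_step <- front / 30
  }
  if (spec$t_stop <= spec$t_start) stop("t_stop must exceed t_start")
  stopifnot(spec$t_step > 0)
  spec
}

# (k, t_05) of the logistic front equivalent to the spec's model; for
# bohart_adams, t_05 is the time at which the exponential reaches 1/2 and k
# its rate, used only for default-grid sizing.
.logistic_equiv <- function(spec) {
  p <- spec$params
  switch(spec$model,
    yoon_nelson = list(k = p$k_YN, t_05 = p$t_05),
    thomas = list(k = p$k_T * spec$C0,
                  t_05 = p$q_e * spec$bed$W / (spec$C0 * spec$F)),
    bohart_adams = {
      v <- spec$F / spec$bed$A                 # cm/min
      Zcm <- spec$bed$Z / UM_PER_CM
      k <- p$k_BA * spec$C0
      t1 <- p$k_BA * p$N_o * Zcm / v / k       # time at which c reaches 1
      list(k = k, t_05 = t1 - log(2) / k)
    })
}

#' Evaluate the noiseless closed-form breakthrough front of a spec
#'
#' @param spec a [synthetic_spec()].
#' @param t times, min.
#' @return `c_ratio` values in `[0, 1]`.
#' @export
breakthrough_closed_form <- function(spec, t) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$params
  if (spec$model == "bohart_adams") {
    v <- spec$F / spec$bed$A
    Zcm <- spec$bed$Z / UM_PER_CM
    pmin(exp(p$k_BA * spec$C0 * t - p$k_BA * p$N_o * Zcm / v), 1)
  } else {
    lg <- .logistic_equiv(spec)
    1 / (1 + exp(lg$k * (lg$t_05 - t)))
  }
}

#' Generate a breakthrough curve from a synthetic specification
#'
#' @param spec a [synthetic_spec()].
#' @return a [breakthrough_curve()] whose bed/operating metadata mirror the
#'   spec; with `noise_sd = 0` the curve is the exact closed form.
#' @export
generate_breakthrough <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- seq(spec$t_start, spec$t_stop, by = spec$t_step)
  c_clean <- breakthrough_closed_form(spec, t)
  c_noisy <- if (spec$noise_sd > 0) {
    .with_seed(spec$seed,
               pmax(0, pmin(1.05, c_clean + stats::rnorm(length(t), 0, spec$noise_sd))))
  } else c_clean
  # overshoot into (1, 1.05] is by construction within tolerance here; the
  # retained-value warning is meant for measured data coming through read_curve
  suppressWarnings(
    breakthrough_curve(t = t, c_ratio = c_noisy, C0 = spec$C0, F_mL = spec$F,
                       bed = spec$bed, label = spec$label))
}

#' Generate a factorial grid of synthetic curves
#'
#' Takes a base specification and a named list of factor levels over any of
#' `C0` (mg/mL), `F` (mL/min), `layers` (bed height and adsorptive mass
#' scale together) and `capacity` (equilibrium capacity q_e, mg/g), and
#' generates one curve per combination.  The base spec's model kinetic rate
#' constant is held fixed; for the logistic family the midpoint time follows
#' t_05 = q_e W / (C0 F), so e.g. halving the flow rate doubles t_05 at
#' fixed capacity.  Labels encode the condition.
#'
#' @param base a [synthetic_spec()] (logistic family; `bohart_adams` grids are
#'   supported for `C0` and `F` only).
#' @param grid named list, keys among `C0`, `F`, `layers`, `capacity`.
#' @return list of [breakthrough_curve()]; an empty grid returns the base
#'   curve alone.
#' @export
generate_condition_grid <- function(base, grid = list()) {
  stopifnot(inherits(base, "synthetic_spec"))
  allowed <- c("C0", "F", "layers", "capacity")
  bad <- setdiff(names(grid), allowed)
  if (length(bad))
    stop("unknown grid factor(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  if (base$model == "bohart_adams" &&
      any(c("layers", "capacity") %in% names(grid)))
    stop("layers/capacity grids require a logistic-family base model")
  if (!length(grid)) return(list(generate_breakthrough(base)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    row <- combos[i, , drop = FALSE]
    C0 <- if ("C0" %in% names(row)) row$C0 else base$C0
    F_mL <- if ("F" %in% names(row)) row$F else base$F
    bed <- if ("layers" %in% names(row))
      scale_layers(base$bed, row$layers) else base$bed
    # work in the Thomas parameterization: capacity is per-gram and invariant
    # under layer scaling, so t_05 responds to W, C0 and F as it should
    lg <- .logistic_equiv(base)
    params <- base$params
    if (base$model != "bohart_adams") {
      k_T <- lg$k / base$C0
      q_e <- if ("capacity" %in% names(row)) row$capacity
             else lg$t_05 * base$C0 * base$F / base$bed$W
      params <- list(k_T = k_T, q_e = q_e)
    }
    lab <- paste0("C0=", C0, ",F=", F_mL, ",layers=", bed$layers,
                  if (base$model != "bohart_adams")
                    paste0(",qe=", signif(params$q_e, 6)) else "")
    sp <- synthetic_spec(
      model = if (base$model == "bohart_adams") "bohart_adams" else "thomas",
      params = params, C0 = C0, F_mL = F_mL, bed = bed,
      t_start = base$t_start, noise_sd = base$noise_sd,
      seed = if (is.null(base$seed)) NULL else base$seed + i,
      label = lab)
    generate_breakthrough(sp)
  })
}
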