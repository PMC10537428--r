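# Dynamic uptake (kinetic) curves and linearized kinetic-model fits.
#
# The uptake curve q_t(t) = (F/W) * int_0^t (C0 - C(s)) ds is obtained from
# the breakthrough curve by trapezoidal integration.  Four classical
# kinetic models are fitted in their linearized forms:
#   pseudo-first-order    ln(q1 - q_t) = ln q1 - k1 t
#   pseudo-second-order   t/q_t = 1/(k2 q2^2) + t/q2
#   Elovich               q_t = (1/beta) ln(alpha beta) + (1/beta) ln t
#   intraparticle (Weber-Morris)  q_t = k_i sqrt(t) + I, piecewise in stages
# R^2 is the squared Pearson correlation of the linearized regression, the
# convention under which linearized-fit studies report goodness of fit.

# simple-OLS helper: slope/intercept/r2 of y on x
.ols <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("insufficient data: need >= 3 points, got ", n)
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- suppressWarnings(stats::cor(x, y))
  list(intercept = fit$coefficients[[1L]], slope = fit$coefficients[[2L]],
       r2 = if (is.na(r)) 0 else r^2, n = n)
}

.new_kinetic_fit <- function(model, params, r2, n_used,
                             n_dropped = 0L, stages = NULL) {
  structure(list(model = model, params = params, r2 = r2, n_used = n_used,
                 n_dropped = n_dropped, stages = stages),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s  (R2 = %.4f, n = %d%s)\n", x$model, x$r2,
              x$n_used,
              if (x$n_dropped > 0L) paste0(", ", x$n_dropped, " dropped")
              else ""))
  if (x$model == "ipd") {
    for (s in x$stages)
      cat(sprintf("  stage [%d..%d]: k_i = %.4g mg/(g min^0.5), I = %.4g, R2 = %.4f\n",
                  s$from, s$to, s$k_i, s$I, s$r2))
  } else {
    p <- unlist(x$params)
    cat("  ", paste(names(p), signif(p, 6), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Convert a breakthrough curve to a dynamic uptake curve
#'
#' Integrates the bound mass flux by the trapezoidal rule on the sample
#' grid: `q_t(t) = (F/W) * integral of (C0 - C)` with `C = c_ratio * C0`.
#' A decrease in `q_t` larger than 2% of its maximum (possible with noisy
#' overshooting data) is flagged via the `nonmonotone` field.
#'
#' @param curve a [breakthrough_curve()].
#' @return object of class `kinetic_curve`: list with `t` (min), `q_t`
#'   (mg/g), `nonmonotone` flag and the `source` curve.
#' @export
to_kinetic_curve <- function(curve) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  t <- curve$t
  integrand <- curve$C0 * (1 - curve$c_ratio)     # mg/mL not yet captured
  n <- length(t)
  # cumulative trapezoid from the first sample; q(t[0]) = 0 with t[0] = 0
  steps <- diff(t) * (integrand[-n] + integrand[-1L]) / 2
  q_t <- c(0, cumsum(steps)) * curve$F / curve$bed$W
  drops <- diff(q_t)
  structure(list(t = t, q_t = q_t,
                 nonmonotone = any(drops < -0.02 * max(q_t, .Machine$double.eps)),
                 source = curve),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("Uptake curve: %d samples, q_t(%g min) = %.2f mg/g%s\n",
              length(x$t), max(x$t), x$q_t[length(x$q_t)],
              if (isTRUE(x$nonmonotone)) " [non-monotone]" else ""))
  invisible(x)
}

.as_kinetic <- function(kin) {
  if (inherits(kin, "breakthrough_curve")) kin <- to_kinetic_curve(kin)
  stopifnot(inherits(kin, "kinetic_curve"))
  kin
}

#' Pseudo-first-order kinetic fit
#'
#' Linearized as `ln(q_e - q_t)` regressed on `t`; the slope gives `-k1`
#' and the intercept `ln(q1)`.  The equilibrium capacity entering the log
#' must be supplied (or is defaulted to `1.02 * max(q_t)`, standard practice
#' when no independent estimate exists); points with `q_t >= q_e` are
#' dropped and counted.
#'
#' @param kin a `kinetic_curve` (or a breakthrough curve, converted on the
#'   fly).
#' @param q_e equilibrium capacity used inside the logarithm, mg/g.
#' @return a `kinetic_fit` with params `k_1` (1/min) and `q_1` (mg/g).
#' @export
fit_pfo <- function(kin, q_e = NULL) {
  kin <- .as_kinetic(kin)
  if (is.null(q_e)) q_e <- 1.02 * max(kin$q_t)
  if (!is.finite(q_e) || q_e <= 0)
    stop("insufficient data for PFO fit: no positive uptake")
  use <- kin$q_t < q_e & kin$q_t > 0
  if (sum(use) < 3L)
    stop("insufficient data for PFO fit: ", sum(use), " usable points")
  o <- .ols(kin$t[use], log(q_e - kin$q_t[use]))
  .new_kinetic_fit("pfo",
                   list(k_1 = -o$slope, q_1 = exp(o$intercept)),
                   o$r2, o$n, n_dropped = sum(!use))
}

#' Pseudo-second-order kinetic fit
#'
#' Linearized as `t/q_t` regressed on `t`; the slope gives `1/q2` and the
#' intercept `1/(k2 q2^2)`.
#'
#' @inheritParams fit_pfo
#' @return a `kinetic_fit` with params `k_2` (g/(mg min)) and `q_2` (mg/g).
#' @export
fit_pso <- function(kin) {
  kin <- .as_kinetic(kin)
  use <- kin$q_t > 0
  if (sum(use) < 3L)
    stop("insufficient data for PSO fit: ", sum(use), " usable points")
  o <- .ols(kin$t[use], kin$t[use] / kin$q_t[use])
  if (o$slope <= 0)
    stop("degenerate PSO fit: non-positive slope (", format(o$slope), ")")
  q_2 <- 1 / o$slope
  .new_kinetic_fit("pso",
                   list(k_2 = 1 / (o$intercept * q_2^2), q_2 = q_2),
                   o$r2, o$n, n_dropped = sum(!use))
}

#' Elovich kinetic fit
#'
#' Linearized as `q_t` regressed on `ln t`; the slope gives `1/beta` and
#' the intercept `(1/beta) ln(alpha beta)`.  Samples at `t = 0` are
#' excluded and counted.
#'
#' @inheritParams fit_pfo
#' @return a `kinetic_fit` with params `alpha` (mg/(g min)) and `beta`
#'   (g/mg).
#' @export
fit_elovich <- function(kin) {
  kin <- .as_kinetic(kin)
  use <- kin$t > 0
  if (sum(use) < 3L)
    stop("insufficient data for Elovich fit: ", sum(use), " usable points")
  o <- .ols(log(kin$t[use]), kin$q_t[use])
  if (o$slope <= 0 || diff(range(kin$q_t[use])) == 0)
    stop("degenerate Elovich fit: non-positive slope (", format(o$slope), ")")
  beta <- 1 / o$slope
  .new_kinetic_fit("elovich",
                   list(alpha = exp(o$intercept * beta) / beta, beta = beta),
                   o$r2, o$n, n_dropped = sum(!use))
}

# per-segment OLS statistics in O(1) via prefix sums
.seg_stats <- function(cs, from, to) {
  n <- to - from + 1
  sx <- cs$x[to + 1L] - cs$x[from]
  sy <- cs$y[to + 1L] - cs$y[from]
  sxx <- cs$xx[to + 1L] - cs$xx[from]
  sxy <- cs$xy[to + 1L] - cs$xy[from]
  syy <- cs$yy[to + 1L] - cs$yy[from]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- cxy / vx
  rss <- max(vy - slope * cxy, 0)
  list(slope = slope, intercept = (sy - slope * sx) / n,
       r2 = if (vy <= 0) 1 else max(0, min(1, cxy^2 / (vx * vy))),
       rss = rss)
}

#' Intraparticle-diffusion (Weber-Morris) fit with multi-stage segmentation
#'
#' Piecewise OLS of `q_t` on `sqrt(t)`.  Multi-linearity of this plot is the
#' classical signature of successive rate-controlling regimes (boundary-layer
#' film diffusion, intraparticle pore diffusion, final equilibrium).  If
#' `breakpoints` are not given, they are chosen by exhaustive search over all
#' admissible segmentations (>= 3 points per stage) minimizing the total
#' residual sum of squares.
#'
#' @inheritParams fit_pfo
#' @param n_stages number of linear stages, 1 to 3.
#' @param breakpoints optional integer vector (length `n_stages - 1`) of last
#'   sample indices of each leading stage.
#' @return a `kinetic_fit` with `model = "ipd"`; `stages` holds one entry per
#'   stage with fields `from`, `to`, `k_i` (mg/(g min^0.5)), `I` (mg/g),
#'   `r2`; the top-level `r2` is the RSS-weighted pooled value, and `params`
#'   carries the per-stage slopes `k_i`.
#' @export
fit_ipd <- function(kin, n_stages = 3L, breakpoints = NULL) {
  kin <- .as_kinetic(kin)
  n_stages <- as.integer(n_stages)
  stopifnot(n_stages >= 1L, n_stages <= 3L)
  x <- sqrt(kin$t); y <- kin$q_t
  n <- length(x)
  if (n < 3L * n_stages)
    stop("insufficient data for ", n_stages, "-stage IPD fit: ", n,
         " points (need >= ", 3L * n_stages, ")")
  cs <- list(x = c(0, cumsum(x)), y = c(0, cumsum(y)),
             xx = c(0, cumsum(x^2)), xy = c(0, cumsum(x * y)),
             yy = c(0, cumsum(y^2)))
  bounds_of <- function(bp) {
    from <- c(1L, bp + 1L)
    to <- c(bp, n)
    Map(function(f, t) c(f, t), from, to)
  }
  if (is.null(breakpoints)) {
    best <- NULL; best_rss <- Inf
    if (n_stages == 1L) {
      best <- integer(0)
    } else if (n_stages == 2L) {
      for (i in 3:(n - 3L)) {
        rss <- .seg_stats(cs, 1L, i)$rss + .seg_stats(cs, i + 1L, n)$rss
        if (rss < best_rss) { best_rss <- rss; best <- i }
      }
    } else {
      for (i in 3:(n - 6L)) {
        r1 <- .seg_stats(cs, 1L, i)$rss
        for (j in (i + 3L):(n - 3L)) {
          rss <- r1 + .seg_stats(cs, i + 1L, j)$rss +
            .seg_stats(cs, j + 1L, n)$rss
          if (rss < best_rss) { best_rss <- rss; best <- c(i, j) }
        }
      }
    }
    breakpoints <- best
  } else {
    breakpoints <- as.integer(breakpoints)
    stopifnot(length(breakpoints) == n_stages - 1L)
    lens <- diff(c(0L, breakpoints, n))
    if (any(lens < 3L)) stop("each IPD stage needs >= 3 points")
  }
  stages <- lapply(bounds_of(breakpoints), function(b) {
    s <- .seg_stats(cs, b[1L], b[2L])
    list(from = b[1L], to = b[2L], k_i = s$slope, I = s$intercept,
         r2 = s$r2, rss = s$rss)
  })
  pooled_rss <- sum(vapply(stages, `[[`, 0, "rss"))
  tss <- sum((y - mean(y))^2)
  .new_kinetic_fit("ipd",
                   list(k_i = vapply(stages, `[[`, 0, "k_i")),
                   r2 = if (tss <= 0) 1 else max(0, 1 - pooled_rss / tss),
                   n_used = n, stages = stages)
}
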