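#' Power model parameters
#'
#' Bundle of the physical constants entering the external-power model: total
#' moving mass (athlete + sit-ski + poles + skis), gravitational
#' acceleration, ski-snow friction coefficient, air density and the drag
#' area (the product of projected frontal area and drag coefficient, which
#' only ever enters as a product).
#'
#' @param mass_total total moving mass, kg.
#' @param mu_s dimensionless ski-snow kinetic friction coefficient (< 1).
#' @param rho air density, kg/m^3 (default 1.29).
#' @param drag_area A*Cd, m^2 (default 0.338, mid poling posture).
#' @param g gravitational acceleration, m/s^2.
#' @return an object of class `power_params`.
#' @examples
#' power_params(mass_total = 71.7, mu_s = 0.036)
#' @export
power_params <- function(mass_total, mu_s, rho = 1.29, drag_area = 0.338,
                         g = 9.81) {
  vals <- c(mass_total = mass_total, mu_s = mu_s, rho = rho,
            drag_area = drag_area, g = g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all power parameters must be finite and > 0")
  if (mu_s >= 1) stop("mu_s must be < 1")
  structure(as.list(vals), class = "power_params")
}

#' Decompose external power into gravity, friction and drag terms
#'
#' Total external power at speed `v` on a slope of the given grade is the sum
#' of power against gravity, against ski-snow friction and against
#' aerodynamic drag:
#' \deqn{P_{tot} = m g \sin\alpha\, v + m g \cos\alpha\, \mu_s v +
#'       \tfrac12 \rho v^3 A C_d}
#' with \eqn{\alpha = \arctan(\mathrm{grade}/100)} (grade is rise/run
#' percent, so no small-angle shortcut is taken; grades up to 16% occur on
#' real courses).  Downhill grades give negative gravitational power; the
#' friction and drag terms are never negative.
#'
#' @param v speed, m/s (vectorised; `v = 0` is legal and gives all-zero
#'   power).
#' @param grade slope in percent (signed), same length as `v` or scalar.
#' @param params a [power_params()] object.
#' @return for scalar input an object of class `power_breakdown` (list with
#'   `P_g`, `P_f`, `P_d`, `P_tot` in W and `shares`, percent of `P_tot`);
#'   for vector input a data.frame with columns `P_g`, `P_f`, `P_d`,
#'   `P_tot`.
#' @examples
#' pb <- power_breakdown(4.0, 8, power_params(71.7, 0.036))
#' pb$P_tot
#' round(pb$shares)
#' @export
power_breakdown <- function(v, grade, params) {
  stopifnot(inherits(params, "power_params"))
  if (any(v < 0, na.rm = TRUE)) stop("speed must be >= 0")
  alpha <- atan(grade / 100)
  m <- params$mass_total; g <- params$g
  P_g <- m * g * sin(alpha) * v
  P_f <- m * g * cos(alpha) * params$mu_s * v
  P_d <- 0.5 * params$rho * v^3 * params$drag_area
  P_tot <- P_g + P_f + P_d
  if (length(v) > 1L || length(grade) > 1L)
    return(data.frame(P_g = P_g, P_f = P_f, P_d = P_d, P_tot = P_tot))
  shares <- if (is.na(P_tot) || P_tot == 0) c(P_g = NA_real_, P_f = NA_real_, P_d = NA_real_)
            else 100 * c(P_g = P_g, P_f = P_f, P_d = P_d) / P_tot
  structure(list(P_g = P_g, P_f = P_f, P_d = P_d, P_tot = P_tot,
                 shares = shares),
            class = "power_breakdown")
}

#' @export
print.power_breakdown <- function(x, ...) {
  cat(sprintf("P_tot %.1f W  (gravity %.1f W, friction %.1f W, drag %.1f W)\n",
              x$P_tot, x$P_g, x$P_f, x$P_d))
  if (!anyNA(x$shares))
    cat(sprintf("shares: P_g %.0f%%, P_f %.0f%%, P_d %.0f%%\n",
                x$shares[["P_g"]], x$shares[["P_f"]], x$shares[["P_d"]]))
  invisible(x)
}

#' Estimate the ski-snow friction coefficient from a passive glide
#'
#' In a glide test the skier enters a measurement zone of known length at
#' speed `v_in`, glides passively (tucked, no poling) and exits at `v_out`.
#' Ignoring air drag — minimal at glide speeds — the energy balance over the
#' zone gives
#' \deqn{\mu = \frac{(v_{in}^2 - v_{out}^2)/(2 g d) - \sin\alpha}{\cos\alpha}}
#' On level ground this reduces to the familiar
#' \eqn{(v_{in}^2 - v_{out}^2)/(2 g d)}.
#' A negative estimate (possible on downhill zones or with measurement
#' error) is returned but flagged with a warning.
#'
#' @param v_in entry speed, m/s.
#' @param v_out exit speed, m/s.
#' @param distance zone length, m (> 0).
#' @param grade zone grade, percent (default 0, a flat zone).
#' @param g gravitational acceleration (default 9.81).
#' @return dimensionless friction coefficient estimate.
#' @examples
#' estimate_friction(5.5, 4.0, 20)   # ~0.036
#' @export
estimate_friction <- function(v_in, v_out, distance, grade = 0, g = 9.81) {
  if (distance <= 0) stop("glide distance must be > 0")
  if (v_in < 0 || v_out < 0) stop("speeds must be >= 0")
  alpha <- atan(grade / 100)
  if (grade >= 0 && v_out > v_in)
    stop("exit speed exceeds entry speed on a non-downhill glide")
  mu <- ((v_in^2 - v_out^2) / (2 * g * distance) - sin(alpha)) / cos(alpha)
  if (mu < 0) warning("negative friction estimate (", signif(mu, 3),
                      "): invalid run?")
  mu
}

#' Combine friction estimates from repeated glide tests
#'
#' The session-level coefficient is the arithmetic mean of the per-bout
#' estimates.
#'
#' @param values numeric vector of friction coefficients (non-empty).
#' @return their mean.
#' @examples
#' combine_friction(c(0.039, 0.033))   # 0.036
#' @export
combine_friction <- function(values) {
  if (length(values) == 0L) stop("no friction values to combine")
  mean(values)
}

#' Maximal speed from timed sprint trials
#'
#' A maximal-speed test times repeated all-out passes (with a self-selected
#' run-up) through a short measurement zone; the best (fastest) trial
#' defines the maximal speed for that terrain.
#'
#' @param zone_length zone length, m (> 0; typically 20).
#' @param trial_times vector of trial times, s (all > 0, non-empty).
#' @return an object of class `vmax_result` with fields `v_max` (m/s),
#'   `best_time` (s) and `n_trials`.
#' @examples
#' vmax_from_splits(20, c(5.0, 5.2))$v_max   # 4.0
#' @export
vmax_from_splits <- function(zone_length, trial_times) {
  if (zone_length <= 0) stop("zone_length must be > 0")
  if (length(trial_times) == 0L) stop("no trial times given")
  if (any(trial_times <= 0)) stop("trial times must be > 0")
  best <- min(trial_times)
  structure(list(v_max = zone_length / best, best_time = best,
                 n_trials = length(trial_times)),
            class = "vmax_result")
}

#' @export
print.vmax_result <- function(x, ...) {
  cat(sprintf("V_max %.2f m/s (best of %d trials, %.2f s)\n",
              x$v_max, x$n_trials, x$best_time))
  invisible(x)
}

#' Power decomposition for every completed course section
#'
#' Evaluates the power model at each split's mean speed and section grade.
#' Drag area may differ per terrain (poling postures uphill/flat, tuck
#' downhill).  Downhill rows are skipped by default: the skier does not
#' pole downhill, so external power there is not propulsive work.
#'
#' @param splits a `split_table` (with `grade` and `mean_speed` columns).
#' @param params a [power_params()] object (its `drag_area` is the fallback).
#' @param drag_by_terrain optional named numeric of per-terrain drag areas,
#'   e.g. `c(uphill = 0.338, flat = 0.336)`.
#' @param include_downhill also evaluate downhill sections (default FALSE,
#'   leaving their power columns `NA`).
#' @return `splits` with added columns `P_g`, `P_f`, `P_d`, `P_tot` (W).
#' @export
power_by_section <- function(splits, params, drag_by_terrain = NULL,
                             include_downhill = FALSE) {
  stopifnot(inherits(splits, "split_table"), inherits(params, "power_params"))
  n <- nrow(splits)
  P <- matrix(NA_real_, n, 4,
              dimnames = list(NULL, c("P_g", "P_f", "P_d", "P_tot")))
  for (i in seq_len(n)) {
    if (is.na(splits$mean_speed[i])) next
    if (!include_downhill && splits$terrain[i] == "downhill") next
    p <- params
    if (!is.null(drag_by_terrain) && splits$terrain[i] %in% names(drag_by_terrain))
      p$drag_area <- drag_by_terrain[[splits$terrain[i]]]
    pb <- power_breakdown(splits$mean_speed[i], splits$grade[i], p)
    P[i, ] <- c(pb$P_g, pb$P_f, pb$P_d, pb$P_tot)
  }
  splits$P_g <- P[, "P_g"]; splits$P_f <- P[, "P_f"]
  splits$P_d <- P[, "P_d"]; splits$P_tot <- P[, "P_tot"]
  splits
}

#' Express a value as percent of its maximum
#'
#' @param value observed value(s).
#' @param max_value the maximum (must be > 0).
#' @return `100 * value / max_value`.
#' @examples
#' percent_of_max(2.0, 4.0)   # 50
#' @export
percent_of_max <- function(value, max_value) {
  if (any(!is.finite(max_value)) || any(max_value <= 0))
    stop("max_value must be finite and > 0")
  100 * value / max_value
}
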