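#' Synthetic session configuration
#'
#' Describes the world a simulated training session is generated from: the
#' course, per-terrain target speeds and poling cycle rates, a first-order
#' heart-rate model and the sensor noise/sampling setup.  The defaults are
#' calibrated to a high-intensity (race-pace) sit-ski session on the
#' demonstration course: terrain speeds 2.4/5.7/7.1 m/s
#' (uphill/flat/downhill), ~60 cycles/min poling uphill and on the flat
#' with poling suppressed downhill (tucked descent), heart-rate
#' steady-state targets of 90/85/88% of a 195 beats/min peak and a 30 s
#' time constant.  `intensity = "LIT"` switches to the low-intensity
#' calibration (1.7/4.2/5.7 m/s, 49/45 cycles/min, 78/67/66% heart-rate
#' targets).
#'
#' @param intensity `"HIT"` (default) or `"LIT"`; sets the speed, cycle-rate
#'   and heart-rate defaults, each individually overridable.
#' @param course a `course_profile` (default [demo_course()], 3 laps).
#' @param speeds named numeric, target speed per terrain, m/s.
#' @param cycle_rates named numeric, poling rate per terrain, cycles/min;
#'   `NA` suppresses poling in that terrain.
#' @param hr_targets named numeric, steady-state heart rate per terrain,
#'   beats/min.
#' @param hr0 starting heart rate, beats/min.
#' @param tau heart-rate time constant, s.
#' @param gnss_sigma GNSS horizontal position noise SD per axis, m.
#' @param gyro_sigma,accel_sigma IMU noise SDs (deg/s, m/s^2).
#' @param gnss_rate,imu_rate sampling rates, Hz.
#' @param rate_jitter_cv coefficient of variation of plant spacing
#'   (default 0.05).
#' @param origin geographic placement, `c(lat, lon)` degrees.
#' @param geometry `"loop"` or `"out_and_back"` course layout.
#' @param seed RNG seed; a fixed seed makes [simulate_session()] output
#'   byte-identical across runs (Mersenne-Twister, inversion).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(intensity = c("HIT", "LIT"),
                         course = demo_course(),
                         speeds = NULL, cycle_rates = NULL, hr_targets = NULL,
                         hr0 = 120, tau = 30,
                         gnss_sigma = 2, gyro_sigma = 10, accel_sigma = 1,
                         gnss_rate = 1, imu_rate = 128,
                         rate_jitter_cv = 0.05,
                         origin = c(63.40, 10.40),
                         geometry = c("loop", "out_and_back"),
                         seed = 1L) {
  intensity <- match.arg(intensity)
  geometry <- match.arg(geometry)
  defaults <- if (intensity == "HIT") {
    list(speeds = c(uphill = 2.4, flat = 5.7, downhill = 7.1),
         rates = c(uphill = 60, flat = 60, downhill = NA),
         hr = 195 * c(uphill = 0.90, flat = 0.85, downhill = 0.88))
  } else {
    list(speeds = c(uphill = 1.7, flat = 4.2, downhill = 5.7),
         rates = c(uphill = 49, flat = 45, downhill = NA),
         hr = 195 * c(uphill = 0.78, flat = 0.67, downhill = 0.66))
  }
  speeds <- if (is.null(speeds)) defaults$speeds else speeds
  cycle_rates <- if (is.null(cycle_rates)) defaults$rates else cycle_rates
  hr_targets <- if (is.null(hr_targets)) defaults$hr else hr_targets
  if (any(speeds <= 0)) stop("target speeds must be > 0")
  ok_rates <- cycle_rates[!is.na(cycle_rates)]
  if (any(ok_rates <= 20 | ok_rates >= 120))
    stop("cycle rates must lie in (20, 120) cycles/min")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(intensity = intensity, course = course, speeds = speeds,
                 cycle_rates = cycle_rates, hr_targets = hr_targets,
                 hr0 = hr0, tau = tau, gnss_sigma = gnss_sigma,
                 gyro_sigma = gyro_sigma, accel_sigma = accel_sigma,
                 gnss_rate = gnss_rate, imu_rate = imu_rate,
                 rate_jitter_cv = rate_jitter_cv, origin = origin,
                 geometry = geometry, seed = as.integer(seed)),
            class = "synth_config")
}

#' Lay out a geographic reference polyline for a course profile
#'
#' Realises a `course_profile` as a geographic polyline with per-vertex
#' along-course distances: a smooth circular loop (default) or a straight
#' out-and-back.  Section lengths are along-surface distances, so the
#' horizontal advance per vertex is `ds * cos(alpha)` and the elevation
#' channel climbs by `ds * sin(alpha)`; the 3-D arc length of the polyline
#' therefore equals the lap length (to within chord-vs-arc error, < 0.1 m).
#'
#' @param course a `course_profile`.
#' @param geometry `"loop"` or `"out_and_back"`.
#' @param origin `c(lat, lon)` of the layout origin, degrees.  Distances are
#'   computed in a local planar frame, so results do not depend on it.
#' @param step vertex spacing along the course, m (default 5).
#' @return a `course_reference` (see [reference_from_track()]).
#' @export
lay_out_reference <- function(course, geometry = c("loop", "out_and_back"),
                              origin = c(63.40, 10.40), step = 5) {
  stopifnot(inherits(course, "course_profile"))
  geometry <- match.arg(geometry)
  L <- lap_length(course)
  d <- unique(c(seq(0, L, by = step), L, course$start, course$end))
  d <- sort(d)
  alpha <- atan(course$grade / 100)
  sec <- section_index(course, d, for_segments = TRUE)
  ds <- diff(d)
  dh <- ds * cos(alpha[sec])          # horizontal advance per segment
  dz <- ds * sin(alpha[sec])
  ele <- 100 + c(0, cumsum(dz))
  if (geometry == "loop") {
    H <- sum(dh)
    R <- H / (2 * pi)
    theta <- 2 * pi * c(0, cumsum(dh)) / H
    x <- R * sin(theta)
    y <- R * (1 - cos(theta))
  } else {
    h <- c(0, cumsum(dh))
    half <- sum(dh) / 2
    x <- ifelse(h <= half, h, 2 * half - h)
    y <- rep(0, length(h))
  }
  ll <- local_latlon(x, y, origin)
  ref <- new_reference(ll$lat, ll$lon, ele, d, origin)
  attr(ref, "lap_length") <- L
  ref
}

# section index of along-lap distances; for_segments indexes interval
# midpoints so boundary vertices belong to the following section
section_index <- function(course, d, for_segments = FALSE) {
  q <- if (for_segments) (d[-length(d)] + d[-1]) / 2 else d
  idx <- findInterval(q, course$start, left.open = FALSE)
  pmin(pmax(idx, 1L), nrow(course))
}

# planar position on the reference polyline at along-lap distance s
ref_position <- function(reference, s) {
  origin <- attr(reference, "origin")
  xy <- local_xy(reference$lat, reference$lon, origin)
  j <- pmin(pmax(findInterval(s, reference$dist), 1L), nrow(reference) - 1L)
  w <- (s - reference$dist[j]) / (reference$dist[j + 1L] - reference$dist[j])
  list(x = xy$x[j] + w * (xy$x[j + 1L] - xy$x[j]),
       y = xy$y[j] + w * (xy$y[j + 1L] - xy$y[j]),
       ele = reference$ele[j] + w * (reference$ele[j + 1L] - reference$ele[j]))
}

#' Simulate a complete training session with ground truth
#'
#' Generates a 1 Hz GNSS + heart-rate track, a wrist IMU stream and the
#' exact ground truth behind them.  The skier advances along the course at
#' the per-terrain target speeds with linear speed ramps over 5 m at
#' section boundaries; GNSS positions are sampled from the reference
#' polyline with isotropic horizontal noise; pole plants are laid down as a
#' renewal process (spacing `60/rate` with the configured jitter) while in
#' poling terrain; heart rate follows the first-order kinetics
#' `dHR/dt = (HR_target(terrain) - HR) / tau`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `synth_session`: list with `track` (a
#'   `ski_track`), `imu` (an `imu_stream`), `reference` (the
#'   `course_reference` used) and `truth` (list: `splits` — true section
#'   entry/exit/duration per lap, `plant_times`, `hr` — the noise-free
#'   heart-rate trajectory, plus the configured speeds and rates).
#' @examples
#' \donttest{
#' ses <- simulate_session(synth_config(course = demo_course(n_laps = 1)))
#' head(ses$track)
#' }
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  course <- cfg$course
  L <- lap_length(course)
  n_l <- n_laps(course)
  total <- n_l * L
  ref <- lay_out_reference(course, cfg$geometry, cfg$origin)

  sec_speed <- cfg$speeds[course$terrain]      # per section target speed
  ramp <- 5                                    # boundary speed ramp, m

  speed_at <- function(s_mod, k) {
    v <- sec_speed[[k]]
    u <- s_mod - course$start[k]
    if (u < ramp) {
      kp <- if (k > 1L) k - 1L else nrow(course)
      vp <- sec_speed[[kp]]
      v <- vp + (v - vp) * u / ramp
    }
    v
  }

  # integrate ds/dt = v(s) (midpoint rule) and collect boundary crossings
  dt <- 0.05
  boundaries <- as.vector(outer(course$start, (seq_len(n_l) - 1) * L, "+"))
  b_order <- order(boundaries)
  boundaries <- c(boundaries[b_order], total)
  cross_t <- rep(NA_real_, length(boundaries))
  tail_s <- 10  # run-out past the finish so 1 Hz sampling covers the last lap
  cap <- as.integer(ceiling(total / min(cfg$speeds) / dt * 1.5)) +
    as.integer(tail_s / dt) + 10L
  ts <- numeric(cap); ss <- numeric(cap); ks <- integer(cap)
  t_cur <- 0; s_cur <- 0; i <- 1L; b_next <- 1L
  k_cur <- 1L
  ts[1L] <- 0; ss[1L] <- 0; ks[1L] <- 1L
  t_stop <- Inf
  while (t_cur < t_stop && i < cap) {
    s_mod <- s_cur %% L
    k_cur <- section_index(course, s_mod)
    v1 <- speed_at(s_mod, k_cur)
    s_half <- s_cur + v1 * dt / 2
    k_half <- section_index(course, s_half %% L)
    v2 <- speed_at(s_half %% L, k_half)
    s_new <- s_cur + v2 * dt
    while (b_next <= length(boundaries) && s_new >= boundaries[b_next]) {
      cross_t[b_next] <- t_cur + dt * (boundaries[b_next] - s_cur) /
        (s_new - s_cur)
      if (b_next == length(boundaries)) t_stop <- cross_t[b_next] + tail_s
      b_next <- b_next + 1L
    }
    i <- i + 1L
    t_cur <- t_cur + dt
    s_cur <- s_new
    ts[i] <- t_cur; ss[i] <- s_cur; ks[i] <- k_cur
  }
  ts <- ts[1:i]; ss <- ss[1:i]; ks <- ks[1:i]
  t_end <- cross_t[length(cross_t)]

  # true splits
  sec_per_lap <- nrow(course)
  entry <- cross_t[-length(cross_t)]
  exit <- c(entry[-1], t_end)
  lap_idx <- rep(seq_len(n_l), each = sec_per_lap)
  sec_idx <- rep(seq_len(sec_per_lap), times = n_l)
  truth_splits <- data.frame(lap = lap_idx, section = course$label[sec_idx],
                             terrain = course$terrain[sec_idx],
                             entry_time = entry, exit_time = exit,
                             duration = exit - entry,
                             length = course$length[sec_idx])

  terrain_at <- function(tt) {
    j <- pmin(pmax(findInterval(tt, ts), 1L), length(ts))
    course$terrain[ks[j]]
  }

  # GNSS track
  t_gnss <- seq(0, floor(max(ts) * cfg$gnss_rate) / cfg$gnss_rate,
                by = 1 / cfg$gnss_rate)
  s_gnss <- stats::approx(ts, ss, xout = t_gnss, rule = 2)$y
  pos <- ref_position(ref, s_gnss %% L)
  nx <- stats::rnorm(length(t_gnss), 0, cfg$gnss_sigma)
  ny <- stats::rnorm(length(t_gnss), 0, cfg$gnss_sigma)
  ll <- local_latlon(pos$x + nx, pos$y + ny, cfg$origin)

  # first-order heart-rate kinetics on the GNSS grid
  hr <- numeric(length(t_gnss))
  hr[1] <- cfg$hr0
  targets <- cfg$hr_targets[terrain_at(t_gnss)]
  for (j in seq_along(t_gnss)[-1]) {
    dtj <- t_gnss[j] - t_gnss[j - 1]
    hr[j] <- targets[j - 1] + (hr[j - 1] - targets[j - 1]) * exp(-dtj / cfg$tau)
  }

  track <- data.frame(time = t_gnss, lat = ll$lat, lon = ll$lon,
                      ele = pos$ele, hr = hr)
  class(track) <- c("ski_track", "data.frame")

  # pole plants: renewal process while in poling terrain
  plant_times <- numeric(0)
  t_p <- 0.3
  while (t_p < t_end) {
    ter <- terrain_at(t_p)
    rate <- cfg$cycle_rates[[ter]]
    if (is.na(rate)) { t_p <- t_p + 0.2; next }
    plant_times <- c(plant_times, t_p)
    gap <- (60 / rate) * max(0.2, 1 + cfg$rate_jitter_cv * stats::rnorm(1))
    t_p <- t_p + gap
  }

  imu <- simulate_imu(plant_times, cfg, t_end = t_end)

  truth <- list(splits = truth_splits, plant_times = plant_times,
                hr = data.frame(time = t_gnss, hr = hr),
                speeds = cfg$speeds, cycle_rates = cfg$cycle_rates,
                hr_targets = cfg$hr_targets, hr0 = cfg$hr0, tau = cfg$tau,
                total_time = t_end)
  structure(list(track = track, imu = imu, reference = ref, truth = truth,
                 config = cfg),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("Synthetic %s session: %.0f s, %d GNSS samples, %d IMU samples, %d pole plants\n",
              x$config$intensity, x$truth$total_time, nrow(x$track),
              nrow(x$imu), length(x$truth$plant_times)))
  invisible(x)
}

#' Simulate the wrist IMU stream for given pole-plant times
#'
#' Each poling cycle contributes a smooth gyroscope x-axis peak (the arm
#' raise; Gaussian bump, 250 deg/s, SD 0.05 s) preceding a sharp
#' accelerometer z-axis transient at the plant instant (impact pulse with
#' its 30 m/s^2 apex at the plant, decaying over 30 ms, so threshold
#' crossing happens within one sample), with the peak-to-plant lag drawn
#' uniformly in
#' 0.08–0.25 s — inside the detector's default search window.  Gaussian
#' noise at the configured SDs is added to all six channels.  Uses the
#' current RNG state; [simulate_session()] seeds it once per session.
#'
#' @param plant_times sorted pole-plant times, s.
#' @param cfg a [synth_config()] (uses `imu_rate`, `gyro_sigma`,
#'   `accel_sigma`).
#' @param t_end stream duration, s (default: last plant + 1 s).
#' @return an `imu_stream` data.frame.
#' @export
simulate_imu <- function(plant_times, cfg, t_end = NULL) {
  if (is.unsorted(plant_times)) stop("plant_times must be sorted")
  if (is.null(t_end))
    t_end <- if (length(plant_times)) max(plant_times) + 1 else 1
  fs <- cfg$imu_rate
  t <- seq(0, t_end, by = 1 / fs)
  n <- length(t)
  gx <- stats::rnorm(n, 0, cfg$gyro_sigma)
  gy <- stats::rnorm(n, 0, cfg$gyro_sigma)
  gz <- stats::rnorm(n, 0, cfg$gyro_sigma)
  axx <- stats::rnorm(n, 0, cfg$accel_sigma)
  ayy <- stats::rnorm(n, 0, cfg$accel_sigma)
  azz <- stats::rnorm(n, 0, cfg$accel_sigma)
  if (length(plant_times)) {
    lags <- stats::runif(length(plant_times), 0.08, 0.25)
    for (p in seq_along(plant_times)) {
      tp <- plant_times[p]
      # gyro bump centred at the arm raise
      ctr <- tp - lags[p]
      lo <- max(1L, as.integer(floor((ctr - 0.2) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((ctr + 0.2) * fs)) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        gx[idx] <- gx[idx] + 250 * exp(-((t[idx] - ctr)^2) / (2 * 0.05^2))
      }
      # accel spike: sharp-onset impact transient, apex at the plant
      lo <- max(1L, as.integer(floor(tp * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((tp + 0.03) * fs)) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        ph <- pmin(pmax((t[idx] - tp) / 0.03, 0), 1)
        azz[idx] <- azz[idx] + 30 * cos(pi / 2 * ph)
      }
    }
  }
  out <- data.frame(time = t, gyro_x = gx, gyro_y = gy, gyro_z = gz,
                    accel_x = axx, accel_y = ayy, accel_z = azz)
  class(out) <- c("imu_stream", "data.frame")
  out
}

#' Forward-simulate a passive glide test
#'
#' Integrates the glide deceleration `dv/dt = -g (mu cos(a) + sin(a)) -
#' (rho A Cd / 2m) v^2` across a measurement zone (closed form in `v^2`
#' over distance) and returns the exit speed — the forward model whose
#' inversion is [estimate_friction()].
#'
#' @param mu true friction coefficient.
#' @param v_entry entry speed, m/s (> 0).
#' @param zone_length zone length, m.
#' @param grade zone grade, percent (default 0).
#' @param params optional [power_params()]; when given, aerodynamic drag is
#'   included with its `rho`, `drag_area` and `mass_total`.
#' @param g gravitational acceleration (default 9.81).
#' @return list with `v_in`, `v_out`, `distance`, `grade`, `stopped` (TRUE
#'   if the skier halts inside the zone; then `distance` is the stopping
#'   distance and `v_out` is 0).
#' @examples
#' simulate_glide(0.036, 5.5, 20)$v_out   # ~4.12
#' @export
simulate_glide <- function(mu, v_entry, zone_length, grade = 0,
                           params = NULL, g = 9.81) {
  if (v_entry <= 0) stop("v_entry must be > 0")
  if (zone_length <= 0) stop("zone_length must be > 0")
  alpha <- atan(grade / 100)
  a <- 2 * g * (mu * cos(alpha) + sin(alpha))
  u0 <- v_entry^2
  if (is.null(params)) {
    u_exit <- u0 - a * zone_length
    stop_x <- if (a > 0) u0 / a else Inf
  } else {
    b <- params$rho * params$drag_area / params$mass_total
    u_exit <- (u0 + a / b) * exp(-b * zone_length) - a / b
    stop_x <- if (a > 0) log((u0 + a / b) / (a / b)) / b else Inf
  }
  if (u_exit <= 0) {
    return(list(v_in = v_entry, v_out = 0, distance = stop_x, grade = grade,
                stopped = TRUE))
  }
  list(v_in = v_entry, v_out = sqrt(u_exit), distance = zone_length,
       grade = grade, stopped = FALSE)
}
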