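#' Pole-plant detector configuration
#'
#' Tuning constants for the two-stage pole-plant detector: an arm-raise is a
#' local maximum of the gyroscope roll-rate (x axis, wrist unit) with
#' prominence at least `gyro_peak_min` over a 0.2 s neighbourhood; the plant
#' itself is the first accelerometer z-axis excursion above
#' `accel_spike_min` within `search_window` after that peak.  Plants closer
#' than `refractory` are merged, keeping the larger spike.  A poling cycle
#' is accepted when the interval between consecutive plants lies in
#' `[accept_min, accept_max]` — longer gaps come from tucked descents or
#' turns, shorter ones from non-poling arm movements.
#'
#' The acceptance gate (0.6–3 s) is the established criterion for upper-body
#' double-poling cycles; the amplitude thresholds are package defaults (the
#' detection logic, not the thresholds, is the validated part) and all are
#' configurable.
#'
#' @param gyro_peak_min gyroscope peak prominence threshold, deg/s.
#' @param accel_spike_min accelerometer spike threshold, m/s^2.
#' @param search_window max gyro-peak-to-spike lag, s.
#' @param refractory minimum spacing between plants, s.
#' @param accept_min,accept_max accepted cycle-duration band, s.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(gyro_peak_min = 100, accel_spike_min = 10,
                            search_window = 0.3, refractory = 0.4,
                            accept_min = 0.6, accept_max = 3.0) {
  if (!(accept_min > 0 && accept_min < accept_max))
    stop("need 0 < accept_min < accept_max")
  if (search_window <= 0) stop("search_window must be > 0")
  structure(list(gyro_peak_min = gyro_peak_min,
                 accel_spike_min = accel_spike_min,
                 search_window = search_window, refractory = refractory,
                 accept_min = accept_min, accept_max = accept_max),
            class = "detector_config")
}

#' Detect pole plants in a wrist IMU stream
#'
#' Two-stage detection: peaks in the gyroscope x component (roll rate, the
#' arm raise) gate a search for the following accelerometer z spike (the
#' pole impact).  See [detector_config()] for the stages' parameters.
#'
#' @param imu an `imu_stream` data.frame (see [read_imu()]): columns `time`,
#'   `gyro_x..z`, `accel_x..z`; time strictly increasing.
#' @param cfg a [detector_config()].
#' @return data.frame of class `pole_plants` with columns `time` (plant
#'   instant, s), `gyro_peak_time` and `spike_magnitude` (m/s^2), sorted by
#'   time.  An empty stream yields zero rows.
#' @export
detect_pole_plants <- function(imu, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  empty <- data.frame(time = numeric(0), gyro_peak_time = numeric(0),
                      spike_magnitude = numeric(0))
  class(empty) <- c("pole_plants", "data.frame")
  if (is.null(imu) || nrow(imu) == 0L) return(empty)
  t <- imu$time
  if (is.unsorted(t, strictly = TRUE))
    stop("IMU time must be strictly increasing")
  g <- imu$gyro_x
  a <- imu$accel_z
  n <- length(t)
  dt <- stats::median(diff(t))
  half <- max(1L, as.integer(round(0.1 / dt)))  # 0.2 s neighbourhood

  # candidate gyro peaks: above threshold, local max with prominence
  cand <- which(g >= cfg$gyro_peak_min)
  peaks <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- g[lo:hi]
    g[i] >= max(w) && (g[i] - min(w)) >= cfg$gyro_peak_min
  }, logical(1))]
  # collapse plateaus of equal-valued adjacent peaks
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > half)]
  if (length(peaks) == 0L) return(empty)

  plants <- lapply(peaks, function(i) {
    hi <- i
    while (hi < n && t[hi + 1L] <= t[i] + cfg$search_window) hi <- hi + 1L
    if (hi == i) return(NULL)
    w <- (i + 1L):hi
    j <- w[which(a[w] >= cfg$accel_spike_min)[1]]
    if (is.na(j)) return(NULL)
    # magnitude: spike apex shortly after the crossing
    k <- j:min(n, j + max(1L, as.integer(round(0.05 / dt))))
    c(time = t[j], gyro_peak_time = t[i], spike_magnitude = max(a[k]))
  })
  plants <- do.call(rbind, plants)
  if (is.null(plants)) return(empty)
  out <- as.data.frame(plants)
  out <- out[order(out$time), , drop = FALSE]
  out <- out[!duplicated(out$time), , drop = FALSE]

  # merge plants within the refractory period, keep the larger spike
  keep <- rep(TRUE, nrow(out))
  last <- 1L
  for (i in seq_len(nrow(out))[-1]) {
    if (out$time[i] - out$time[last] < cfg$refractory) {
      if (out$spike_magnitude[i] > out$spike_magnitude[last]) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pole_plants", "data.frame")
  out
}

#' Build poling cycles from detected pole plants
#'
#' Each interval between consecutive pole plants is one candidate cycle; it
#' is accepted as an upper-body double-poling cycle when its duration lies
#' within the configured band (default 0.6–3 s).  Rejected intervals are
#' retained with `accepted = FALSE` so that counts are conserved
#' (`n_plants - 1` intervals in total).
#'
#' @param plants a `pole_plants` data.frame (sorted by time).
#' @param cfg a [detector_config()].
#' @return data.frame of class `cycle_records` with columns `start`, `end`,
#'   `duration` (s), `accepted` (logical) and `rate` (cycles/min, `NA` for
#'   rejected cycles).  Fewer than two plants yield zero rows.
#' @examples
#' p <- data.frame(time = c(0, 1, 1.5, 5, 7),
#'                 gyro_peak_time = NA, spike_magnitude = NA)
#' cycles_from_plants(p)$accepted
#' @export
cycles_from_plants <- function(plants, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  out <- data.frame(start = numeric(0), end = numeric(0),
                    duration = numeric(0), accepted = logical(0),
                    rate = numeric(0))
  if (!is.null(plants) && nrow(plants) >= 2L) {
    tt <- plants$time
    if (is.unsorted(tt)) stop("plants must be sorted by time")
    dur <- diff(tt)
    acc <- dur >= cfg$accept_min & dur <= cfg$accept_max
    out <- data.frame(start = tt[-length(tt)], end = tt[-1], duration = dur,
                      accepted = acc, rate = ifelse(acc, 60 / dur, NA_real_))
  }
  class(out) <- c("cycle_records", "data.frame")
  out
}

#' Assign section context and cycle length to poling cycles
#'
#' Each accepted cycle is attributed to the course section whose split
#' window contains the cycle midpoint (the midpoint rule settles cycles
#' straddling a boundary).  Cycle length is the section mean speed from the
#' GNSS analysis times the cycle duration; single-cycle GNSS distances are
#' not accurate enough at 1 Hz, so length is always section-mean based.
#'
#' @param cycles a `cycle_records` data.frame.
#' @param splits a `split_table` from [virtual_splits()].
#' @param clock_offset seconds added to cycle times to align the IMU clock
#'   with the GNSS clock (default 0).
#' @return `cycles` with added columns `lap`, `section`, `terrain` and
#'   `length` (m; `NA` for rejected or unassigned cycles).  The number of
#'   accepted cycles falling outside every section window is stored in the
#'   `unassigned` attribute.
#' @export
assign_cycle_length <- function(cycles, splits, clock_offset = 0) {
  stopifnot(inherits(splits, "split_table"))
  n <- nrow(cycles)
  cycles$lap <- rep(NA_integer_, n)
  cycles$section <- rep(NA_character_, n)
  cycles$terrain <- rep(NA_character_, n)
  cycles$length <- rep(NA_real_, n)
  unassigned <- 0L
  ok_rows <- which(!is.na(splits$entry_time) & !is.na(splits$exit_time))
  if (n > 0L) {
    mid <- (cycles$start + cycles$end) / 2 + clock_offset
    for (i in seq_len(n)) {
      j <- ok_rows[splits$entry_time[ok_rows] <= mid[i] &
                   mid[i] < splits$exit_time[ok_rows]][1]
      if (is.na(j)) {
        if (cycles$accepted[i]) unassigned <- unassigned + 1L
        next
      }
      cycles$lap[i] <- splits$lap[j]
      cycles$section[i] <- splits$section[j]
      cycles$terrain[i] <- splits$terrain[j]
      if (cycles$accepted[i])
        cycles$length[i] <- splits$mean_speed[j] * cycles$duration[i]
    }
  }
  attr(cycles, "unassigned") <- unassigned
  cycles
}

#' Per-section and per-terrain poling cycle statistics
#'
#' Terrain-level statistics pool all accepted cycles recorded in that
#' terrain (across sections and laps); the SD is the pooled sample SD of
#' those cycles.  Terrains or sections with no accepted cycles are reported
#' with count 0 and `NA` statistics — absent, not zero, mirroring how
#' downhill rows stay empty when the skier does not pole downhill.
#'
#' @param cycles a `cycle_records` data.frame after [assign_cycle_length()].
#' @return list with data.frames `section` (per section x lap) and `terrain`
#'   (per terrain), each with columns `n`, `rate_mean`, `rate_sd`,
#'   `length_mean`, `length_sd`.
#' @export
section_cycle_stats <- function(cycles) {
  acc <- cycles[cycles$accepted & !is.na(cycles$section), , drop = FALSE]
  stat_block <- function(df, by) {
    groups <- unique(by)
    res <- lapply(groups, function(gr) {
      s <- df[by == gr, , drop = FALSE]
      data.frame(n = nrow(s),
                 rate_mean = mean(s$rate), rate_sd = stats::sd(s$rate),
                 length_mean = mean(s$length), length_sd = stats::sd(s$length))
    })
    cbind(group = groups, do.call(rbind, res))
  }
  terrain_levels <- c("uphill", "flat", "downhill")
  terr <- data.frame(terrain = terrain_levels, n = 0L,
                     rate_mean = NA_real_, rate_sd = NA_real_,
                     length_mean = NA_real_, length_sd = NA_real_)
  if (nrow(acc)) {
    tb <- stat_block(acc, acc$terrain)
    idx <- match(tb$group, terr$terrain)
    terr[idx, -1] <- tb[, -1]
    sec <- stat_block(acc, paste(acc$lap, acc$section, sep = ":"))
    names(sec)[1] <- "lap_section"
  } else {
    sec <- data.frame(lap_section = character(0), n = integer(0),
                      rate_mean = numeric(0), rate_sd = numeric(0),
                      length_mean = numeric(0), length_sd = numeric(0))
  }
  list(section = sec, terrain = terr)
}
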