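#' Reference course polylines
#'
#' A `course_reference` is a geographic polyline with a known along-course
#' distance at every vertex — the common mapping trajectory that all tracks
#' of a session are projected onto, so that section times come from one
#' shared geometry rather than from each receiver's own noisy path length.
#'
#' `reference_from_track()` builds one from a clean recorded lap: planar
#' arc length is accumulated along the track and, when a course is given,
#' rescaled so the total equals the course lap length.
#'
#' @param track a `ski_track` covering exactly one clean lap.
#' @param course optional `course_profile`; its lap length calibrates the
#'   distance scale.
#' @return a `course_reference`: data.frame with columns `lat`, `lon`, `ele`,
#'   `dist` (m along course) and attributes `origin` (lat/lon of the local
#'   projection origin) and `lap_length`.
#' @seealso [lay_out_reference()] to construct one synthetically from a
#'   `course_profile`.
#' @export
reference_from_track <- function(track, course = NULL) {
  origin <- geo_origin(track$lat, track$lon)
  xy <- local_xy(track$lat, track$lon, origin)
  step <- sqrt(diff(xy$x)^2 + diff(xy$y)^2 + diff(track$ele)^2)
  dist <- c(0, cumsum(step))
  if (!is.null(course)) dist <- dist * lap_length(course) / dist[length(dist)]
  new_reference(track$lat, track$lon, track$ele, dist, origin)
}

new_reference <- function(lat, lon, ele, dist, origin) {
  structure(data.frame(lat = lat, lon = lon, ele = ele, dist = dist),
            origin = origin, lap_length = dist[length(dist)],
            class = c("course_reference", "data.frame"))
}

#' Map a GNSS track onto a reference course
#'
#' Projects every track point onto the reference polyline and assigns it the
#' along-course distance of its projection, accumulated over laps.  The
#' projection is forward-monotonic: candidate segments are restricted to a
#' window from `backtrack_tol` behind to `lookahead` ahead of the current
#' along-course position, which resolves self-crossing and out-and-back
#' courses; among equally near candidates the smallest along-course advance
#' wins.
#'
#' The raw projected distances are smoothed with a centred rolling mean of
#' `smooth_window` samples (edge samples kept raw) and made non-decreasing;
#' instantaneous speed is the central difference of the smoothed distance,
#' median-filtered over 3 samples.
#'
#' @param track a `ski_track` (see [read_track()]).
#' @param reference a `course_reference`.
#' @param gate maximum allowed distance (m) from track point to reference
#'   before mapping aborts with an error naming the sample (default 30).
#' @param backtrack_tol allowed apparent backtrack, m (default 5).
#' @param lookahead forward search window, m (default 50).
#' @param smooth_window rolling-mean window, samples (odd; default 3).
#' @param max_gap longest sampling gap (s) bridged by interpolation before
#'   the affected lap is flagged (default 30).
#' @return data.frame of class `mapped_track` with columns `time`,
#'   `course_distance` (smoothed, non-decreasing, m), `dist_raw` and `speed`
#'   (m/s); attributes `lap_length` and `gap_flags` (times of gaps exceeding
#'   `max_gap`).
#' @export
map_to_course <- function(track, reference, gate = 30, backtrack_tol = 5,
                          lookahead = 50, smooth_window = 3, max_gap = 30) {
  stopifnot(inherits(reference, "course_reference"))
  origin <- attr(reference, "origin")
  lap <- attr(reference, "lap_length")
  rxy <- local_xy(reference$lat, reference$lon, origin)
  txy <- local_xy(track$lat, track$lon, origin)
  n_seg <- nrow(reference) - 1L
  ax <- rxy$x[-(n_seg + 1L)]; ay <- rxy$y[-(n_seg + 1L)]
  bx <- rxy$x[-1L]; by <- rxy$y[-1L]
  seg_d0 <- reference$dist[-(n_seg + 1L)]
  seg_len <- diff(reference$dist)

  n <- nrow(track)
  raw <- numeric(n)
  p <- NA_real_  # current cumulative along-course anchor
  for (i in seq_len(n)) {
    if (i == 1L) {
      pr <- project_on_segments(txy$x[i], txy$y[i], ax, ay, bx, by)
      dmin <- sqrt(min(pr$d2))
      if (dmin > gate)
        stop(sprintf("sample %d is %.1f m from the reference (gate %.0f m)",
                     i, dmin, gate))
      # among near-tied candidates (closed loops tie the first and last
      # segment at the start line) anchor nearest the reference start,
      # allowing a slightly negative start offset behind the line
      near <- which(sqrt(pr$d2) <= dmin + 1)
      cand <- seg_d0[near] + pr$t[near] * seg_len[near]
      off0 <- ((cand + lap / 2) %% lap) - lap / 2
      j <- near[which.min(abs(off0))]
      raw[i] <- ((seg_d0[j] + pr$t[j] * seg_len[j] + lap / 2) %% lap) - lap / 2
      p <- raw[i]
      next
    }
    p_mod <- p %% lap
    # signed lap-relative offset of each segment start from the anchor
    off <- ((seg_d0 - p_mod + lap / 2) %% lap) - lap / 2
    keep <- off >= -(backtrack_tol + seg_len + 1) & off <= lookahead
    if (!any(keep)) keep <- rep(TRUE, n_seg)  # degenerate tiny course
    pr <- project_on_segments(txy$x[i], txy$y[i], ax[keep], ay[keep],
                              bx[keep], by[keep])
    cum_cand <- p + off[keep] + pr$t * seg_len[keep]
    ok <- cum_cand >= p - backtrack_tol & cum_cand <= p + lookahead
    if (!any(ok)) ok <- rep(TRUE, length(cum_cand))
    d2 <- ifelse(ok, pr$d2, Inf)
    best <- which(d2 <= min(d2) + 1e-9)
    j <- best[which.min(cum_cand[best])]  # tie: smallest advance
    if (sqrt(d2[j]) > gate)
      stop(sprintf("sample %d is %.1f m from the reference (gate %.0f m)",
                   i, sqrt(d2[j]), gate))
    raw[i] <- cum_cand[j]
    p <- max(p, cum_cand[j])
  }

  sm <- roll_mean_keep_edges(raw, smooth_window)
  mono <- cummax(sm)
  spd <- central_speed(mono, track$time)
  gaps <- track$time[c(FALSE, diff(track$time) > max_gap)]
  structure(data.frame(time = track$time, course_distance = mono,
                       dist_raw = raw, speed = spd),
            lap_length = lap, gap_flags = gaps,
            class = c("mapped_track", "data.frame"))
}

# centred rolling mean, raw values kept where the window is incomplete
roll_mean_keep_edges <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  n <- length(x)
  out <- x
  idx <- (h + 1L):(n - h)
  out[idx] <- (cs[idx + h + 1L] - cs[idx - h]) / w
  out
}

central_speed <- function(d, t) {
  n <- length(d)
  if (n < 2L) return(rep(0, n))
  v <- numeric(n)
  v[1] <- (d[2] - d[1]) / (t[2] - t[1])
  v[n] <- (d[n] - d[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) v[2:(n - 1)] <- (d[3:n] - d[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  stats::runmed(pmax(v, 0), 3)
}

#' Virtual split times over a sectioned course
#'
#' Boundary-crossing times are obtained by linear interpolation of the mapped
#' along-course distance between adjacent samples — virtual split times, in
#' place of physical timing gates.  Within a lap, the exit time of one
#' section is by construction the entry time of the next, so per-lap section
#' durations sum exactly to the lap traversal time.
#'
#' @param mapped a `mapped_track` from [map_to_course()].
#' @param course a `course_profile`; its lap length must match the
#'   reference the track was mapped on.
#' @return data.frame of class `split_table` with columns `lap`, `section`,
#'   `terrain`, `entry_time`, `exit_time`, `duration` (s), `length` (m) and
#'   `mean_speed` (m/s).  Sections never entered keep `NA` times and are
#'   listed in the `missing` attribute (with a warning).
#' @export
virtual_splits <- function(mapped, course) {
  stopifnot(inherits(mapped, "mapped_track"), inherits(course, "course_profile"))
  lap_len <- lap_length(course)
  if (abs(lap_len - attr(mapped, "lap_length")) > 0.5)
    warning("course lap length and mapped reference lap length differ by ",
            sprintf("%.1f m", abs(lap_len - attr(mapped, "lap_length"))))
  d <- mapped$course_distance
  t <- mapped$time
  if (floor((max(d) + 1e-9) / lap_len) < 1L)
    stop("mapped track does not cover a full lap (",
         sprintf("%.0f of %.0f m)", max(d), lap_len))
  # include a partially covered final lap: its unreached sections are
  # reported as missing splits rather than dropped
  n_l <- min(as.integer(ceiling((max(d) - 1e-9) / lap_len)), n_laps(course))

  rows <- expand.grid(section = seq_len(nrow(course)), lap = seq_len(n_l))
  bound_entry <- (rows$lap - 1) * lap_len + course$start[rows$section]
  bound_exit <- (rows$lap - 1) * lap_len + course$end[rows$section]
  entry <- cross_times(d, t, bound_entry)
  exit <- cross_times(d, t, bound_exit)
  duration <- exit - entry
  out <- data.frame(lap = rows$lap,
                    section = course$label[rows$section],
                    terrain = course$terrain[rows$section],
                    entry_time = entry, exit_time = exit,
                    duration = duration,
                    length = course$length[rows$section],
                    grade = course$grade[rows$section],
                    mean_speed = course$length[rows$section] / duration)
  missing <- out$section[is.na(out$duration)]
  if (length(missing))
    warning("section(s) never entered: ",
            paste(unique(missing), collapse = ", "))
  structure(out, missing = unique(missing), lap_length = lap_len,
            class = c("split_table", "data.frame"))
}

# First time the non-decreasing distance series reaches each value.
# Boundaries falling just outside the sampled range (noise offsets the
# first sample; recording may stop at the line) are recovered by linear
# extrapolation with the local slope, up to tol metres.
cross_times <- function(d, t, values, tol = 10) {
  keep <- !duplicated(d)  # earliest time at each distance plateau
  dk <- d[keep]; tk <- t[keep]
  out <- stats::approx(dk, tk, xout = values, method = "linear",
                       rule = 1, ties = "ordered")$y
  n <- length(dk)
  if (n >= 2L) {
    lo <- is.na(out) & values < dk[1] & values >= dk[1] - tol
    if (any(lo)) {
      s1 <- (dk[2] - dk[1]) / (tk[2] - tk[1])
      if (s1 > 0) out[lo] <- tk[1] + (values[lo] - dk[1]) / s1
    }
    hi <- is.na(out) & values > dk[n] & values <= dk[n] + tol
    if (any(hi)) {
      s2 <- (dk[n] - dk[n - 1]) / (tk[n] - tk[n - 1])
      if (s2 > 0) out[hi] <- tk[n] + (values[hi] - dk[n]) / s2
    }
  }
  out
}

#' Mean speed of a section traversal
#'
#' @param length section length in metres.
#' @param duration traversal time in seconds (> 0).
#' @return speed in m/s.
#' @examples
#' section_speed(348, 139.2)
#' @export
section_speed <- function(length, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("section duration must be finite and > 0")
  length / duration
}

#' Share of session time per terrain type
#'
#' @param splits a `split_table`.
#' @param course the matching `course_profile` (used only to fix the terrain
#'   ordering; may be omitted).
#' @return named numeric vector of percentages over uphill/flat/downhill;
#'   unrounded values sum to 100.
#' @export
time_in_terrain <- function(splits, course = NULL) {
  stopifnot(inherits(splits, "split_table"))
  ok <- !is.na(splits$duration)
  if (!any(ok)) stop("split table has no completed sections")
  agg <- tapply(splits$duration[ok], splits$terrain[ok], sum)
  out <- c(uphill = 0, flat = 0, downhill = 0)
  out[names(agg)] <- agg
  100 * out / sum(out)
}

#' @export
print.split_table <- function(x, ...) {
  cat(sprintf("Virtual splits: %d laps x %d sections\n",
              max(x$lap), length(unique(x$section))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
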