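# Shared fixtures: tiny courses, tracks laid on a reference, and independent
# oracles (brute-force projection, textbook t formulas).

tiny_course <- function(n_laps = 1L) {
  build_course(data.frame(label = c("U1", "F1", "D1"),
                          length = c(100, 150, 120),
                          grade = c(10, 0, -8)),
               n_laps = n_laps)
}

# a ski_track whose points lie exactly on the reference polyline, moving at
# constant speed (m/s), sampled at 1 Hz
track_on_reference <- function(reference, speed = 2.0, t_end = NULL,
                               hr = NA_real_) {
  L <- attr(reference, "lap_length")
  if (is.null(t_end)) t_end <- floor(L / speed)
  t <- seq(0, t_end, by = 1)
  s <- t * speed
  pos <- sitski:::ref_position(reference, pmin(s %% L, L - 1e-9))
  ll <- sitski:::local_latlon(pos$x, pos$y, attr(reference, "origin"))
  out <- data.frame(time = t, lat = ll$lat, lon = ll$lon, ele = pos$ele,
                    hr = hr)
  class(out) <- c("ski_track", "data.frame")
  out
}

# brute-force nearest-point oracle: densify the polyline and take the
# nearest sample
brute_force_project <- function(px, py, vx, vy, dist, step = 0.01) {
  best_d2 <- Inf; best_s <- NA_real_
  for (j in seq_len(length(vx) - 1L)) {
    seg_len <- sqrt((vx[j + 1] - vx[j])^2 + (vy[j + 1] - vy[j])^2)
    tt <- seq(0, 1, by = step / max(seg_len, step))
    qx <- vx[j] + tt * (vx[j + 1] - vx[j])
    qy <- vy[j] + tt * (vy[j + 1] - vy[j])
    d2 <- (px - qx)^2 + (py - qy)^2
    k <- which.min(d2)
    if (d2[k] < best_d2) {
      best_d2 <- d2[k]
      best_s <- dist[j] + tt[k] * (dist[j + 1] - dist[j])
    }
  }
  list(s = best_s, d = sqrt(best_d2))
}

# textbook t formulas, independent of stats::t.test
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# recall/precision of detected against true plant times
match_plants <- function(detected, truth, tol = 0.15) {
  if (length(truth) == 0L)
    return(list(recall = NA_real_, precision = NA_real_))
  if (length(detected) == 0L) return(list(recall = 0, precision = NA_real_))
  hits <- outer(detected, truth, function(a, b) abs(a - b) <= tol)
  list(recall = mean(apply(hits, 2, any)),
       precision = mean(apply(hits, 1, any)))
}
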