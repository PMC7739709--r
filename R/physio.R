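#' Athlete profile
#'
#' Identity and physiology constants for one athlete.  Only `hr_peak` enters
#' computations (relative heart-rate intensity); masses feed the power
#' parameters; other entries (class label, VO2peak, ...) are carried as
#' metadata.
#'
#' @param hr_peak laboratory peak heart rate, beats/min (> 0).
#' @param body_mass body mass, kg.
#' @param equipment_mass total sit-ski + poles + skis mass, kg.
#' @param ... further metadata stored verbatim.
#' @return an object of class `athlete_profile`; `mass_total` is the sum of
#'   body and equipment mass.
#' @examples
#' athlete_profile(hr_peak = 195, body_mass = 67.5, equipment_mass = 4.2)
#' @export
athlete_profile <- function(hr_peak, body_mass = NA_real_,
                            equipment_mass = NA_real_, ...) {
  if (!is.numeric(hr_peak) || hr_peak <= 0) stop("hr_peak must be > 0")
  structure(list(hr_peak = hr_peak, body_mass = body_mass,
                 equipment_mass = equipment_mass,
                 mass_total = body_mass + equipment_mass,
                 metadata = list(...)),
            class = "athlete_profile")
}

#' Mean relative heart rate per course section
#'
#' For every completed split, the time-weighted mean heart rate over the
#' section's `[entry, exit]` window (trapezoidal integration over the
#' samples inside the window) expressed as percent of peak heart rate.
#' Sections where fewer than 80% of the expected samples carry heart rate
#' are flagged; sections with no usable heart rate get `NA` with a warning.
#'
#' @param track a `ski_track` with an `hr` column.
#' @param splits a `split_table`.
#' @param profile an [athlete_profile()] (supplies `hr_peak`).
#' @param min_coverage minimum fraction of in-window samples with heart
#'   rate (default 0.8).
#' @return `splits` with added columns `hr_mean`, `pct_hr_peak`,
#'   `hr_coverage` and `hr_flagged`.
#' @export
hr_percent_by_section <- function(track, splits, profile, min_coverage = 0.8) {
  stopifnot(inherits(splits, "split_table"), inherits(profile, "athlete_profile"))
  n <- nrow(splits)
  hr_mean <- cov <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- splits$entry_time[i]; x <- splits$exit_time[i]
    if (is.na(e) || is.na(x)) next
    win <- track$time >= e & track$time <= x
    if (!any(win)) next
    cov[i] <- mean(!is.na(track$hr[win]))
    ok <- win & !is.na(track$hr)
    tt <- track$time[ok]; hh <- track$hr[ok]
    if (length(tt) >= 2L) {
      hr_mean[i] <- sum(diff(tt) * (hh[-1] + hh[-length(hh)]) / 2) /
        (tt[length(tt)] - tt[1])
    } else if (length(tt) == 1L) hr_mean[i] <- hh
  }
  if (all(is.na(hr_mean)))
    warning("no heart-rate data in any section window")
  splits$hr_mean <- hr_mean
  splits$pct_hr_peak <- percent_of_max(hr_mean, profile$hr_peak)
  splits$hr_coverage <- cov
  splits$hr_flagged <- is.na(cov) | cov < min_coverage
  splits
}

#' Paired-samples t test on matched section values
#'
#' Classical paired t test (two-sided) on matched per-section values from
#' two conditions, e.g. high- vs low-intensity sessions matched by
#' section x lap.  All-equal differences (zero within-pair variance) are a
#' degenerate case: reported as such rather than as an error.
#'
#' @param a,b numeric vectors of equal length (>= 2), matched pairwise.
#' @return an object of class `ski_ttest`: list with `method`, `t`, `df`,
#'   `p`, `mean_diff`, `n` and `degenerate`.
#' @examples
#' compare_paired(c(5, 6, 7, 8), c(4, 6, 6, 7))
#' @export
compare_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired comparison needs equal lengths")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(method = "paired", t = NA_real_, df = length(d) - 1,
                          p = NA_real_, mean_diff = mean(d), n = length(d),
                          degenerate = TRUE),
                     class = "ski_ttest"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(method = "paired", t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_diff = unname(tt$estimate), n = length(d),
                 degenerate = FALSE),
            class = "ski_ttest")
}

#' Independent-samples t test between terrains
#'
#' Welch (unequal-variance) form by default; two-sided.  Two zero-variance
#' groups are a degenerate case, reported rather than raised.
#'
#' @param a,b numeric vectors (each >= 2 non-missing values).
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return an object of class `ski_ttest` (see [compare_paired()]); for the
#'   independent test `mean_diff` is `mean(a) - mean(b)`.
#' @examples
#' compare_independent(c(3, 4, 5), c(5, 6, 7))
#' @export
compare_independent <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(structure(list(method = "independent", t = NA_real_, df = NA_real_,
                          p = NA_real_, mean_diff = mean(a) - mean(b),
                          n = c(length(a), length(b)), degenerate = TRUE),
                     class = "ski_ttest"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(method = if (var_equal) "independent (pooled)" else "independent (Welch)",
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(a) - mean(b),
                 n = c(length(a), length(b)), degenerate = FALSE),
            class = "ski_ttest")
}

#' @export
print.ski_ttest <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s t test: degenerate (zero variance), mean difference %.4g\n",
                x$method, x$mean_diff))
  } else {
    cat(sprintf("%s t test: t = %.4f, df = %.2f, p = %.4g, mean diff = %.4g\n",
                x$method, x$t, x$df, x$p, x$mean_diff))
  }
  invisible(x)
}

#' Terrain-level session summary
#'
#' Combines the per-section analyses into one row per terrain plus an
#' overall row: time share, mean speed (and % of maximal speed where a
#' maximal-speed test exists for that terrain), mean external power (and %
#' of maximal power), poling cycle rate and length (mean and pooled SD) and
#' mean % of peak heart rate.  Components that were not computed simply
#' leave their columns `NA`; the `notes` attribute records which.
#'
#' @param splits a `split_table`, ideally after [hr_percent_by_section()]
#'   and [power_by_section()].
#' @param cycle_stats result of [section_cycle_stats()], or `NULL`.
#' @param vmax named numeric, maximal speed (m/s) per terrain (e.g.
#'   `c(uphill = 4.0, flat = 6.2)`), or `NULL`.
#' @param pmax named numeric, maximal power (W) per terrain, or `NULL`.
#' @param intensity optional session label (e.g. `"HIT"`, `"LIT"`).
#' @return data.frame of class `terrain_summary` with one row per terrain
#'   (uphill, flat, downhill) plus `"overall"`.
#' @export
build_summary <- function(splits, cycle_stats = NULL, vmax = NULL,
                          pmax = NULL, intensity = NA_character_) {
  stopifnot(inherits(splits, "split_table"))
  terrains <- c("uphill", "flat", "downhill")
  ok <- !is.na(splits$duration)
  notes <- character(0)
  shares <- time_in_terrain(splits)

  one <- function(ter) {
    s <- splits[ok & splits$terrain == ter, , drop = FALSE]
    if (nrow(s) == 0L)
      return(data.frame(terrain = ter, time_share_pct = 0, mean_speed = NA,
                        pct_vmax = NA, power_W = NA, pct_pmax = NA,
                        cycle_rate = NA, cycle_rate_sd = NA,
                        cycle_length = NA, cycle_length_sd = NA,
                        pct_hr_peak = NA))
    spd <- sum(s$length) / sum(s$duration)
    pw <- if ("P_tot" %in% names(s) && any(!is.na(s$P_tot)))
      stats::weighted.mean(s$P_tot, s$duration, na.rm = TRUE) else NA_real_
    hr <- if ("pct_hr_peak" %in% names(s) && any(!is.na(s$pct_hr_peak)))
      stats::weighted.mean(s$pct_hr_peak, s$duration, na.rm = TRUE) else NA_real_
    cr <- cl <- c(NA_real_, NA_real_)
    if (!is.null(cycle_stats)) {
      row <- cycle_stats$terrain[cycle_stats$terrain$terrain == ter, ]
      if (nrow(row) == 1L && row$n > 0L) {
        cr <- c(row$rate_mean, row$rate_sd)
        cl <- c(row$length_mean, row$length_sd)
      }
    }
    data.frame(terrain = ter, time_share_pct = shares[[ter]],
               mean_speed = spd,
               pct_vmax = if (!is.null(vmax) && ter %in% names(vmax))
                 percent_of_max(spd, vmax[[ter]]) else NA_real_,
               power_W = pw,
               pct_pmax = if (!is.null(pmax) && ter %in% names(pmax) &&
                              !is.na(pw)) percent_of_max(pw, pmax[[ter]])
                 else NA_real_,
               cycle_rate = cr[1], cycle_rate_sd = cr[2],
               cycle_length = cl[1], cycle_length_sd = cl[2],
               pct_hr_peak = hr)
  }
  out <- do.call(rbind, lapply(terrains, one))

  s <- splits[ok, , drop = FALSE]
  overall <- data.frame(
    terrain = "overall", time_share_pct = 100,
    mean_speed = sum(s$length) / sum(s$duration),
    pct_vmax = NA_real_,
    power_W = if ("P_tot" %in% names(s) && any(!is.na(s$P_tot)))
      stats::weighted.mean(s$P_tot, s$duration, na.rm = TRUE) else NA_real_,
    pct_pmax = NA_real_,
    cycle_rate = NA_real_, cycle_rate_sd = NA_real_,
    cycle_length = NA_real_, cycle_length_sd = NA_real_,
    pct_hr_peak = if ("pct_hr_peak" %in% names(s) && any(!is.na(s$pct_hr_peak)))
      stats::weighted.mean(s$pct_hr_peak, s$duration, na.rm = TRUE)
      else NA_real_)
  out <- rbind(out, overall)
  if (!("P_tot" %in% names(splits))) notes <- c(notes, "no power rows")
  if (!("pct_hr_peak" %in% names(splits))) notes <- c(notes, "no heart-rate rows")
  if (is.null(cycle_stats)) notes <- c(notes, "no cycle statistics")
  rownames(out) <- NULL
  structure(out, intensity = intensity, notes = notes,
            class = c("terrain_summary", "data.frame"))
}

#' @export
print.terrain_summary <- function(x, ...) {
  lab <- attr(x, "intensity")
  cat(sprintf("Session summary%s\n",
              if (!is.na(lab)) paste0(" (", lab, ")") else ""))
  print.data.frame(x, digits = 3, row.names = FALSE)
  nt <- attr(x, "notes")
  if (length(nt)) cat("notes:", paste(nt, collapse = "; "), "\n")
  invisible(x)
}
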