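#' Read or write a reference polyline as CSV
#'
#' The reference polyline CSV dialect has columns
#' `lat, lon, ele_m, dist_m` (one row per vertex, `dist_m` non-decreasing
#' along-course distance).  On reading, the local projection origin is the
#' polyline centroid.
#'
#' @param path CSV path.
#' @return a `course_reference`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("lat", "lon", "ele_m", "dist_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference CSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(df$dist_m)) stop("reference dist_m must be non-decreasing")
  new_reference(df$lat, df$lon, df$ele_m, df$dist_m,
                geo_origin(df$lat, df$lon))
}

#' @rdname read_reference
#' @param reference a `course_reference`.
#' @export
write_reference <- function(reference, path) {
  utils::write.csv(data.frame(lat = reference$lat, lon = reference$lon,
                              ele_m = reference$ele, dist_m = reference$dist),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a session configuration file
#'
#' JSON schema (all paths relative to the config file's directory):
#' \preformatted{
#' {
#'   "paths":    {"track": "...", "imu": "...",        # imu optional
#'                "course": "...", "reference": "..."},
#'   "athlete":  {"hr_peak": 195, "body_mass": 67.5, "equipment_mass": 4.2},
#'   "power":    {"mu_s": 0.036, "rho": 1.29, "drag_area": 0.338,
#'                "drag_by_terrain": {"uphill": 0.338, "flat": 0.336},
#'                "include_downhill": false},
#'   "detector": {"gyro_peak_min": 100, ...},          # optional overrides
#'   "analysis": {"intensity": "HIT", "clock_offset": 0,
#'                "vmax": {"uphill": 4.0, "flat": 6.2},
#'                "pmax": {"uphill": 342, "flat": 252}}
#' }
#' }
#'
#' @param path path to the JSON config.
#' @return a validated `session_config` list.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  if (is.null(cfg$paths) || is.null(cfg$paths$track) ||
      is.null(cfg$paths$course) || is.null(cfg$paths$reference))
    stop("config error: paths must name track, course and reference files")
  for (k in names(cfg$paths)) {
    p <- cfg$paths[[k]]
    if (!file.exists(p)) {
      p2 <- file.path(base, p)
      if (!file.exists(p2))
        stop("config error: ", k, " file not found: ", p)
      cfg$paths[[k]] <- p2
    }
  }
  if (is.null(cfg$athlete$hr_peak))
    stop("config error: athlete$hr_peak is required")
  if (is.null(cfg$power$mu_s))
    stop("config error: power$mu_s is required")
  structure(cfg, class = "session_config")
}

round6 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Run the full session analysis pipeline
#'
#' Orchestrates every stage — read inputs, map the track onto the reference,
#' compute virtual splits and section speeds, decompose power, detect pole
#' plants and derive cycle statistics (if an IMU stream is configured),
#' attach heart-rate intensity and build the terrain summary — and writes
#' the report bundle: `splits.csv` (splits + power + heart rate columns),
#' `cycles.csv`, `summary.csv` and `report.txt`, all with fixed column
#' order and 6-significant-digit floats for reproducible diffs.
#'
#' Stage failures abort with a stage-named error and remove any partially
#' written outputs.
#'
#' @param config a `session_config` (see [read_session_config()]) or the
#'   path to one.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns the results only.
#' @return invisibly, a list with `splits`, `cycles`, `cycle_stats`,
#'   `summary` and `files` (paths written).
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_session_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  course <- stage("course", read_course(config$paths$course))
  reference <- stage("reference", read_reference(config$paths$reference))
  track <- stage("track", read_track(config$paths$track))
  imu <- NULL
  if (!is.null(config$paths$imu))
    imu <- stage("imu", read_imu(config$paths$imu))

  mapped <- stage("mapping", map_to_course(track, reference))
  splits <- stage("splits", virtual_splits(mapped, course))

  profile <- athlete_profile(hr_peak = config$athlete$hr_peak,
                             body_mass = config$athlete$body_mass,
                             equipment_mass = config$athlete$equipment_mass)
  pw_cfg <- config$power
  params <- power_params(
    mass_total = if (!is.null(pw_cfg$mass_total)) pw_cfg$mass_total
                 else profile$mass_total,
    mu_s = pw_cfg$mu_s,
    rho = if (is.null(pw_cfg$rho)) 1.29 else pw_cfg$rho,
    drag_area = if (is.null(pw_cfg$drag_area)) 0.338 else pw_cfg$drag_area)
  splits <- stage("power", power_by_section(
    splits, params, drag_by_terrain = unlist(pw_cfg$drag_by_terrain),
    include_downhill = isTRUE(pw_cfg$include_downhill)))
  splits <- stage("heart rate",
                  hr_percent_by_section(track, splits, profile))

  cycles <- NULL; cycle_stats <- NULL
  if (!is.null(imu)) {
    det <- do.call(detector_config, as.list(config$detector))
    off <- config$analysis$clock_offset
    cycles <- stage("cycles", {
      plants <- detect_pole_plants(imu, det)
      cyc <- cycles_from_plants(plants, det)
      assign_cycle_length(cyc, splits,
                          clock_offset = if (is.null(off)) 0 else off)
    })
    cycle_stats <- stage("cycle stats", section_cycle_stats(cycles))
  }

  vmax <- unlist(config$analysis$vmax)
  pmax <- unlist(config$analysis$pmax)
  intensity <- config$analysis$intensity
  summary_tab <- stage("summary", build_summary(
    splits, cycle_stats = cycle_stats, vmax = vmax, pmax = pmax,
    intensity = if (is.null(intensity)) NA_character_ else intensity))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(out_dir,
                       c("splits.csv", "cycles.csv", "summary.csv",
                         "report.txt"))
    names(files) <- c("splits", "cycles", "summary", "report")
    on_fail <- function(e) { unlink(files); stop(e) }
    tryCatch({
      utils::write.csv(round6(as.data.frame(splits)), files[["splits"]],
                       row.names = FALSE)
      if (!is.null(cycles))
        utils::write.csv(round6(as.data.frame(cycles)), files[["cycles"]],
                         row.names = FALSE)
      else files <- files[names(files) != "cycles"]
      utils::write.csv(round6(as.data.frame(summary_tab)),
                       files[["summary"]], row.names = FALSE)
      writeLines(format_report(summary_tab, splits, cycle_stats),
                 files[["report"]])
    }, error = on_fail)
  }
  invisible(list(splits = splits, cycles = cycles, cycle_stats = cycle_stats,
                 summary = summary_tab, files = files))
}

format_report <- function(summary_tab, splits, cycle_stats) {
  lab <- attr(summary_tab, "intensity")
  ok <- !is.na(splits$duration)
  out <- c(
    sprintf("Session report%s", if (!is.na(lab)) paste0(" - ", lab) else ""),
    sprintf("Total time: %.1f s over %d laps",
            sum(splits$duration[ok]), max(splits$lap)),
    sprintf("Mean speed: %.2f m/s",
            sum(splits$length[ok]) / sum(splits$duration[ok])),
    "", "Terrain summary:",
    utils::capture.output(print.data.frame(round6(as.data.frame(summary_tab)),
                                           row.names = FALSE)))
  if (!is.null(cycle_stats)) {
    acc_n <- sum(cycle_stats$terrain$n)
    out <- c(out, "", sprintf("Accepted poling cycles: %d", acc_n))
  }
  miss <- attr(splits, "missing")
  if (length(miss))
    out <- c(out, "", paste("WARNING: sections never entered:",
                            paste(miss, collapse = ", ")))
  out
}

#' End-to-end demonstration on paper-calibrated synthetic sessions
#'
#' Simulates a high-intensity and a low-intensity session on the
#' demonstration course, runs the complete analysis on both (mapping,
#' splits, power, cycles, heart rate, summary) and compares them with
#' paired t tests on matched section x lap values of speed, cycle rate,
#' cycle length and % of peak heart rate.  All randomness flows from
#' `seed`.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory; bundles are written under
#'   `HIT/` and `LIT/` subdirectories plus `comparison.csv`.
#' @param n_laps laps per session (default 3).
#' @return list with `hit`, `lit` (each as [run_analysis()] results),
#'   `comparison` (data.frame of paired tests) and `sessions` (the two
#'   `synth_session` objects).
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_laps = 3L) {
  course <- demo_course(n_laps = n_laps)
  ses <- list(
    HIT = simulate_session(synth_config("HIT", course = course, seed = seed)),
    LIT = simulate_session(synth_config("LIT", course = course,
                                        seed = seed + 1L)))
  profile <- athlete_profile(hr_peak = 195, body_mass = 67.5,
                             equipment_mass = 4.2)
  params <- power_params(mass_total = profile$mass_total, mu_s = 0.036)
  det <- detector_config()

  analyse <- function(s, label) {
    mapped <- map_to_course(s$track, s$reference)
    splits <- virtual_splits(mapped, course)
    splits <- power_by_section(splits, params,
                               drag_by_terrain = c(uphill = 0.338,
                                                   flat = 0.336))
    splits <- hr_percent_by_section(s$track, splits, profile)
    plants <- detect_pole_plants(s$imu, det)
    cycles <- assign_cycle_length(cycles_from_plants(plants, det), splits)
    stats <- section_cycle_stats(cycles)
    list(splits = splits, cycles = cycles, cycle_stats = stats,
         summary = build_summary(splits, cycle_stats = stats,
                                 intensity = label))
  }
  res <- list(hit = analyse(ses$HIT, "HIT"), lit = analyse(ses$LIT, "LIT"))

  key <- function(sp) paste(sp$lap, sp$section)
  a <- res$hit$splits; b <- res$lit$splits
  stopifnot(identical(key(a), key(b)))
  per_section_rate <- function(cyc, sp) {
    acc <- cyc[cyc$accepted & !is.na(cyc$section), ]
    k <- paste(acc$lap, acc$section)
    r <- tapply(acc$rate, k, mean)[key(sp)]
    l <- tapply(acc$length, k, mean)[key(sp)]
    list(rate = unname(r), length = unname(l))
  }
  ra <- per_section_rate(res$hit$cycles, a)
  rb <- per_section_rate(res$lit$cycles, b)

  vars <- list(speed = list(a$mean_speed, b$mean_speed),
               cycle_rate = list(ra$rate, rb$rate),
               cycle_length = list(ra$length, rb$length),
               pct_hr_peak = list(a$pct_hr_peak, b$pct_hr_peak))
  comparison <- do.call(rbind, lapply(names(vars), function(v) {
    x <- vars[[v]][[1]]; y <- vars[[v]][[2]]
    keep <- !is.na(x) & !is.na(y)
    tt <- compare_paired(x[keep], y[keep])
    data.frame(variable = v, n = tt$n, mean_hit = mean(x[keep]),
               mean_lit = mean(y[keep]), mean_diff = tt$mean_diff,
               t = tt$t, df = tt$df, p = tt$p)
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in c("hit", "lit")) {
      d <- file.path(out_dir, toupper(lab))
      dir.create(d, showWarnings = FALSE)
      r <- res[[lab]]
      utils::write.csv(round6(as.data.frame(r$splits)),
                       file.path(d, "splits.csv"), row.names = FALSE)
      utils::write.csv(round6(as.data.frame(r$cycles)),
                       file.path(d, "cycles.csv"), row.names = FALSE)
      utils::write.csv(round6(as.data.frame(r$summary)),
                       file.path(d, "summary.csv"), row.names = FALSE)
    }
    utils::write.csv(round6(comparison), file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  invisible(list(hit = res$hit, lit = res$lit, comparison = comparison,
                 sessions = ses))
}
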