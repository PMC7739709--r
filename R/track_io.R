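#' Read a GNSS/heart-rate track
#'
#' Reads a recorded track into a data.frame of track points.  Supported
#' formats: GPX 1.1 (`trkpt` elements, heart rate from the Garmin
#' TrackPointExtension), TCX (`Trackpoint` elements) and a documented CSV
#' dialect with columns `time_s, lat, lon, ele_m, hr_bpm`.
#'
#' Points are sorted by time, duplicate timestamps are collapsed (first
#' occurrence kept) and times are re-expressed as seconds from the first
#' sample.  Heart rate is optional; missing values are `NA`.
#'
#' @param path path to the track file.
#' @param format one of `"gpx"`, `"tcx"`, `"csv"`; default guesses from the
#'   file extension.
#' @return data.frame of class `ski_track` with columns `time` (s from start),
#'   `lat`, `lon` (deg), `ele` (m) and `hr` (beats/min, may be `NA`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time_s = 0:2, lat = 63.4, lon = 10.4,
#'                      ele_m = 100, hr_bpm = 120), f, row.names = FALSE)
#' read_track(f)
#' @export
read_track <- function(path, format = c("auto", "gpx", "tcx", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("track file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gpx = "gpx", tcx = "tcx", csv = "csv",
                     stop("cannot guess track format from extension '.",
                          ext, "'; pass format="))
  }
  pts <- switch(format,
                gpx = read_track_gpx(path),
                tcx = read_track_tcx(path),
                csv = read_track_csv(path))
  if (nrow(pts) == 0L) stop("empty track: ", path)
  pts <- pts[order(pts$time), , drop = FALSE]
  pts <- pts[!duplicated(pts$time), , drop = FALSE]
  if (any(abs(pts$lat) > 90) || any(abs(pts$lon) > 180))
    stop("track has coordinates outside valid lat/lon ranges")
  pts$time <- pts$time - pts$time[1]
  rownames(pts) <- NULL
  class(pts) <- c("ski_track", "data.frame")
  pts
}

parse_utc <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) stop("unparseable ISO-8601 timestamp(s) in track")
  as.numeric(t)
}

read_track_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  tp <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(tp) == 0L) stop("no track points found in GPX file: ", path)
  time_nodes <- xml2::xml_find_first(tp, "./time")
  ele <- xml2::xml_double(xml2::xml_find_first(tp, "./ele"))
  hr <- xml2::xml_double(xml2::xml_find_first(tp, ".//*[local-name()='hr']"))
  data.frame(time = parse_utc(xml2::xml_text(time_nodes)),
             lat = as.numeric(xml2::xml_attr(tp, "lat")),
             lon = as.numeric(xml2::xml_attr(tp, "lon")),
             ele = ele, hr = hr)
}

read_track_tcx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  tp <- xml2::xml_find_all(doc, ".//Trackpoint")
  if (length(tp) == 0L) stop("no track points found in TCX file: ", path)
  lat <- xml2::xml_double(xml2::xml_find_first(tp, "./Position/LatitudeDegrees"))
  lon <- xml2::xml_double(xml2::xml_find_first(tp, "./Position/LongitudeDegrees"))
  keep <- !is.na(lat) & !is.na(lon)   # TCX may carry HR-only points
  data.frame(
    time = parse_utc(xml2::xml_text(xml2::xml_find_first(tp, "./Time")))[keep],
    lat = lat[keep], lon = lon[keep],
    ele = xml2::xml_double(xml2::xml_find_first(tp, "./AltitudeMeters"))[keep],
    hr = xml2::xml_double(xml2::xml_find_first(tp, "./HeartRateBpm/Value"))[keep])
}

read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "lat", "lon", "ele_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track CSV missing required column(s): ", paste(miss, collapse = ", "))
  data.frame(time = as.numeric(df$time_s), lat = as.numeric(df$lat),
             lon = as.numeric(df$lon), ele = as.numeric(df$ele_m),
             hr = if ("hr_bpm" %in% names(df)) as.numeric(df$hr_bpm) else NA_real_)
}

#' Write a track to GPX 1.1 or CSV
#'
#' GPX output stores heart rate in the Garmin TrackPointExtension so that
#' `read_track()` round-trips it.  Times are written as UTC timestamps
#' starting at an arbitrary epoch (2024-01-01); only time differences are
#' meaningful to the analysis.
#'
#' @param track a `ski_track` data.frame (see [read_track()]).
#' @param path output path; format from extension (`.gpx` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(data.frame(time_s = track$time, lat = track$lat,
                                lon = track$lon, ele_m = track$ele,
                                hr_bpm = track$hr),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  if (ext != "gpx") stop("write_track supports .gpx and .csv, got .", ext)
  epoch <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
  stamp <- format(epoch + track$time, "%Y-%m-%dT%H:%M:%OS3Z")
  hr_block <- ifelse(is.na(track$hr), "",
    sprintf("<extensions><gpxtpx:TrackPointExtension><gpxtpx:hr>%d</gpxtpx:hr></gpxtpx:TrackPointExtension></extensions>",
            as.integer(round(track$hr))))
  pts <- sprintf(
    "      <trkpt lat=\"%.8f\" lon=\"%.8f\"><ele>%.3f</ele><time>%s</time>%s</trkpt>",
    track$lat, track$lon, track$ele, stamp, hr_block)
  xml <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<gpx version=\"1.1\" creator=\"sitski\" ",
           "xmlns=\"http://www.topografix.com/GPX/1/1\" ",
           "xmlns:gpxtpx=\"http://www.garmin.com/xmlschemas/TrackPointExtension/v1\">"),
    "  <trk><name>session</name><trkseg>", pts,
    "  </trkseg></trk>", "</gpx>")
  writeLines(xml, path)
  invisible(path)
}

#' Read or write the wrist IMU CSV dialect
#'
#' The IMU stream is a CSV with columns
#' `time_s, gyro_x, gyro_y, gyro_z, accel_x, accel_y, accel_z`
#' (gyroscope in deg/s, accelerometer in m/s^2), optionally preceded by a
#' `#`-prefixed units header line.  Time must be strictly increasing.
#'
#' @param path path to the IMU CSV file.
#' @return data.frame of class `imu_stream` with the seven columns above
#'   (`time_s` renamed `time`).
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) stop("IMU file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "gyro_x", "gyro_y", "gyro_z",
            "accel_x", "accel_y", "accel_z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("IMU CSV missing required column(s): ", paste(miss, collapse = ", "))
  names(df)[names(df) == "time_s"] <- "time"
  if (is.unsorted(df$time, strictly = TRUE))
    stop("IMU time column must be strictly increasing")
  class(df) <- c("imu_stream", "data.frame")
  df
}

#' @rdname read_imu
#' @param imu an `imu_stream` data.frame.
#' @export
write_imu <- function(imu, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: time_s s, gyro deg/s, accel m/s^2", con)
  df <- as.data.frame(imu)
  names(df)[names(df) == "time"] <- "time_s"
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
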