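#' Build a sectioned course profile
#'
#' A course profile represents one lap of a race or training course as an
#' ordered sequence of contiguous terrain sections, each with an along-surface
#' length and a signed mean grade (rise/run, percent).  Cumulative start/end
#' distances are assigned in order; the lap length defaults to the sum of the
#' section lengths.
#'
#' When `lap_length` is supplied and differs from the arithmetic sum of the
#' section lengths (e.g. to match a published course total), all section
#' lengths are rescaled proportionally so that the sections still partition
#' `[0, lap_length]` exactly.  Grades are never rescaled.
#'
#' @param sections data.frame with columns `label`, `length` (m, > 0) and
#'   `grade` (percent, signed), and optionally `terrain` (one of `"uphill"`,
#'   `"flat"`, `"downhill"`).  When `terrain` is absent it is derived from the
#'   grade via [classify_terrain()].
#' @param n_laps number of laps skied on this course (default 1).
#' @param lap_length optional lap length override in metres; sections are
#'   rescaled proportionally to sum to it.
#' @param flat_band two-element numeric, the grade band (percent) classified
#'   as flat when terrain labels are auto-derived; default `c(-3, 3)`.
#' @return An object of class `course_profile`: a data.frame of sections with
#'   columns `label`, `terrain`, `start`, `end`, `length`, `grade`, and
#'   attributes `lap_length` and `n_laps`.
#' @examples
#' cp <- build_course(data.frame(label = c("A", "B"),
#'                               length = c(100, 50),
#'                               grade = c(8, 0)), n_laps = 3)
#' lap_length(cp)
#' @seealso [demo_course()] for the 16-section demonstration lap,
#'   [terrain_fractions()], [read_course()]
#' @export
build_course <- function(sections, n_laps = 1L, lap_length = NULL,
                         flat_band = c(-3, 3)) {
  sections <- as.data.frame(sections)
  req <- c("label", "length", "grade")
  miss <- setdiff(req, names(sections))
  if (length(miss))
    stop("course sections missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sections) == 0L) stop("course must have at least one section")
  lab <- as.character(sections$label)
  if (anyDuplicated(lab))
    stop("duplicate section label(s): ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  len <- as.numeric(sections$length)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("all section lengths must be finite and > 0")
  grd <- as.numeric(sections$grade)
  if (any(!is.finite(grd))) stop("all section grades must be finite")
  if (!is.numeric(n_laps) || length(n_laps) != 1L || n_laps < 1)
    stop("n_laps must be a single count >= 1")

  if (!is.null(lap_length)) {
    if (!is.numeric(lap_length) || lap_length <= 0)
      stop("lap_length override must be a positive number")
    len <- len * lap_length / sum(len)
  }
  total <- sum(len)

  if ("terrain" %in% names(sections)) {
    ter <- as.character(sections$terrain)
    bad <- setdiff(unique(ter), c("uphill", "flat", "downhill"))
    if (length(bad)) stop("unknown terrain label(s): ", paste(bad, collapse = ", "))
  } else {
    ter <- classify_terrain(grd, flat_band)
  }

  end <- cumsum(len)
  out <- data.frame(label = lab, terrain = ter,
                    start = c(0, end[-length(end)]), end = end,
                    length = len, grade = grd,
                    stringsAsFactors = FALSE)
  structure(out, lap_length = total, n_laps = as.integer(n_laps),
            class = c("course_profile", "data.frame"))
}

#' @rdname build_course
#' @param course a `course_profile`.
#' @export
lap_length <- function(course) attr(course, "lap_length")

#' @rdname build_course
#' @export
n_laps <- function(course) attr(course, "n_laps")

#' Classify a grade into terrain type
#'
#' Sections with a mean grade at or above the upper edge of the flat band are
#' uphill, at or below the lower edge downhill, otherwise flat.  The band is
#' a package choice (sit-ski course flats are near-level; labelled downhills
#' start around -6%), configurable per call.
#'
#' @param grade numeric vector of grades in percent (rise/run x 100, signed).
#' @param flat_band two-element numeric `(lo, hi)` with `lo < 0 < hi`.
#' @return character vector, elements in `"uphill"`, `"flat"`, `"downhill"`.
#' @examples
#' classify_terrain(c(8, -9, 0))
#' @export
classify_terrain <- function(grade, flat_band = c(-3, 3)) {
  if (length(flat_band) != 2L || !(flat_band[1] < 0 && 0 < flat_band[2]))
    stop("flat_band must be (lo, hi) with lo < 0 < hi")
  ifelse(grade >= flat_band[2], "uphill",
         ifelse(grade <= flat_band[1], "downhill", "flat"))
}

#' Terrain composition of a course
#'
#' Percent of the lap length in each terrain type.  Unrounded values sum to
#' exactly 100.
#'
#' @param course a `course_profile`.
#' @return named numeric vector (percent) over `uphill`, `flat`, `downhill`;
#'   terrains absent from the course get 0.
#' @examples
#' terrain_fractions(demo_course())
#' @export
terrain_fractions <- function(course) {
  stopifnot(inherits(course, "course_profile"))
  out <- c(uphill = 0, flat = 0, downhill = 0)
  agg <- tapply(course$length, course$terrain, sum)
  out[names(agg)] <- agg
  100 * out / lap_length(course)
}

#' The 16-section demonstration lap
#'
#' A ~1.9 km competition-style lap used throughout the package examples and
#' tests: four uphill sections (S2, S5, S8, S10; grades 8/14/16/10%), seven
#' flat sections and five downhill sections (grades -9/-10/-7/-6/-10%).  The
#' printed section lengths sum to 1,915 m; pass `lap_length = 1918` to
#' rescale to the surveyed lap total.
#'
#' @param n_laps number of laps (default 3, a 5.75 km session).
#' @param lap_length optional override, see [build_course()].
#' @return a `course_profile`.
#' @export
demo_course <- function(n_laps = 3L, lap_length = NULL) {
  specs <- data.frame(
    label  = paste0("S", 1:16),
    terrain = c("flat", "uphill", "downhill", "flat", "uphill", "downhill",
                "flat", "uphill", "flat", "uphill", "downhill", "flat",
                "downhill", "flat", "downhill", "flat"),
    length = c(91, 348, 56, 112, 54, 76, 117, 33, 90, 157, 113, 82,
               128, 38, 269, 151),
    grade  = c(0, 8, -9, 0, 14, -10, 0, 16, 0, 10, -7, 0, -6, 0, -10, 0),
    stringsAsFactors = FALSE)
  build_course(specs, n_laps = n_laps, lap_length = lap_length)
}

#' Read a course definition file
#'
#' Reads a JSON course definition with the schema
#' \preformatted{
#' {
#'   "sections": [ {"label": "S1", "terrain": "flat",   # terrain optional
#'                  "length_m": 91, "grade_pct": 0}, ... ],
#'   "n_laps": 3,
#'   "lap_length_m": 1918          # optional override
#' }
#' }
#' Validation is strict: unknown terrain labels, non-positive lengths and
#' duplicate section labels are errors.
#'
#' @param path path to a `.json` course file.
#' @return a `course_profile`.
#' @export
read_course <- function(path) {
  if (!file.exists(path)) stop("course file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$sections)) stop("course file has no 'sections' entry")
  sec <- as.data.frame(doc$sections)
  need <- c("label", "length_m", "grade_pct")
  miss <- setdiff(need, names(sec))
  if (length(miss))
    stop("course sections missing field(s): ", paste(miss, collapse = ", "))
  df <- data.frame(label = sec$label, length = sec$length_m,
                   grade = sec$grade_pct, stringsAsFactors = FALSE)
  if ("terrain" %in% names(sec)) df$terrain <- sec$terrain
  build_course(df,
               n_laps = if (is.null(doc$n_laps)) 1L else doc$n_laps,
               lap_length = doc$lap_length_m)
}

#' Write a course definition file
#'
#' @param course a `course_profile`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_course <- function(course, path) {
  stopifnot(inherits(course, "course_profile"))
  doc <- list(sections = data.frame(label = course$label,
                                    terrain = course$terrain,
                                    length_m = course$length,
                                    grade_pct = course$grade),
              n_laps = n_laps(course),
              lap_length_m = lap_length(course))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.course_profile <- function(x, ...) {
  fr <- round(terrain_fractions(x))
  cat(sprintf("Course profile: %d sections, lap %.0f m x %d lap(s)\n",
              nrow(x), lap_length(x), n_laps(x)))
  cat(sprintf("Terrain: uphill %d%%, flat %d%%, downhill %d%%\n",
              fr[["uphill"]], fr[["flat"]], fr[["downhill"]]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
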