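# Local planar geometry helpers.  All course-scale distance computations use
# an equirectangular projection around a local origin: adequate below ~10 km,
# keeps the core free of a geodesy dependency.

.EARTH_R <- 6371000  # mean Earth radius, m

# lat/lon (deg) -> local x/y (m) around origin c(lat0, lon0)
local_xy <- function(lat, lon, origin) {
  lat0 <- origin[1] * pi / 180
  list(x = .EARTH_R * cos(lat0) * (lon - origin[2]) * pi / 180,
       y = .EARTH_R * (lat - origin[1]) * pi / 180)
}

# inverse of local_xy
local_latlon <- function(x, y, origin) {
  lat0 <- origin[1] * pi / 180
  list(lat = origin[1] + (y / .EARTH_R) * 180 / pi,
       lon = origin[2] + (x / (.EARTH_R * cos(lat0))) * 180 / pi)
}

# centroid origin of a set of coordinates
geo_origin <- function(lat, lon) c(mean(lat), mean(lon))

# Project point (px, py) onto segment (ax,ay)-(bx,by); returns t in [0,1]
# along the segment and the squared distance.  Vectorised over segments.
project_on_segments <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx
  qy <- ay + t * dy
  list(t = t, d2 = (px - qx)^2 + (py - qy)^2)
}
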