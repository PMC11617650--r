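# Planar geometry helpers for the prediction grid.
#
# All map work happens in a local equirectangular projection (km) about a
# reference point; adequate at the few-hundred-km extent of a regional trial
# network and keeps the package dependency-light.

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Project lon/lat degrees to local planar km coordinates
#'
#' Local equirectangular projection about `origin` (a `c(lat, lon)` pair,
#' typically the centroid of the trial points). Distances are in km.
#'
#' @param lat,lon numeric vectors of WGS84 degrees.
#' @param origin numeric `c(lat0, lon0)` reference point in degrees.
#' @return matrix with columns `x_km`, `y_km`.
#' @keywords internal
project_local_km <- function(lat, lon, origin) {
  lat0 <- origin[1]; lon0 <- origin[2]
  x <- (lon - lon0) * KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180)
  y <- (lat - lat0) * KM_PER_DEG_LAT
  cbind(x_km = x, y_km = y)
}

#' @keywords internal
unproject_local_km <- function(x, y, origin) {
  lat0 <- origin[1]; lon0 <- origin[2]
  lat <- lat0 + y / KM_PER_DEG_LAT
  lon <- lon0 + x / (KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180))
  cbind(lat = lat, lon = lon)
}

# Distance from point p to segment a-b (all length-2 numeric).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  t <- if (denom == 0) 0 else sum((p - a) * ab) / denom
  t <- min(1, max(0, t))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# Ray-casting point-in-polygon; poly is an n x 2 matrix of vertices in order.
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- (poly[j, 1] - poly[i, 1]) * (p[2] - yi) / (yj - yi) + poly[i, 1]
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Euclidean distance from a point to a convex polygon (0 if inside).
distance_to_polygon <- function(p, poly) {
  if (point_in_polygon(p, poly)) return(0)
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- min(d, point_segment_distance(p, poly[i, ], poly[j, ]))
  }
  d
}
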