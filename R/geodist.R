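## Great-circle migratory distances along waypoint routes.
## The published distances were produced with interactive mapping software;
## here the computation is explicit: haversine legs on the IUGG mean-radius
## sphere, summed along a route. Published distances remain authoritative
## inputs and are never re-derived as targets.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points
#'
#' Haversine formula on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).
#'
#' @param a,b `geo_point` objects (see [geo_point()]).
#' @return Distance in km.
#' @export
#' @examples
#' haversine_km(geo_point(0, 0), geo_point(0, 1))  # ~111.2 km
haversine_km <- function(a, b) {
  stopifnot(inherits(a, "geo_point"), inherits(b, "geo_point"))
  to_rad <- pi / 180
  dlat <- (b$lat - a$lat) * to_rad
  dlon <- (b$lon - a$lon) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a$lat * to_rad) * cos(b$lat * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Construct a migration route
#'
#' An ordered list of waypoints, origin first. Consecutive duplicate
#' waypoints are allowed (zero-length legs).
#'
#' @param waypoints A list of `geo_point`s, or a data.frame with `lat`,
#'   `lon` columns.
#' @return An object of class `migration_route`.
#' @export
migration_route <- function(waypoints) {
  if (is.data.frame(waypoints)) {
    stopifnot(all(c("lat", "lon") %in% names(waypoints)))
    waypoints <- lapply(seq_len(nrow(waypoints)), function(i)
      geo_point(waypoints$lat[i], waypoints$lon[i]))
  }
  if (length(waypoints) < 1L) stop("a route needs at least one waypoint")
  stopifnot(all(vapply(waypoints, inherits, logical(1), "geo_point")))
  structure(list(waypoints = waypoints), class = "migration_route")
}

#' Read a waypoint route from TSV
#' @param path Tab-separated file with header `lat  lon`, one waypoint per
#'   line, origin first.
#' @return A `migration_route`.
#' @export
read_route <- function(path) {
  migration_route(utils::read.delim(path, check.names = FALSE))
}

#' Migratory distance along a route to a terminus
#'
#' Sum of great-circle legs origin -> ... -> last waypoint -> terminus.
#' A population at the route origin (the African origin convention) has
#' distance 0.
#'
#' @param route A `migration_route`.
#' @param terminus A `geo_point`: the population location.
#' @return Cumulative distance in km.
#' @export
route_distance_km <- function(route, terminus) {
  stopifnot(inherits(route, "migration_route"), inherits(terminus, "geo_point"))
  pts <- c(route$waypoints, list(terminus))
  total <- 0
  for (i in seq_len(length(pts) - 1L))
    total <- total + haversine_km(pts[[i]], pts[[i + 1L]])
  total
}
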