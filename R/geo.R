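# Geodesic utilities. Two distance conventions are supported:
#  * "geodesic"  -- WGS84 ellipsoidal geodesic (geosphere::distGeo), the
#                   convention used for the site geometry worked examples;
#  * "haversine" -- spherical great-circle with R = 6371.0088 km, a closed
#                   form used for all track-level metrics where millions of
#                   pairwise distances are needed. The two differ by < 0.3 %
#                   at the 10 km scales involved.

#' Mean Earth radius (metres) used by the spherical distance convention
#' @keywords internal
.EARTH_RADIUS_M <- 6371008.8

.check_geopoint <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    rm_abort("rm_domain_error", sprintf("non-finite coordinates in %s", what))
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    rm_abort("rm_domain_error",
             sprintf("coordinates out of WGS84 range in %s", what))
  invisible(TRUE)
}

#' Distance between geographic points
#'
#' Computes the distance in metres between points given as decimal-degree
#' WGS84 latitude/longitude. The default is the ellipsoidal geodesic; the
#' spherical haversine alternative (mean radius 6371.0088 km) is what all
#' route metrics in this package use internally.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param method `"geodesic"` (WGS84 ellipsoid) or `"haversine"` (sphere).
#' @return numeric vector of distances in metres.
#' @examples
#' # Stanton Harcourt release site to the Oxford home loft, in km
#' geo_distance(51.7527778, -1.42375, 51.7828602, -1.3173753) / 1000
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2,
                         method = c("geodesic", "haversine")) {
  method <- match.arg(method)
  .check_geopoint(lat1, lon1, "p")
  .check_geopoint(lat2, lon2, "q")
  if (method == "geodesic") {
    geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
  } else {
    geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                             r = .EARTH_RADIUS_M)
  }
}

#' Initial great-circle bearing
#'
#' Initial bearing from point 1 to point 2, clockwise from true north,
#' in `[0, 360)` degrees.
#'
#' @inheritParams geo_distance
#' @return bearing in degrees.
#' @export
geo_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_geopoint(lat1, lon1, "p")
  .check_geopoint(lat2, lon2, "q")
  if (any(lat1 == lat2 & lon1 == lon2))
    rm_abort("rm_domain_error", "bearing undefined for coincident points")
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) %% 360
}

# Spherical haversine distance for two coordinate vectors (elementwise),
# same formula as geosphere::distHaversine but kept internal so the
# nearest-neighbour search below can reuse the final-step computation.
.hav_dist <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  2 * atan2(sqrt(a), sqrt(1 - a)) * .EARTH_RADIUS_M
}

# Local tangent-plane conversions used by the synthetic generator. East/north
# offsets in metres about an origin; adequate over the ~10 km scales here.
.local_from_geo <- function(lat, lon, lat0, lon0) {
  m_per_deg <- .EARTH_RADIUS_M * pi / 180
  cbind(east = (lon - lon0) * m_per_deg * cos(lat0 * pi / 180),
        north = (lat - lat0) * m_per_deg)
}

.geo_from_local <- function(east, north, lat0, lon0) {
  m_per_deg <- .EARTH_RADIUS_M * pi / 180
  cbind(lat = lat0 + north / m_per_deg,
        lon = lon0 + east / (m_per_deg * cos(lat0 * pi / 180)))
}
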