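#' Construct geographic points
#'
#' A `geo_point` holds latitude/longitude in decimal degrees plus an altitude
#' in metres above datum. All geometry helpers accept vectors, so a
#' `geo_point` of length n is a table of n positions.
#'
#' @param lat latitude in decimal degrees, in \[-90, 90\].
#' @param lon longitude in decimal degrees, in \[-180, 180\].
#' @param alt altitude in metres above datum (default 0).
#' @return a data.frame of class `geo_point` with columns `lat`, `lon`, `alt`.
#' @examples
#' rawhiti <- geo_point(-35.2330, 174.2606)
#' @export
geo_point <- function(lat, lon, alt = 0) {
  if (!all(is.finite(lat)) || !all(is.finite(lon)) || !all(is.finite(alt)))
    stop("geo_point coordinates must be finite", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude must lie in [-180, 180]", call. = FALSE)
  out <- data.frame(lat = lat, lon = lon, alt = rep_len(alt, length(lat)))
  class(out) <- c("geo_point", "data.frame")
  out
}

# Mean Earth radius in metres used throughout (spherical model).
EARTH_RADIUS_M <- 6371000

#' Great-circle distance between two points (Haversine)
#'
#' Computes the as-the-crow-flies distance over the Earth's surface on a
#' sphere of mean radius 6,371 km:
#' \deqn{a = \sin^2(\Delta\phi/2) + \cos\phi_1 \cos\phi_2 \sin^2(\Delta\lambda/2)}
#' \deqn{c = 2\,\mathrm{atan2}(\sqrt a, \sqrt{1-a}), \quad d = R c}
#'
#' @param p1,p2 `geo_point` objects (recycled to a common length).
#' @return distance(s) in metres.
#' @seealso [initial_bearing()], [direction_sector()]
#' @export
haversine_distance <- function(p1, p2) {
  stopifnot(inherits(p1, "geo_point"), inherits(p2, "geo_point"))
  phi1 <- p1$lat * pi / 180
  phi2 <- p2$lat * pi / 180
  dphi <- (p2$lat - p1$lat) * pi / 180
  dlam <- (p2$lon - p1$lon) * pi / 180
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  c <- 2 * atan2(sqrt(a), sqrt(1 - a))
  EARTH_RADIUS_M * c
}

#' Initial bearing (forward azimuth) from one point to another
#'
#' The direction covariate of the detection model is the bearing from the
#' listener (station) to the sound source (speaker): it describes where a
#' call is coming *from*, seen from the listening position.
#'
#' @param p1 listener position (`geo_point`).
#' @param p2 sound-source position (`geo_point`).
#' @return bearing in degrees clockwise from true north, in \[0, 360).
#' @export
initial_bearing <- function(p1, p2) {
  stopifnot(inherits(p1, "geo_point"), inherits(p2, "geo_point"))
  if (any(p1$lat == p2$lat & p1$lon == p2$lon))
    stop("bearing is undefined for coincident points", call. = FALSE)
  phi1 <- p1$lat * pi / 180
  phi2 <- p2$lat * pi / 180
  dlam <- (p2$lon - p1$lon) * pi / 180
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Assign a bearing to one of eight 45-degree direction sectors
#'
#' Sectors partition the compass into eight half-open 45-degree classes,
#' sector 1 starting at true north: sector k covers \[(k-1) * 45, k * 45).
#' A call from ~70 degrees (E-NE) falls in sector 2; one from ~200 degrees
#' (S-SW) falls in sector 5. Any finite angle is first reduced modulo 360.
#'
#' @param angle_deg bearing(s) in degrees (any finite value).
#' @return integer sector(s) in 1..8.
#' @export
direction_sector <- function(angle_deg) {
  if (!all(is.finite(angle_deg)))
    stop("angle must be finite", call. = FALSE)
  as.integer(floor((angle_deg %% 360) / 45)) + 1L
}

#' Relative altitude of a listener above a sound source
#'
#' Listener altitude minus speaker altitude, so a positive value means the
#' speaker (bird) is lower than the listener.
#'
#' @param listener_alt,speaker_alt altitudes in metres.
#' @return altitude difference in metres.
#' @export
relative_altitude <- function(listener_alt, speaker_alt) {
  if (!all(is.finite(listener_alt)) || !all(is.finite(speaker_alt)))
    stop("altitudes must be finite", call. = FALSE)
  listener_alt - speaker_alt
}

#' Build a station-by-speaker geometry table from coordinates
#'
#' Expands every (station, speaker) pair into one row of spatial covariates:
#' great-circle distance, relative altitude (station minus speaker), bearing
#' from station to speaker, the 45-degree direction sector of that bearing,
#' and a line-of-sight flag. Line of sight is an input (whether terrain
#' separates the pair is not computable from coordinates alone): pass a
#' logical matrix (stations x speakers) or a single default.
#'
#' @param stations,speakers `geo_point` tables; row i is station/speaker i.
#' @param line_of_sight logical matrix `[station, speaker]`, or one logical
#'   recycled to all pairs (default `TRUE`).
#' @return a `geometry_table` data.frame with columns `station_id`,
#'   `speaker_id`, `distance_m`, `relative_altitude_m`, `line_of_sight`,
#'   `bearing_deg`, `sector`.
#' @export
build_geometry_table <- function(stations, speakers, line_of_sight = TRUE) {
  stopifnot(inherits(stations, "geo_point"), inherits(speakers, "geo_point"))
  ns <- nrow(stations); nk <- nrow(speakers)
  if (is.matrix(line_of_sight)) {
    stopifnot(identical(dim(line_of_sight), c(ns, nk)))
  } else {
    line_of_sight <- matrix(rep_len(as.logical(line_of_sight), ns * nk), ns, nk)
  }
  grid <- expand.grid(station_id = seq_len(ns), speaker_id = seq_len(nk))
  st <- stations[grid$station_id, , drop = FALSE]
  sp <- speakers[grid$speaker_id, , drop = FALSE]
  class(st) <- class(sp) <- c("geo_point", "data.frame")
  bearing <- initial_bearing(st, sp)
  out <- data.frame(
    station_id = grid$station_id,
    speaker_id = grid$speaker_id,
    distance_m = haversine_distance(st, sp),
    relative_altitude_m = relative_altitude(st$alt, sp$alt),
    line_of_sight = line_of_sight[cbind(grid$station_id, grid$speaker_id)],
    bearing_deg = bearing,
    sector = direction_sector(bearing)
  )
  validate_geometry_table(out)
}

#' Validate a geometry table
#'
#' Checks the column set, ranges and internal consistency (sector derived
#' from bearing, non-negative distances) of a station-by-speaker geometry
#' table, whether built by [build_geometry_table()] or supplied directly.
#'
#' @param x data.frame with the `geometry_table` columns.
#' @return `x`, classed `geometry_table`, invisibly usable downstream.
#' @export
validate_geometry_table <- function(x) {
  needed <- c("station_id", "speaker_id", "distance_m", "relative_altitude_m",
              "line_of_sight", "bearing_deg", "sector")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("geometry table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$distance_m)) || any(x$distance_m < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(x$bearing_deg)))
    stop("bearings must be finite", call. = FALSE)
  if (!all(x$sector == direction_sector(x$bearing_deg)))
    stop("sector column inconsistent with bearing_deg", call. = FALSE)
  if (anyDuplicated(x[c("station_id", "speaker_id")]))
    stop("duplicate (station, speaker) pairs", call. = FALSE)
  x$line_of_sight <- as.logical(x$line_of_sight)
  class(x) <- unique(c("geometry_table", class(x)))
  x
}

#' Read / write geometry tables as tab-delimited text
#'
#' @param path file path.
#' @param x a `geometry_table`.
#' @return `read_geometry_table` returns a validated `geometry_table`.
#' @export
read_geometry_table <- function(path) {
  validate_geometry_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_geometry_table
#' @export
write_geometry_table <- function(x, path) {
  x <- validate_geometry_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Geometry row lookup used when assembling covariates.
geometry_lookup <- function(geometry, station, speaker) {
  key <- paste(geometry$station_id, geometry$speaker_id)
  idx <- match(paste(station, speaker), key)
  if (anyNA(idx)) {
    bad <- unique(paste0("(", station[is.na(idx)], ",", speaker[is.na(idx)], ")"))
    stop("geometry table missing station-speaker pairs: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  geometry[idx, , drop = FALSE]
}
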