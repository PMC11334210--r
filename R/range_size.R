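#' Read species occurrence coordinates
#'
#' Delimited text (comma or tab) with columns \code{species} plus
#' \code{decimalLongitude}/\code{decimalLatitude} (GBIF export dialect;
#' plain \code{longitude}/\code{latitude} also accepted, extra columns
#' ignored). Rows with missing or out-of-bounds coordinates are
#' dropped with a message -- occurrence downloads are dirty by nature.
#'
#' @param path Path to the table.
#' @return Data frame: \code{species}, \code{longitude},
#'   \code{latitude}.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  lon_col <- intersect(c("decimalLongitude", "longitude", "lon"), names(df))[1]
  lat_col <- intersect(c("decimalLatitude", "latitude", "lat"), names(df))[1]
  if (is.na(lon_col) || is.na(lat_col) || !"species" %in% names(df))
    stop("need columns species + decimalLongitude/decimalLatitude")
  out <- data.frame(species = normalize_label(df$species),
                    longitude = as.numeric(df[[lon_col]]),
                    latitude = as.numeric(df[[lat_col]]),
                    stringsAsFactors = FALSE)
  ok <- is.finite(out$longitude) & is.finite(out$latitude) &
    abs(out$longitude) <= 180 & abs(out$latitude) <= 90
  if (any(!ok)) message("dropped ", sum(!ok),
                        " rows with missing/out-of-bounds coordinates")
  out[ok, , drop = FALSE]
}

# mean Earth radius, km (IUGG)
EARTH_RADIUS_KM <- 6371.0088

#' Convex-hull range area for one species
#'
#' Area (km^2) of the spherical polygon spanned by the convex hull of
#' the occurrence points, on a sphere of radius 6371.0088 km. Point
#' sets spanning the antimeridian are unwrapped (longitudes below zero
#' shifted by +360 when the raw spread exceeds 180 degrees). Fewer
#' than three distinct non-collinear points give area 0.
#'
#' @param points Data frame with \code{longitude}, \code{latitude} for
#'   a single species.
#' @return List: \code{area_km2}, \code{n_points} (distinct points
#'   used).
#' @export
estimate_range <- function(points) {
  pts <- unique(points[, c("longitude", "latitude")])
  if (nrow(pts) == 0L) stop("no valid occurrence points")
  if (nrow(pts) < 3L) return(list(area_km2 = 0, n_points = nrow(pts)))
  lon <- pts$longitude
  if (diff(range(lon)) > 180) lon <- ifelse(lon < 0, lon + 360, lon)
  hull <- grDevices::chull(lon, pts$latitude)
  if (length(hull) < 3L) return(list(area_km2 = 0, n_points = nrow(pts)))
  poly <- cbind(lon[hull], pts$latitude[hull])
  a <- geosphere::areaPolygon(poly, a = EARTH_RADIUS_KM * 1000, f = 0) / 1e6
  list(area_km2 = abs(a), n_points = nrow(pts))
}

#' Range areas for every species in an occurrence table
#'
#' @param occ Output of \code{\link{read_occurrences}}.
#' @return Data frame: \code{species}, \code{area_km2},
#'   \code{n_points}.
#' @export
estimate_ranges <- function(occ) {
  out <- lapply(split(occ, occ$species), function(d) {
    est <- estimate_range(d)
    data.frame(species = d$species[1], area_km2 = est$area_km2,
               n_points = est$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Discretize range areas at the dataset median
#'
#' Species with area greater than or equal to the median are classed
#' \code{large}, the rest \code{small}.
#'
#' @param estimates Data frame with \code{species} and
#'   \code{area_km2} (e.g. from \code{\link{estimate_ranges}}).
#' @return Data frame: \code{species}, \code{area_km2}, \code{class}
#'   (factor small/large), \code{median_km2}.
#' @export
discretize_by_median <- function(estimates) {
  if (nrow(estimates) < 2L) stop("need at least 2 species to discretize")
  med <- median(estimates$area_km2)
  cls <- ifelse(estimates$area_km2 >= med, "large", "small")
  if (all(cls == "large"))
    warning("all areas >= median (identical values?); every species large")
  data.frame(species = estimates$species, area_km2 = estimates$area_km2,
             class = factor(cls, levels = c("small", "large")),
             median_km2 = med, stringsAsFactors = FALSE)
}
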