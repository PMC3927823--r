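#' Read point localities from CSV
#'
#' Expects at least the columns \code{species}, \code{longitude},
#' \code{latitude}; \code{precision_m} (metres) and \code{source} are
#' optional and carried through unchanged. Rows violating the coordinate
#' bounds (longitude in [-180, 180], latitude in [-90, 90]) or with an
#' empty species label raise an error naming the offending rows.
#'
#' @param path path to a CSV file.
#' @return a data.frame with columns species, longitude, latitude,
#'   precision_m, source.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(species = "sp1", longitude = 29.5, latitude = -29.3),
#'           f, row.names = FALSE)
#' read_localities(f)
#' @export
read_localities <- function(path) {
  if (!file.exists(path)) stop("locality file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("locality CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("locality file ", path, " contains no rows")
    return(data.frame(species = character(0), longitude = numeric(0),
                      latitude = numeric(0), precision_m = numeric(0),
                      source = character(0)))
  }
  if (is.null(df$precision_m)) df$precision_m <- NA_real_
  if (is.null(df$source)) df$source <- NA_character_
  df <- df[c("species", "longitude", "latitude", "precision_m", "source")]
  bad <- which(is.na(df$species) | !nzchar(trimws(df$species)) |
               !is.finite(df$longitude) | !is.finite(df$latitude) |
               df$longitude < -180 | df$longitude > 180 |
               df$latitude < -90 | df$latitude > 90)
  if (length(bad))
    stop("invalid locality row(s): ", paste(bad, collapse = ", "),
         " (coordinates out of range or empty species)")
  df
}

#' Project longitude/latitude to a planar km frame
#'
#' Equirectangular projection anchored at a reference point:
#' \eqn{x = R \cos(\phi_0)(\lambda - \lambda_0)\pi/180},
#' \eqn{y = R (\phi - \phi_0)\pi/180} with \eqn{R = 6371} km. Adequate for
#' study extents of a few hundred km, which is the intended use (ranges
#' digitised from large-scale topographic maps).
#'
#' @param localities data.frame with longitude and latitude columns (e.g.
#'   from [read_localities()]).
#' @param reference_latitude reference latitude in degrees, or "auto"
#'   (default) to anchor at the mean of the input coordinates.
#' @param reference_longitude reference longitude in degrees, or "auto".
#' @return data.frame with columns x and y (km); the reference point is
#'   attached as attributes \code{ref_lon} and \code{ref_lat}.
#' @export
project_localities <- function(localities, reference_latitude = "auto",
                               reference_longitude = "auto") {
  if (nrow(localities) == 0L) stop("cannot project an empty locality set")
  lat0 <- if (identical(reference_latitude, "auto"))
    mean(localities$latitude) else as.numeric(reference_latitude)
  lon0 <- if (identical(reference_longitude, "auto"))
    mean(localities$longitude) else as.numeric(reference_longitude)
  R <- 6371
  out <- data.frame(
    x = R * cos(lat0 * pi / 180) * (localities$longitude - lon0) * pi / 180,
    y = R * (localities$latitude - lat0) * pi / 180
  )
  if (!is.null(localities$species)) out$species <- localities$species
  attr(out, "ref_lon") <- lon0
  attr(out, "ref_lat") <- lat0
  out
}

# inverse of project_localities for a planar point set
unproject_points <- function(xy, ref_lon, ref_lat) {
  R <- 6371
  data.frame(
    longitude = ref_lon + xy[, 1L] / (R * cos(ref_lat * pi / 180)) * 180 / pi,
    latitude = ref_lat + xy[, 2L] / R * 180 / pi
  )
}

#' Build a convex-hull range polygon
#'
#' The minimal convex polygon containing all projected localities of a
#' species (monotone-chain construction; collinear boundary points are
#' dropped). With fewer than three non-collinear points the range is
#' degenerate: it has zero area and is handled by the locality-membership
#' rule in [overlap_proportion()].
#'
#' @param points data.frame or matrix with x and y columns (km).
#' @param species_id species label for the range.
#' @return an object of class \code{convex_range}: a list with elements
#'   species_id, vertices (counter-clockwise matrix), area (km^2),
#'   n_localities, degenerate, and points (the input localities).
#' @export
build_hull <- function(points, species_id = "") {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(points) < 1L || any(!is.finite(points)))
    stop("build_hull needs at least one finite point")
  hull <- monotone_chain(points)
  degenerate <- nrow(hull) < 3L
  area <- if (degenerate) 0 else polygon_area(hull)
  structure(list(species_id = species_id,
                 vertices = hull,
                 area = area,
                 n_localities = nrow(points),
                 degenerate = degenerate,
                 points = points),
            class = "convex_range")
}

#' @export
print.convex_range <- function(x, ...) {
  cat("Convex range", if (nzchar(x$species_id)) paste0("'", x$species_id, "'"),
      "\n  localities:", x$n_localities,
      "\n  hull vertices:", nrow(x$vertices),
      "\n  area:", format(x$area), "km^2",
      if (x$degenerate) "\n  degenerate (fewer than 3 non-collinear points)",
      "\n")
  invisible(x)
}

#' Area of intersection of two convex ranges
#'
#' Convex-convex clipping (each edge of one polygon clips the other);
#' returns 0 for disjoint ranges. Both ranges must be non-degenerate;
#' degenerate ranges are handled by [overlap_proportion()].
#'
#' @param a,b \code{convex_range} objects.
#' @return intersection area in km^2.
#' @export
intersection_area <- function(a, b) {
  stopifnot(inherits(a, "convex_range"), inherits(b, "convex_range"))
  if (a$degenerate || b$degenerate)
    stop("intersection_area requires non-degenerate ranges; ",
         "use overlap_proportion for degenerate cases")
  polygon_area(convex_intersection(a$vertices, b$vertices))
}

#' Pairwise range-overlap proportion
#'
#' For two polygonal ranges: intersection area divided by the area of the
#' smaller range, so a value of 1 means the narrower range is completely
#' embedded in the wider one. When one range is degenerate (a point or a
#' line), the proportion is the fraction of its localities lying inside or
#' on the other polygon; two degenerate ranges overlap (value 1) only if
#' some pair of their localities coincides within \code{tol} km.
#'
#' @param a,b \code{convex_range} objects.
#' @param tol coincidence tolerance in km for the degenerate-degenerate
#'   case (default 1e-6 km, i.e. 1 mm).
#' @return proportion in [0, 1].
#' @export
overlap_proportion <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "convex_range"), inherits(b, "convex_range"))
  if (!a$degenerate && !b$degenerate) {
    p <- polygon_area(convex_intersection(a$vertices, b$vertices)) /
      min(a$area, b$area)
    return(min(max(p, 0), 1))
  }
  if (a$degenerate && b$degenerate) {
    d2 <- outer(a$points[, 1L], b$points[, 1L], "-")^2 +
      outer(a$points[, 2L], b$points[, 2L], "-")^2
    return(as.numeric(any(d2 <= tol^2)))
  }
  deg <- if (a$degenerate) a else b
  poly <- if (a$degenerate) b else a
  mean(points_in_convex(deg$points, poly$vertices))
}

#' Pairwise overlap matrix for a set of ranges
#'
#' @param ranges list of \code{convex_range} objects with unique species ids.
#' @return symmetric matrix of overlap proportions with unit diagonal and
#'   species ids as dimnames.
#' @export
overlap_matrix <- function(ranges) {
  if (length(ranges) < 2L) stop("need at least two ranges")
  ids <- vapply(ranges, function(r) r$species_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(ranges)
  M <- diag(1, n)
  dimnames(M) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    M[i, j] <- M[j, i] <- overlap_proportion(ranges[[i]], ranges[[j]])
  }
  M
}

#' Build ranges for every species in a projected locality table
#'
#' @param projected data.frame with x, y and species columns (from
#'   [project_localities()]).
#' @return named list of \code{convex_range} objects, one per species, in
#'   order of first appearance.
#' @export
species_ranges <- function(projected) {
  stopifnot(!is.null(projected$species))
  sp <- unique(projected$species)
  out <- lapply(sp, function(s) {
    build_hull(projected[projected$species == s, c("x", "y")], s)
  })
  names(out) <- sp
  out
}

#' Write range polygons and a per-species summary to CSV
#'
#' Emits a vertex table (species, vertex_index, x_km, y_km) and a summary
#' (species, n_localities, area_km2, degenerate).
#'
#' @param ranges named list of \code{convex_range} objects.
#' @param vertex_path,summary_path output CSV paths.
#' @return invisibly, the summary data.frame.
#' @export
write_ranges <- function(ranges, vertex_path, summary_path) {
  verts <- do.call(rbind, lapply(ranges, function(r) {
    v <- r$vertices
    data.frame(species = r$species_id, vertex_index = seq_len(nrow(v)),
               x_km = v[, 1L], y_km = v[, 2L])
  }))
  utils::write.csv(verts, vertex_path, row.names = FALSE)
  summ <- data.frame(
    species = vapply(ranges, function(r) r$species_id, character(1)),
    n_localities = vapply(ranges, function(r) r$n_localities, integer(1)),
    area_km2 = vapply(ranges, function(r) r$area, numeric(1)),
    degenerate = vapply(ranges, function(r) r$degenerate, logical(1))
  )
  utils::write.csv(summ, summary_path, row.names = FALSE)
  invisible(summ)
}

#' Write an overlap matrix as a square CSV
#' @param M overlap matrix from [overlap_matrix()].
#' @param path output CSV path.
#' @export
write_overlap_matrix <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Read an overlap matrix written by [write_overlap_matrix()]
#' @param path CSV path with species header row and column.
#' @return symmetric numeric matrix.
#' @export
read_overlap_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M) || !all(rownames(M) == colnames(M)))
    stop("overlap matrix CSV must be square with matching row/column names")
  M
}
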