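#' Project longitude/latitude to planar kilometres
#'
#' Equirectangular projection about the centroid: latitude maps to
#' north-south km on a 6371-km sphere and longitude is scaled by the cosine
#' of the centroid latitude. Adequate for study extents of a few degrees,
#' where it perturbs neighbor topology negligibly; spans above 10 degrees
#' are refused unless `allow_wide = TRUE`.
#'
#' @param lon,lat numeric vectors, decimal degrees.
#' @param allow_wide permit extents wider than 10 degrees.
#' @return tibble with planar `x`, `y` in km; the projection centre is
#'   attached as `attr(, "center")`.
#' @export
project_coordinates <- function(lon, lat, allow_wide = FALSE) {
  stopifnot(length(lon) == length(lat))
  if (!all(is.finite(lon)) || !all(is.finite(lat))) stop("non-finite coordinates")
  if (!allow_wide && (diff(range(lon)) > 10 || diff(range(lat)) > 10)) {
    stop("coordinate span exceeds 10 degrees; equirectangular distortion is ",
         "no longer negligible (set allow_wide = TRUE to override)")
  }
  r_earth <- 6371
  lat0 <- mean(lat)
  lon0 <- mean(lon)
  out <- tibble::tibble(
    x = r_earth * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
    y = r_earth * (lat - lat0) * pi / 180
  )
  attr(out, "center") <- c(lon = lon0, lat = lat0)
  out
}

# deterministic jitter for coincident points so the triangulation sees
# distinct sites; magnitude 1e-6 km, keyed to a fixed internal seed
.jitter_duplicates <- function(xy) {
  key <- paste(format(xy[, 1], digits = 15), format(xy[, 2], digits = 15))
  dup <- duplicated(key)
  if (!any(dup)) return(xy)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(190501L)
  xy[dup, 1] <- xy[dup, 1] + stats::runif(sum(dup), -1e-6, 1e-6)
  xy[dup, 2] <- xy[dup, 2] + stats::runif(sum(dup), -1e-6, 1e-6)
  message(sum(dup), " coincident point(s) jittered by <= 1e-6 km")
  xy
}

#' Delaunay neighbor lists for planar points
#'
#' Two observations are neighbors iff they share an edge of some triangle of
#' the Delaunay triangulation of the point set (equivalently, iff they are
#' two vertex points of a common triangle). The relation is symmetric and,
#' for non-degenerate inputs, every point has at least two neighbors.
#' Coincident points are first separated by a deterministic 1e-6 km jitter.
#'
#' @param xy two-column matrix or data frame of planar coordinates (km).
#' @return list of integer neighbor index vectors, one per point.
#' @export
delaunay_neighbors <- function(xy) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 3) stop("Delaunay triangulation needs at least 3 points")
  xy <- .jitter_duplicates(xy)
  cx <- xy[, 1] - mean(xy[, 1])
  cy <- xy[, 2] - mean(xy[, 2])
  area2 <- abs((cx[2] - cx[1]) * (cy - cy[1]) - (cy[2] - cy[1]) * (cx - cx[1]))
  if (n >= 3 && max(outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2) > 0) {
    # cheap collinearity guard for small point sets
    if (all(abs(stats::residuals(stats::lm(cy ~ cx))) < 1e-12) ||
        all(abs(stats::residuals(stats::lm(cx ~ cy))) < 1e-12)) {
      stop("all points are collinear; Delaunay triangulation undefined")
    }
  }
  tri <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  seg <- tri$delsgs
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (k in seq_len(nrow(seg))) {
    i <- seg$ind1[k]; j <- seg$ind2[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  if (any(lengths(nb) == 0)) {
    stop("triangulation left ", sum(lengths(nb) == 0), " point(s) without neighbors")
  }
  nb
}

#' Row-standardize neighbor lists into a spatial weight matrix
#'
#' Builds the sparse n x n matrix W with `w_ij = 1/|N(i)|` for j in the
#' neighbor set N(i) and 0 otherwise, so every row sums to one. W is
#' generally asymmetric after standardization even though the neighbor
#' relation is symmetric.
#'
#' @param neighbors list of integer neighbor vectors (as from
#'   [delaunay_neighbors()]).
#' @param coords optional planar coordinates (km) retained for distance
#'   summaries.
#' @return object of class `weight_matrix`: list with `w` (dgCMatrix),
#'   `neighbors`, `coords`, and `meta` (neighbor counts, per-row mean
#'   neighbor distance in km, projection centre).
#' @export
row_standardize <- function(neighbors, coords = NULL) {
  n <- length(neighbors)
  deg <- lengths(neighbors)
  if (any(deg == 0)) stop("empty neighbor row(s): ", paste(which(deg == 0), collapse = ", "))
  ii <- rep(seq_len(n), deg)
  jj <- unlist(neighbors, use.names = FALSE)
  w <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1 / deg, deg), dims = c(n, n))
  mean_dist <- rep(NA_real_, n)
  center <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    stopifnot(nrow(coords) == n)
    center <- attr(coords, "center")
    mean_dist <- vapply(seq_len(n), function(i) {
      js <- neighbors[[i]]
      mean(sqrt((coords[js, 1] - coords[i, 1])^2 + (coords[js, 2] - coords[i, 2])^2))
    }, numeric(1))
  }
  structure(
    list(
      w = methods::as(w, "CsparseMatrix"),
      neighbors = neighbors,
      coords = coords,
      meta = list(
        n = n, min_neighbors = min(deg), max_neighbors = max(deg),
        mean_neighbor_dist_km = mean_dist, center = center
      )
    ),
    class = "weight_matrix"
  )
}

#' Build a Delaunay spatial weight matrix from an owner table
#'
#' Convenience pipeline: project lon/lat to planar km, triangulate, and
#' row-standardize. For subsample models (e.g. residential owners only) the
#' subsample must be re-triangulated, since W must match the estimation
#' sample's dimension; pass the subset table.
#'
#' @param df survey tibble with `lon`/`lat` columns, or a two-column matrix
#'   of coordinates.
#' @param planar treat the input coordinates as already planar km (skip
#'   projection).
#' @param allow_wide see [project_coordinates()].
#' @return a [row_standardize()] `weight_matrix`.
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 50, seed = 1))
#' w <- spatial_weights(s)
#' neighbor_stats(w)
spatial_weights <- function(df, planar = FALSE, allow_wide = FALSE) {
  if (is.matrix(df)) {
    xy <- df
    if (!planar) {
      xy <- as.matrix(project_coordinates(df[, 1], df[, 2], allow_wide = allow_wide))
    }
  } else {
    if (!all(c("lon", "lat") %in% names(df))) {
      stop("spatial_weights: table has no lon/lat coordinates")
    }
    xy <- if (planar) cbind(df$lon, df$lat) else {
      as.matrix(project_coordinates(df$lon, df$lat, allow_wide = allow_wide))
    }
  }
  nb <- delaunay_neighbors(xy)
  row_standardize(nb, coords = xy)
}

#' Neighbor-count and neighbor-distance summary of a weight matrix
#'
#' @param w a `weight_matrix`.
#' @return one-row tibble: n, min/max neighbor counts, and the range of
#'   per-row mean neighbor distances (km; NA without coordinates).
#' @export
neighbor_stats <- function(w) {
  stopifnot(inherits(w, "weight_matrix"))
  md <- w$meta$mean_neighbor_dist_km
  tibble::tibble(
    n = w$meta$n,
    min_neighbors = w$meta$min_neighbors,
    max_neighbors = w$meta$max_neighbors,
    min_mean_dist_km = if (all(is.na(md))) NA_real_ else min(md, na.rm = TRUE),
    max_mean_dist_km = if (all(is.na(md))) NA_real_ else max(md, na.rm = TRUE)
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> n = %d, Delaunay neighbors per row: %d..%d, row-standardized\n",
    x$meta$n, x$meta$min_neighbors, x$meta$max_neighbors
  ))
  invisible(x)
}

#' Write / read a weight matrix
#'
#' The sparse matrix is stored in Matrix Market format (`<stem>.mtx`), the
#' planar coordinates (if any) as `<stem>_coords.csv`, and the neighbor
#' summary as `<stem>_stats.json`.
#'
#' @param w a `weight_matrix`.
#' @param stem path stem without extension.
#' @return `write_weights`: `stem` invisibly; `read_weights`: a
#'   `weight_matrix`.
#' @export
write_weights <- function(w, stem) {
  stopifnot(inherits(w, "weight_matrix"))
  Matrix::writeMM(w$w, paste0(stem, ".mtx"))
  if (!is.null(w$coords)) {
    utils::write.csv(data.frame(x = w$coords[, 1], y = w$coords[, 2]),
                     paste0(stem, "_coords.csv"), row.names = FALSE)
  }
  jsonlite::write_json(neighbor_stats(w), paste0(stem, "_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_weights
#' @export
read_weights <- function(stem) {
  w <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  coords <- NULL
  cpath <- paste0(stem, "_coords.csv")
  if (file.exists(cpath)) {
    cdf <- utils::read.csv(cpath)
    coords <- cbind(cdf$x, cdf$y)
  }
  n <- nrow(w)
  nb <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  row_standardize(nb, coords = coords)
}
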