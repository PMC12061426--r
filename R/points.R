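#' 2D point sets of column / cluster centres
#'
#' A thin wrapper around a two-column data frame with optional periodic box
#' dimensions.  When a box is present all distances are computed with the
#' minimum-image convention (the points live on a torus).
#'
#' @param x,y coordinates.
#' @param box `NULL` for points in the plane, or `c(Lx, Ly)` periodic box
#'   dimensions.
#' @return an object of class `point_set` (also a data frame).
#' @export
point_set <- function(x, y, box = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (anyDuplicated(complex(real = x, imaginary = y)))
    stop("point set contains coincident points")
  if (!is.null(box)) stopifnot(length(box) == 2, all(box > 0))
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            box = box, class = c("point_set", "data.frame"))
}

point_box <- function(points) attr(points, "box", exact = TRUE)

#' @export
print.point_set <- function(x, ...) {
  b <- point_box(x)
  cat(sprintf("point_set: %d points%s\n", nrow(x),
              if (is.null(b)) "" else sprintf(" on a %g x %g torus", b[1], b[2])))
  NextMethod()
}

# pairwise distances under the appropriate metric (dense; for modest n)
point_dist <- function(points) {
  b <- point_box(points)
  if (is.null(b)) return(as.matrix(stats::dist(cbind(points$x, points$y))))
  dx <- outer(points$x, points$x, `-`)
  dx <- dx - b[1] * round(dx / b[1])
  dy <- outer(points$y, points$y, `-`)
  dy <- dy - b[2] * round(dy / b[2])
  sqrt(dx^2 + dy^2)
}

#' Nearest-neighbour distances
#'
#' @param points a [point_set()].
#' @return per-point distance to the nearest other point.
#' @export
nn_distances <- function(points) {
  if (nrow(points) < 2) stop("at least 2 points are required")
  D <- point_dist(points)
  diag(D) <- Inf
  apply(D, 1, min)
}

#' Rescale a point set to a target mean nearest-neighbour distance
#'
#' Applies the uniform scaling (about the centroid) that makes the mean
#' nearest-neighbour distance equal to `target`, and recentres the pattern at
#' the origin.  This is how observed column coordinates are brought to the
#' model's length scale (sensing radius 1, target spacing 0.61).  Being a
#' similarity transform it leaves every angle, and hence every symmetry
#' index, unchanged.
#'
#' @param points a [point_set()] in the plane.
#' @param target the target mean nearest-neighbour distance (default 0.61).
#' @return the rescaled, recentred `point_set`.
#' @export
rescale_to_mean_nn <- function(points, target = 0.61) {
  stopifnot(target > 0, nrow(points) >= 2)
  cur <- mean(nn_distances(points))
  if (cur == 0) stop("all points coincide; cannot rescale")
  s <- target / cur
  cx <- mean(points$x); cy <- mean(points$y)
  b <- point_box(points)
  point_set((points$x - cx) * s, (points$y - cy) * s,
            box = if (is.null(b)) NULL else b * s)
}

#' Read and write point sets as CSV
#'
#' Plain two-column CSV (`x,y`); a periodic box is recorded in a leading
#' comment line `# box Lx Ly`.
#'
#' @param points a [point_set()].
#' @param path file path.
#' @return `read_point_set()` returns a `point_set`.
#' @export
write_point_set <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- point_box(points)
  if (!is.null(b))
    writeLines(sprintf("# box %.17g %.17g", b[1], b[2]), con)
  write.csv(data.frame(x = points$x, y = points$y), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_set
#' @export
read_point_set <- function(path) {
  first <- readLines(path, n = 1)
  box <- NULL
  if (startsWith(first, "# box")) {
    box <- as.numeric(strsplit(trimws(sub("# box", "", first)), "\\s+")[[1]])
  }
  d <- read.csv(path, comment.char = "#")
  point_set(d$x, d$y, box = box)
}

## ---- cluster centres from density fields ----------------------------------

#' Extract cluster centres from a density field
#'
#' Thresholds the field, takes connected components of super-threshold cells
#' under periodic 8-connectivity (configurable to 4), and returns the
#' density-weighted centroid of each component.  Centroids are computed with
#' the circular-mean construction per axis so clusters straddling the
#' periodic boundary are located correctly.
#'
#' @param field an `N x N` density matrix (e.g. the R7 field `u`).
#' @param grid an [ara_grid()].
#' @param threshold draw threshold (default 0.01; cells with
#'   `field >= threshold` belong to clusters).
#' @param connectivity 8 (default) or 4.
#' @return a [point_set()] on the `2L x 2L` torus with one point per
#'   component (empty if no cell exceeds the threshold), with the component
#'   cell counts in attribute `component_cells`.
#' @export
extract_cluster_centers <- function(field, grid, threshold = 0.01,
                                    connectivity = 8) {
  stopifnot(inherits(grid, "ara_grid"), threshold > 0,
            connectivity %in% c(4, 8))
  N <- grid$N
  on <- which(field >= threshold)
  if (length(on) == 0) {
    out <- structure(data.frame(x = numeric(0), y = numeric(0)),
                     box = c(2 * grid$L, 2 * grid$L),
                     component_cells = integer(0),
                     class = c("point_set", "data.frame"))
    return(out)
  }
  id <- integer(N * N)
  id[on] <- seq_along(on)
  ri <- (on - 1L) %% N          # 0-based row (x index)
  ci <- (on - 1L) %/% N         # 0-based col (y index)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (o in offs) {
    rn <- (ri + o[1]) %% N
    cn <- (ci + o[2]) %% N
    nb <- id[rn + cn * N + 1L]
    keep <- nb > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(seq_along(on)[keep], nb[keep]))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  # periodic density-weighted centroid via circular means
  wgt <- field[on]
  theta_x <- (ri + 0.5) / N * 2 * pi
  theta_y <- (ci + 0.5) / N * 2 * pi
  cx <- cy <- numeric(max(comp))
  cells <- integer(max(comp))
  for (k in seq_len(max(comp))) {
    m <- comp == k
    ax <- atan2(sum(wgt[m] * sin(theta_x[m])), sum(wgt[m] * cos(theta_x[m])))
    ay <- atan2(sum(wgt[m] * sin(theta_y[m])), sum(wgt[m] * cos(theta_y[m])))
    cx[k] <- (ax / (2 * pi)) %% 1 * 2 * grid$L - grid$L
    cy[k] <- (ay / (2 * pi)) %% 1 * 2 * grid$L - grid$L
    cells[k] <- sum(m)
  }
  out <- point_set(cx, cy, box = c(2 * grid$L, 2 * grid$L))
  attr(out, "component_cells") <- cells
  out
}

#' Flag a significantly disrupted columnar pattern
#'
#' A steady state is considered disrupted when the extracted cluster count
#' deviates from the initial column count by more than `count_tol` (relative)
#' or when any single component covers more than `area_frac` of the domain
#' (clusters have merged into stripes or a single blob).
#'
#' @param centers output of [extract_cluster_centers()].
#' @param n_initial initial number of columns.
#' @param grid an [ara_grid()].
#' @param count_tol relative tolerance on the cluster count (default 0.2).
#' @param area_frac maximal fraction of the domain one component may cover
#'   (default 0.1).
#' @return logical.
#' @export
pattern_disrupted <- function(centers, n_initial, grid,
                              count_tol = 0.2, area_frac = 0.1) {
  n <- nrow(centers)
  if (n == 0) return(TRUE)
  cells <- attr(centers, "component_cells", exact = TRUE)
  if (abs(n - n_initial) / n_initial > count_tol) return(TRUE)
  if (!is.null(cells) &&
      max(cells) * grid$dx^2 > area_frac * (2 * grid$L)^2) return(TRUE)
  FALSE
}
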