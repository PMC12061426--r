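#' Generate a centered-rectangular lattice
#'
#' The one-parameter family of regular lattices used as references for the
#' symmetry indices: rows of points at horizontal pitch `spacing` and
#' vertical pitch `h * spacing`, with alternate rows offset by half a
#' spacing.  `h = sqrt(3)/2` gives the triangular (hexagonal) lattice,
#' `h = 1/2` the square lattice (rotated 45 degrees, side
#' `spacing / sqrt(2)`), and intermediate `h` a centered rectangular
#' lattice.
#'
#' @param h row-height parameter in `[0.5, 1]`.
#' @param spacing horizontal lattice constant.
#' @param rows,cols lattice extent (`rows * cols >= 16`; `rows` must be even
#'   when `wrap = TRUE` so the row offsets close up periodically).
#' @param wrap if `TRUE` the points live on the torus
#'   `cols*spacing x rows*h*spacing` and have no edges.
#' @return a [point_set()] with attributes `spacing`, `h` and `nn_dist`
#'   (the exact nearest-neighbour distance of the unperturbed lattice, used
#'   as the "interparticle distance" scale for perturbations).
#' @export
generate_lattice <- function(h, spacing = 1, rows = 16, cols = 16,
                             wrap = FALSE) {
  if (h < 0.5 || h > 1) stop("h must lie in [0.5, 1]")
  stopifnot(spacing > 0, rows >= 1, cols >= 1)
  if (rows * cols < 16) stop("lattice must contain at least 16 points")
  if (wrap && rows %% 2 != 0)
    stop("wrapped lattices need an even number of rows")
  j <- rep(0:(rows - 1), each = cols)
  i <- rep(0:(cols - 1), times = rows)
  x <- i * spacing + (j %% 2) * spacing / 2
  y <- j * h * spacing
  box <- if (wrap) c(cols * spacing, rows * h * spacing) else NULL
  out <- point_set(x, y, box = box)
  attr(out, "spacing") <- spacing
  attr(out, "h") <- h
  attr(out, "nn_dist") <- spacing * min(1, sqrt(0.25 + h^2))
  out
}

#' Apply bounded random displacements to a point set
#'
#' Each point is displaced independently by a vector drawn uniformly from
#' the disk of radius `(p/100) * scale`, where the scale is the lattice's
#' interparticle (nearest-neighbour) distance.  `p = 0` returns the input
#' unchanged without consuming random numbers; a fixed `seed` makes the
#' perturbation reproducible and leaves the caller's RNG state untouched.
#'
#' @param points a [point_set()].
#' @param p maximum displacement as a percentage of the interparticle
#'   distance (`>= 0`).
#' @param seed optional integer seed.
#' @param scale displacement scale; defaults to the `nn_dist` attribute of
#'   lattices from [generate_lattice()], else the mean nearest-neighbour
#'   distance.
#' @return the perturbed `point_set` (wrapped back into the box if
#'   periodic).
#' @export
perturb_points <- function(points, p, seed = NULL, scale = NULL) {
  if (p < 0) stop("disturbance percentage p must be >= 0")
  if (p == 0) return(points)
  if (is.null(scale)) {
    scale <- attr(points, "nn_dist", exact = TRUE)
    if (is.null(scale)) scale <- mean(nn_distances(points))
  }
  n <- nrow(points)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rad <- (p / 100) * scale * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  x <- points$x + rad * cos(ang)
  y <- points$y + rad * sin(ang)
  b <- point_box(points)
  if (!is.null(b)) {
    x <- x %% b[1]
    y <- y %% b[2]
  }
  out <- point_set(x, y, box = b)
  for (a in c("spacing", "h", "nn_dist"))
    attr(out, a) <- attr(points, a, exact = TRUE)
  out
}

#' Reference angle distribution of a perturbed regular lattice
#'
#' Builds the cumulative angle distribution `F_k(theta; h, p)` against which
#' observed patterns are fitted: a torus lattice of about `n_particles`
#' points at height `h` is perturbed by `p` percent (single fixed-seed
#' realisation) and the NBH-`k` angles of all particles are pooled.  On a
#' torus every particle is interior, so no edge correction is involved, and
#' for `p = 0` the result depends only on the lattice geometry.
#'
#' @param k neighbourhood rule, 1, 2 or 3.
#' @param h lattice height in `[0.5, 1]`.
#' @param p disturbance percent.
#' @param n_particles lattice size; rounded to an even-by-even grid
#'   (default 4096 = 64 x 64).
#' @param seed seed for the perturbation.
#' @param theta_n number of evaluation nodes on `(0, pi)`.
#' @return an `angle_ecdf` object (see [angle_ecdf()]).
#' @export
reference_cdf <- function(k, h, p, n_particles = 4096, seed = 1,
                          theta_n = 2048) {
  side <- max(4L, 2L * round(sqrt(n_particles) / 2))
  lat <- generate_lattice(h, spacing = 1, rows = side, cols = side,
                          wrap = TRUE)
  pert <- perturb_points(lat, p, seed = seed)
  angle_ecdf(pert, k, theta_n = theta_n)
}

#' Build a reference library of perturbed-lattice angle distributions
#'
#' One reference ECDF per node of the `(h, p)` grid, evaluated on a common
#' `theta` grid, as required by the index fit ([fit_index()]).  The default
#' grids (h step 0.005, p step 1) are finer than the index differences of
#' interest.
#'
#' @param k neighbourhood rule, 1, 2 or 3.
#' @param h_grid,p_grid fit grids; `h_grid` within `[0.5, 1]`, `p_grid`
#'   nonnegative and non-empty.
#' @param n_particles,seed,theta_n as in [reference_cdf()].
#' @param progress print progress.
#' @return an object of class `ara_reference_library` with the node
#'   coordinates `h`, `p` and the `nodes x theta_n` matrix `Fmat`.
#' @export
build_reference_library <- function(k, h_grid = seq(0.5, 1, by = 0.005),
                                    p_grid = 0:40, n_particles = 4096,
                                    seed = 1, theta_n = 2048,
                                    progress = FALSE) {
  if (length(p_grid) == 0) stop("empty p grid")
  if (length(h_grid) == 0) stop("empty h grid")
  if (any(h_grid < 0.5 | h_grid > 1)) stop("h grid must lie within [0.5, 1]")
  if (any(p_grid < 0)) stop("p grid must be nonnegative")
  hs <- rep(h_grid, each = length(p_grid))
  ps <- rep(p_grid, times = length(h_grid))
  Fmat <- matrix(0, length(hs), theta_n)
  side <- max(4L, 2L * round(sqrt(n_particles) / 2))
  q <- 0L
  for (h in h_grid) {
    lat <- generate_lattice(h, spacing = 1, rows = side, cols = side,
                            wrap = TRUE)
    for (p in p_grid) {
      q <- q + 1L
      pert <- perturb_points(lat, p, seed = seed)
      Fmat[q, ] <- angle_ecdf(pert, k, theta_n = theta_n)$F
      if (progress && q %% 250 == 0)
        message(sprintf("reference library %d/%d", q, length(hs)))
    }
  }
  structure(list(k = k, h = hs, p = ps, Fmat = Fmat, theta = theta_grid(theta_n),
                 n_particles = n_particles, seed = seed),
            class = "ara_reference_library")
}

#' @export
print.ara_reference_library <- function(x, ...) {
  cat(sprintf("reference library: NBH-%d, %d (h, p) nodes, h in [%g, %g], p in [%g, %g]\n",
              x$k, length(x$h), min(x$h), max(x$h), min(x$p), max(x$p)))
  cat(sprintf("  %d particles per node, seed %d\n", x$n_particles, x$seed))
  invisible(x)
}

#' Persist and reload a reference library
#'
#' @param library an `ara_reference_library`.
#' @param path file path.
#' @return `load_reference_library()` returns the library, bit-identically.
#' @export
save_reference_library <- function(library, path) {
  stopifnot(inherits(library, "ara_reference_library"))
  saveRDS(library, path)
  invisible(path)
}

#' @rdname save_reference_library
#' @export
load_reference_library <- function(path) {
  lib <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!inherits(lib, "ara_reference_library")) {
    warning("corrupt reference library cache at ", path)
    return(NULL)
  }
  lib
}

# session-level cache; libraries are deterministic in their parameters
cached_reference_library <- function(k, pmax, h_grid = seq(0.5, 1, by = 0.005),
                                     n_particles = 4096, seed = 1,
                                     theta_n = 2048) {
  key <- paste("lib", k, pmax, length(h_grid), min(h_grid), max(h_grid),
               n_particles, seed, theta_n, sep = "_")
  lib <- .aratile_cache[[key]]
  if (is.null(lib)) {
    lib <- build_reference_library(k, h_grid, 0:pmax, n_particles, seed,
                                   theta_n)
    .aratile_cache[[key]] <- lib
  }
  lib
}
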