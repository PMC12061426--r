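#' Periodic computational grid
#'
#' A square grid of `N x N` cells over the periodic domain `(-L, L)^2`.  The
#' sensing radius of the interaction kernels is 1, so the domain must satisfy
#' `2L > 1` or a cell would interact with its own periodic image.
#'
#' @param N cells per side (even).
#' @param L domain half-width (default 2.8, i.e. the domain `(-2.8, 2.8)^2`).
#' @return an object of class `ara_grid` with elements `N`, `L`, `dx` and the
#'   cell-centre coordinates `centers`.
#' @export
ara_grid <- function(N = 128, L = 2.8) {
  N <- as.integer(N)
  if (N < 2 || N %% 2 != 0) stop("N must be an even integer >= 2")
  if (!(2 * L > 1))
    stop("configuration error: sensing radius 1 must be smaller than the ",
         "domain size 2L (self-interaction wraparound)")
  dx <- 2 * L / N
  structure(list(N = N, L = L, dx = dx,
                 centers = -L + (seq_len(N) - 0.5) * dx),
            class = "ara_grid")
}

#' @export
print.ara_grid <- function(x, ...) {
  cat(sprintf("periodic grid: %d x %d cells on (-%g, %g)^2, dx = %g\n",
              x$N, x$N, x$L, x$L, x$dx))
  invisible(x)
}

# The finest kernel feature (the adhesion band [0, R0)) must be resolved:
# refuse dx >= R0, warn when the band spans fewer than 3 cells.
check_grid_resolution <- function(grid, kernels) {
  r0 <- min(vapply(kernels_as_list(kernels), function(k) k$R0, 0))
  if (grid$dx >= r0)
    stop("grid too coarse: dx = ", signif(grid$dx, 4),
         " does not resolve the adhesion band R0 = ", r0)
  if (grid$dx > r0 / 3)
    warning("adhesion band R0 = ", r0, " spans fewer than 3 cells (dx = ",
            signif(grid$dx, 4), "); consider a finer grid", call. = FALSE)
  invisible(grid)
}

kernels_as_list <- function(kernels) {
  if (inherits(kernels, "ara_kernel")) list(kernels)
  else if (inherits(kernels, "ara_kernel_matrix")) kernels[seq_along(kernels)]
  else stop("kernels must be an ara_kernel or an ara_kernel_matrix")
}

#' Species state on a grid
#'
#' Bundles one density field (single-species model) or the three fields
#' `u, v, w` of the R7/R8/Mi1 system with the grid and the simulated time.
#'
#' @param fields a named list of `N x N` matrices of nonnegative cell
#'   averages: `list(u = ...)` or `list(u = , v = , w = )`.
#' @param grid an [ara_grid()].
#' @param t simulation time.
#' @return an object of class `ara_state`.
#' @export
ara_state <- function(fields, grid, t = 0) {
  stopifnot(inherits(grid, "ara_grid"))
  if (!length(fields) %in% c(1L, 3L))
    stop("fields must hold 1 (single-species) or 3 (R7/R8/Mi1) matrices")
  for (f in fields) {
    if (!is.matrix(f) || !all(dim(f) == grid$N))
      stop("each field must be an N x N matrix matching the grid")
    if (any(f < 0)) stop("density fields must be nonnegative")
  }
  names(fields) <- if (length(fields) == 1) "u" else c("u", "v", "w")
  structure(list(fields = fields, grid = grid, t = t), class = "ara_state")
}

#' Total cell density
#'
#' @param state an [ara_state()].
#' @return the matrix `sigma = u + v + w` (or `u` for a single species).
#' @export
total_density <- function(state) {
  Reduce(`+`, state$fields)
}

#' Per-species mass
#'
#' @param state an [ara_state()].
#' @return named vector of `sum(field) * dx^2` per species.
#' @export
species_mass <- function(state) {
  vapply(state$fields, function(f) sum(f) * state$grid$dx^2, 0)
}

#' @export
print.ara_state <- function(x, ...) {
  cat(sprintf("ara_state: %d species on %dx%d grid, t = %g\n",
              length(x$fields), x$grid$N, x$grid$N, x$t))
  m <- species_mass(x)
  cat("  mass:", paste(sprintf("%s = %.6g", names(m), m), collapse = ", "), "\n")
  invisible(x)
}

#' Disk initial condition
#'
#' Constant density `level` inside a disk centred at the origin, 0 outside;
#' the cell value is set from the cell-centre position.
#'
#' @param grid an [ara_grid()].
#' @param level density inside the disk (default 0.1).
#' @param radius disk radius (default 0.2; must be `< L`).
#' @return an `N x N` density matrix.
#' @export
disk_initial <- function(grid, level = 0.1, radius = 0.2) {
  stopifnot(inherits(grid, "ara_grid"), radius >= 0, radius < grid$L)
  r2 <- outer(grid$centers^2, grid$centers^2, `+`)
  level * (r2 < radius^2)
}

#' Three-species initial condition from column centres
#'
#' Builds the R7/R8/Mi1 state used to start simulations from an observed (or
#' synthetic) column pattern: with `d` the periodic distance from a cell
#' centre to the nearest column centre, `u = 0.2` where `d < 0.04`,
#' `v = 0.1` where `0.04 <= d < 0.12` and `w = 0.04` where `d >= 0.12`.
#' Centres are expected to be rescaled beforehand so that the mean
#' nearest-neighbour distance is 0.61 (see [rescale_to_mean_nn()]).
#'
#' @param points a [point_set()] of column centres inside the domain.
#' @param grid an [ara_grid()].
#' @param r_u,r_v radii of the R7 core and the R8 annulus.
#' @param level_u,level_v,level_w the three density levels.
#' @return an [ara_state()] with fields `u`, `v`, `w`.
#' @export
initial_from_points <- function(points, grid, r_u = 0.04, r_v = 0.12,
                                level_u = 0.2, level_v = 0.1, level_w = 0.04) {
  stopifnot(inherits(grid, "ara_grid"))
  pts <- as.data.frame(points)
  if (nrow(pts) == 0) stop("empty point set")
  side <- 2 * grid$L
  d2 <- matrix(Inf, grid$N, grid$N)
  cx <- grid$centers
  for (q in seq_len(nrow(pts))) {
    ddx <- cx - pts$x[q]
    ddx <- ddx - side * round(ddx / side)
    ddy <- cx - pts$y[q]
    ddy <- ddy - side * round(ddy / side)
    d2 <- pmin(d2, outer(ddx^2, ddy^2, `+`))
  }
  d <- sqrt(d2)
  u <- level_u * (d < r_u)
  v <- level_v * (d >= r_u & d < r_v)
  w <- level_w * (d >= r_v)
  ara_state(list(u = u, v = v, w = w), grid)
}
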