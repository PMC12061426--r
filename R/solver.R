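## Nonlocal term and time integration for the single- and three-species
## models.  The heavy lifting is in compiled code (src/solver.cpp); this file
## builds the quadrature stencils and exposes the user-facing interface.

# Cartesian vector stencil for one kernel on one grid: the weight attached to
# the cell-centre offset y is w(y) = omega(|y|) * (y/|y|) * dx^2, zero at the
# origin and beyond the sensing radius.  Offsets are stored wraparound-indexed
# so compiled code can apply them as a circular cross-correlation.  Offsets
# whose centre lands exactly on a band breakpoint take the right-hand band,
# inheriting the half-open convention of kernel_eval().
build_stencil <- function(kernel, grid) {
  N <- grid$N
  m <- 0:(N - 1)
  off <- ifelse(m < N / 2, m, m - N) * grid$dx
  yx <- matrix(off, N, N)
  yy <- matrix(off, N, N, byrow = TRUE)
  r <- sqrt(yx^2 + yy^2)
  w <- kernel_eval(kernel, r) * grid$dx^2
  wx <- ifelse(r > 0, w * yx / r, 0)
  wy <- ifelse(r > 0, w * yy / r, 0)
  list(wx = wx, wy = wy)
}

# ns x ns stencil list in row-major order, as the compiled code expects
build_stencils <- function(kernels, grid, check = TRUE) {
  if (check) check_grid_resolution(grid, kernels)
  if (inherits(kernels, "ara_kernel"))
    return(list(build_stencil(kernels, grid)))
  stopifnot(inherits(kernels, "ara_kernel_matrix"))
  out <- vector("list", 9)
  idx <- 1
  for (i in 1:3) for (j in 1:3) {
    out[[idx]] <- build_stencil(kernels[[i, j]], grid)
    idx <- idx + 1
  }
  out
}

match_kernels_state <- function(state, kernels) {
  ns <- length(state$fields)
  if (ns == 1 && !inherits(kernels, "ara_kernel"))
    stop("a single-species state needs a single ara_kernel")
  if (ns == 3 && !inherits(kernels, "ara_kernel_matrix"))
    stop("a three-species state needs an ara_kernel_matrix")
  invisible(ns)
}

#' Nonlocal interaction term
#'
#' Evaluates the drift field
#' \deqn{K_i(x) = \sum_j \int_{|y| \le 1} u_j(x+y)\,\omega_{ij}(|y|)\,
#'   \frac{y}{|y|}\, dy}
#' for every species on the grid, by applying a precomputed cell-centre
#' stencil either through the FFT (default) or by direct summation over the
#' quadrature nodes.  The two methods evaluate the identical discrete sum and
#' agree to round-off; the direct path is provided for cross-validation and
#' costs `O(N^2 M)`.
#'
#' @param state an [ara_state()].
#' @param kernels an [ara_kernel()] (single species) or
#'   [interaction_matrix()] (three species).
#' @param method `"fft"` or `"direct"`.
#' @return a list, one element per species, each with matrices `Kx`, `Ky`.
#' @export
nonlocal_term <- function(state, kernels, method = c("fft", "direct")) {
  method <- match.arg(method)
  match_kernels_state(state, kernels)
  st <- build_stencils(kernels, state$grid, check = FALSE)
  f <- unname(state$fields)
  if (method == "fft") nonlocal_fft_cpp(f, st) else nonlocal_direct_cpp(f, st)
}

#' One explicit upwind finite-volume step
#'
#' Advances the state by one conservative update.  Face velocities combine
#' the nonlinear-diffusion part (central two-point gradient of the total
#' density) and the advective part `(1 - sigma) K_i` (saturation clamped at
#' 0 from below); the donor cell is chosen by the sign of the face velocity.
#' With `dt = NULL` the admissible step `cfl * dt_max` is used; an explicit
#' `dt` beyond the stability restriction aborts, reporting the admissible
#' value.
#'
#' @param state an [ara_state()].
#' @param kernels kernel or kernel matrix matching the state.
#' @param dt time step, or `NULL` for the admissible step.
#' @param cfl safety factor for the automatic step (default 0.9).
#' @return the updated [ara_state()].
#' @export
ara_step <- function(state, kernels, dt = NULL, cfl = 0.9) {
  match_kernels_state(state, kernels)
  st <- build_stencils(kernels, state$grid)
  res <- ara_step_cpp(unname(state$fields), st, state$grid$L,
                      if (is.null(dt)) -1 else dt, cfl)
  out <- ara_state(res$fields, state$grid, t = state$t + res$dt)
  out
}

#' Run the model to a numerical steady state
#'
#' Integrates the single-species model
#' \deqn{u_t = \nabla\cdot(u \nabla u) - \nabla\cdot(u (1-u) K(u))}
#' or the three-species system (with common pressure `sigma = u+v+w` and
#' saturation `1 - sigma`) until the discrete `l2(Omega)` distance between
#' the solutions at time `t` and `t - 1` falls below `tol`, comparing states
#' one time unit apart, not one step apart.  The time step is recomputed
#' every step from the explicit stability restriction
#' `dt = cfl * min(dx^2 / (4 max sigma), dx / (2 max |velocity|))`
#' (plus a strict donor-cell positivity bound), so the scheme conserves each
#' species' mass to round-off and keeps densities nonnegative.
#'
#' @param state initial [ara_state()].
#' @param kernels kernel ([ara_kernel()]) or kernel matrix
#'   ([interaction_matrix()]) matching the number of species.
#' @param tol steady-state tolerance on the one-time-unit residual
#'   (default `1e-5`).
#' @param t_max hard cap on simulated time; if reached first the run is
#'   flagged non-converged.
#' @param cfl stability safety factor.
#' @param check_interval spacing of the residual checks (default 1 time
#'   unit).
#' @param max_steps hard cap on step count.
#' @param dt_max optional cap on the time step.
#' @return an object of class `ara_run`: the final `state`, `converged`
#'   flag, data frame `residuals` (time, residual), step count, and the
#'   initial/final per-species mass.
#' @export
ara_simulate <- function(state, kernels, tol = 1e-5, t_max = 200, cfl = 0.9,
                         check_interval = 1, max_steps = 5e6, dt_max = Inf) {
  stopifnot(tol > 0, t_max > state$t)
  match_kernels_state(state, kernels)
  st <- build_stencils(kernels, state$grid)
  mass0 <- species_mass(state)
  elapsed <- system.time(
    res <- ara_run_cpp(unname(state$fields), st, state$grid$L, tol, state$t,
                       t_max, cfl, check_interval, as.integer(max_steps),
                       dt_max)
  )[["elapsed"]]
  final <- ara_state(res$fields, state$grid, t = res$t)
  structure(list(state = final, converged = res$converged,
                 residuals = data.frame(time = res$res_times,
                                        residual = res$res_values),
                 steps = res$steps, mass_initial = mass0,
                 mass_final = species_mass(final),
                 settings = list(tol = tol, t_max = t_max, cfl = cfl,
                                 check_interval = check_interval),
                 elapsed = elapsed),
            class = "ara_run")
}

#' @export
print.ara_run <- function(x, ...) {
  cat(sprintf("ara_run: %s at t = %.4g after %d steps (%.1f s)\n",
              if (x$converged) "steady state" else "NOT converged",
              x$state$t, x$steps, x$elapsed))
  if (nrow(x$residuals))
    cat(sprintf("  last residual %.3g (tol %.3g)\n",
                x$residuals$residual[nrow(x$residuals)], x$settings$tol))
  drift <- abs(x$mass_final - x$mass_initial) / pmax(x$mass_initial, 1e-300)
  cat(sprintf("  relative mass drift: %s\n",
              paste(signif(drift, 3), collapse = ", ")))
  invisible(x)
}

#' Plot a simulation result
#'
#' Images the total density of the final state (or one species).
#'
#' @param x an `ara_run`.
#' @param species `"sigma"` for the total density or one of `"u"`, `"v"`,
#'   `"w"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ara_run <- function(x, species = "sigma", ...) {
  f <- if (species == "sigma") total_density(x$state) else
    x$state$fields[[species]]
  g <- x$state$grid
  image(g$centers, g$centers, f, asp = 1, xlab = "x", ylab = "y",
        col = gray.colors(64, start = 1, end = 0), ...)
  invisible(x)
}
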