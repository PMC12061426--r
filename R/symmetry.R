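## NBH-1/2/3 angle statistics and the symmetry-index fit.
##
## Angles around a home particle are defined as the gaps between azimuthally
## consecutive neighbour directions; they always sum to 360 degrees.  This is
## the unique simple definition under which the concentration values of all
## three neighbourhood rules come out right for both reference lattices:
## NBH-1 gives {90} on the square lattice and {60, 120, 180} on the
## triangular one, NBH-2 gives {45, 90} and {60}, NBH-3 gives {45} (8
## neighbours) and {60} (6 neighbours).

theta_grid <- function(n = 2048) seq_len(n) * pi / n

# trapezoidal L2 norm over (0, pi) of a function sampled on theta_grid(n),
# with the value at theta = 0 known to be 0 (both curves are CDFs of
# positive angles)
trapz_l2 <- function(d, theta) {
  th <- c(0, theta)
  dd <- c(0, d)^2
  sqrt(sum(diff(th) * (dd[-1] + dd[-length(dd)]) / 2))
}

#' Empirical cumulative distribution of pooled neighbourhood angles
#'
#' Pools the NBH-`k` angles of every home (interior) particle of a point set
#' into one sample and evaluates its empirical CDF on a fixed uniform grid
#' over `(0, pi)`.  Edge particles are excluded by the `d_med` rule (see
#' [interior_particles()]); on a torus every particle is a home particle.
#' Angles exceeding `pi` (possible under heavy perturbation) stay in the
#' sample but lie beyond the evaluation window, so `F(pi)` may fall short
#' of 1.
#'
#' @param points a [point_set()].
#' @param k neighbourhood rule: 1 (4 nearest), 2 (6 nearest) or 3 (adaptive
#'   radius `d_ave * sqrt(2) * alpha1`).
#' @param alpha1 radius factor of NBH-3 (default 1.1).
#' @param alpha2 radius factor of the home-particle rule (default 1.2).
#' @param theta_n number of evaluation nodes.
#' @return an object of class `angle_ecdf`: the sorted angle sample
#'   (radians), the `theta` grid and the ECDF values `F`, plus the number of
#'   interior particles.
#' @export
angle_ecdf <- function(points, k, alpha1 = 1.1, alpha2 = 1.2,
                       theta_n = 2048) {
  stopifnot(k %in% 1:3)
  b <- point_box(points)
  res <- pooled_angles_cpp(points$x, points$y, as.integer(k),
                           !is.null(b), if (is.null(b)) 0 else b[1],
                           if (is.null(b)) 0 else b[2], alpha1, alpha2)
  if (length(res$angles) == 0)
    stop("no angles could be pooled (no interior particles)")
  angle_ecdf_from_sample(res$angles, theta_n,
                         n_interior = sum(res$interior),
                         d_med = res$d_med)
}

# build an angle_ecdf object from a raw pooled sample (radians)
angle_ecdf_from_sample <- function(angles, theta_n = 2048, n_interior = NA,
                                   d_med = NA) {
  angles <- sort(angles)
  theta <- theta_grid(theta_n)
  structure(list(angles = angles, n = length(angles), theta = theta,
                 F = findInterval(theta, angles) / length(angles),
                 n_interior = n_interior, d_med = d_med),
            class = "angle_ecdf")
}

#' @export
print.angle_ecdf <- function(x, ...) {
  cat(sprintf("angle ECDF: %d pooled angles%s, F(pi) = %.4f\n", x$n,
              if (is.na(x$n_interior)) "" else
                sprintf(" from %d interior particles", x$n_interior),
              x$F[length(x$F)]))
  invisible(x)
}

#' L2 distance between two angle ECDFs
#'
#' The discrete `L2(0, pi)` norm of the difference of two ECDFs sampled on
#' the same `theta` grid (trapezoidal quadrature; both CDFs vanish at 0).
#'
#' @param f,g `angle_ecdf` objects on a common grid.
#' @return the scalar error `E >= 0`.
#' @export
ecdf_l2 <- function(f, g) {
  if (length(f$theta) != length(g$theta) ||
      any(f$theta != g$theta))
    stop("ECDFs are evaluated on different theta grids")
  trapz_l2(f$F - g$F, f$theta)
}

## ---- per-home angle operations (reference implementation) -----------------

# displacement of every other point from the home particle, minimum-image if
# periodic
home_displacements <- function(points, home) {
  b <- point_box(points)
  dx <- points$x - points$x[home]
  dy <- points$y - points$y[home]
  if (!is.null(b)) {
    dx <- dx - b[1] * round(dx / b[1])
    dy <- dy - b[2] * round(dy / b[2])
  }
  cbind(dx, dy)[-home, , drop = FALSE]
}

# gaps between azimuthally consecutive directions; ties in azimuth broken by
# the (original) point index
gap_angles <- function(disp, idx) {
  az <- atan2(disp[, 2], disp[, 1])
  o <- order(az, idx)
  az <- az[o]
  m <- length(az)
  c(diff(az), az[1] + 2 * pi - az[m])
}

# k nearest others of the home particle, ties by point index
nearest_of_home <- function(points, home, k) {
  disp <- home_displacements(points, home)
  idx <- seq_len(nrow(points))[-home]
  d <- sqrt(disp[, 1]^2 + disp[, 2]^2)
  o <- order(d, idx)[seq_len(k)]
  list(disp = disp[o, , drop = FALSE], idx = idx[o], d = d[o])
}

#' Neighbourhood angles of one home particle
#'
#' The NBH-1 rule collects the directions to the 4 nearest neighbours,
#' NBH-2 to the 6 nearest, and NBH-3 to all particles within
#' `d_ave * sqrt(2) * alpha1` of the home particle, where `d_ave` is the
#' mean distance to its 4 nearest neighbours.  In each case the returned
#' angles are the gaps between azimuthally consecutive directions (radians;
#' they sum to `2*pi`).  Exact distance or azimuth ties, which occur on
#' perfect lattices, are broken by point index.
#'
#' These are the transparent single-particle reference implementations; the
#' pooled statistics used by the fits ([angle_ecdf()]) run in compiled code.
#'
#' @param points a [point_set()].
#' @param home index of the home particle.
#' @param alpha1 radius factor of NBH-3.
#' @param degrees return degrees instead of radians.
#' @return numeric vector of angles; for NBH-3 a home particle with fewer
#'   than 2 neighbours in range contributes none (a zero-length vector, with
#'   a message).
#' @export
angles_nbh1 <- function(points, home, degrees = FALSE) {
  if (nrow(points) < 5) stop("NBH-1 needs at least 4 other particles")
  nb <- nearest_of_home(points, home, 4)
  a <- gap_angles(nb$disp, nb$idx)
  if (degrees) a * 180 / pi else a
}

#' @rdname angles_nbh1
#' @export
angles_nbh2 <- function(points, home, degrees = FALSE) {
  if (nrow(points) < 7) stop("NBH-2 needs at least 6 other particles")
  nb <- nearest_of_home(points, home, 6)
  a <- gap_angles(nb$disp, nb$idx)
  if (degrees) a * 180 / pi else a
}

#' @rdname angles_nbh1
#' @export
angles_nbh3 <- function(points, home, alpha1 = 1.1, degrees = FALSE) {
  if (nrow(points) < 5) stop("NBH-3 needs at least 4 other particles")
  nb4 <- nearest_of_home(points, home, 4)
  r3 <- mean(nb4$d) * sqrt(2) * alpha1
  disp <- home_displacements(points, home)
  idx <- seq_len(nrow(points))[-home]
  d <- sqrt(disp[, 1]^2 + disp[, 2]^2)
  keep <- d <= r3
  if (sum(keep) < 2) {
    message("home particle ", home, " has fewer than 2 neighbours in range; ",
            "no angles")
    return(numeric(0))
  }
  a <- gap_angles(disp[keep, , drop = FALSE], idx[keep])
  if (degrees) a * 180 / pi else a
}

#' Home (interior) particles of a finite point set
#'
#' A particle is a home particle when at least 6 others lie within
#' `d_med * sqrt(2) * alpha2` of it, where `d_med` is the median
#' nearest-neighbour distance of the whole set; other particles sit at the
#' edge of the cluster and contribute no angles.  With the default
#' `alpha2 = 1.2` the radius (about `1.7 d_med`) captures the diagonal
#' neighbours of a tetragonal lattice under perturbations of roughly 20
#' percent while excluding particles two positions away.  On a torus the
#' rule keeps every particle.
#'
#' @param points a [point_set()] with at least 7 points.
#' @param alpha2 radius factor (default 1.2).
#' @return the subset `point_set` of home particles, with their indices in
#'   attribute `interior_index`.
#' @export
interior_particles <- function(points, alpha2 = 1.2) {
  n <- nrow(points)
  if (n < 7) stop("at least 7 points are needed to identify home particles")
  D <- point_dist(points)
  diag(D) <- Inf
  d_med <- median(apply(D, 1, min))
  keep <- rowSums(D <= d_med * sqrt(2) * alpha2) >= 6
  out <- if (any(keep)) {
    point_set(points$x[keep], points$y[keep], box = point_box(points))
  } else {
    structure(data.frame(x = numeric(0), y = numeric(0)),
              box = point_box(points), class = c("point_set", "data.frame"))
  }
  attr(out, "interior_index") <- which(keep)
  out
}

## ---- the index fit ---------------------------------------------------------

#' Fit a symmetry index to an angle ECDF
#'
#' Finds the perturbed regular lattice whose angle distribution best matches
#' the data in the `L2(0, pi)` sense:
#' \deqn{(h^*, p^*) = \mathrm{argmin}_{0.5 \le h \le 1,\ 0 \le p \le p_{max}}
#'   \| F^{data}_k - F_k(\cdot; h, p) \|_{L^2(0,\pi)}}
#' by exhaustive search over the reference-library grid.  Ties are broken in
#' favour of smaller `p`, then smaller `h`.  The fitted height `h*` is the
#' symmetry index: 1/2 for a tetragonal pattern, `sqrt(3)/2 ~ 0.866` for a
#' hexagonal one.
#'
#' @param f_data an [angle_ecdf()] of the observed pattern.
#' @param k neighbourhood rule the data were pooled with.
#' @param library an [build_reference_library()] result; built (and cached
#'   for the session) if `NULL`.
#' @param pmax maximal disturbance percent searched (default 40; library
#'   nodes beyond `pmax` are ignored).
#' @return an object of class `symmetry_fit` with elements `k`, `h`
#'   (Index-k), `p`, `E`, the data and fitted reference curves, and the
#'   search grids.
#' @export
fit_index <- function(f_data, k, library = NULL, pmax = 40) {
  stopifnot(inherits(f_data, "angle_ecdf"), k %in% 1:3)
  if (is.null(library))
    library <- cached_reference_library(k, pmax,
                                        theta_n = length(f_data$theta))
  if (!inherits(library, "ara_reference_library") || length(library$h) == 0)
    stop("empty or invalid reference library")
  if (library$k != k)
    stop("reference library was built for NBH-", library$k, ", not NBH-", k)
  if (length(library$theta) != length(f_data$theta))
    stop("library and data use different theta grids")
  sel <- library$p <= pmax
  if (!any(sel)) stop("library does not cover p <= pmax")
  if (max(library$p[sel]) < pmax)
    warning("library only covers p <= ", max(library$p[sel]),
            " of the requested pmax = ", pmax)
  hs <- library$h[sel]
  ps <- library$p[sel]
  Fm <- library$Fmat[sel, , drop = FALSE]

  theta <- f_data$theta
  th <- c(0, theta)
  wts <- numeric(length(th))
  dt <- diff(th)
  wts[-1] <- wts[-1] + dt / 2
  wts[-length(wts)] <- wts[-length(wts)] + dt / 2
  wts <- wts[-1]                       # the value at theta = 0 is always 0
  diffs <- sweep(Fm, 2, f_data$F)
  E <- sqrt(as.vector(diffs^2 %*% wts))

  o <- order(ps, hs)                   # tie-break: smaller p, then smaller h
  best <- o[which.min(E[o])]
  structure(list(k = k, h = hs[best], p = ps[best], E = E[best],
                 ecdf_data = f_data, F_ref = Fm[best, ], theta = theta,
                 pmax = pmax, h_grid = sort(unique(hs)),
                 p_grid = sort(unique(ps)),
                 E_grid = data.frame(h = hs, p = ps, E = E),
                 n_interior = f_data$n_interior, n_angles = f_data$n),
            class = "symmetry_fit")
}

#' Symmetry index of a point pattern
#'
#' The one-call estimator: pools the NBH-`k` angles of the pattern,
#' builds/uses a perturbed-lattice reference library and fits `(h*, p*)`
#' (see [fit_index()]).
#'
#' @param points a [point_set()] (at least 7 points, some of them interior).
#' @param k neighbourhood rule (default 3, the headline index).
#' @param pmax maximal disturbance percent (default 40 for observed
#'   patterns; 30 is used inside parameter sweeps).
#' @param library optional prebuilt reference library.
#' @param alpha1,alpha2,theta_n see [angle_ecdf()].
#' @return a `symmetry_fit`.
#' @examples
#' \donttest{
#' sq <- generate_lattice(0.5, rows = 16, cols = 16, wrap = TRUE)
#' fit <- symmetry_fit(sq, k = 3, pmax = 2)
#' coef(fit)   # h = 0.5: tetragonal
#' }
#' @export
symmetry_fit <- function(points, k = 3, pmax = 40, library = NULL,
                         alpha1 = 1.1, alpha2 = 1.2, theta_n = 2048) {
  f <- angle_ecdf(points, k, alpha1 = alpha1, alpha2 = alpha2,
                  theta_n = theta_n)
  fit_index(f, k, library = library, pmax = pmax)
}

#' Indices 1, 2 and 3 of a point pattern
#'
#' Runs [symmetry_fit()] for all three neighbourhood rules.  Index-3 is the
#' headline index (its neighbourhood adapts to the local spacing instead of
#' fixing a neighbour count).
#'
#' @inheritParams symmetry_fit
#' @param library optional list of three prebuilt reference libraries, one
#'   per neighbourhood rule.
#' @return an object of class `symmetry_index_set`: a list of three
#'   `symmetry_fit`s with a tabular print method.
#' @export
compute_indices <- function(points, pmax = 40, library = NULL,
                            alpha1 = 1.1, alpha2 = 1.2, theta_n = 2048) {
  fits <- lapply(1:3, function(k)
    symmetry_fit(points, k = k, pmax = pmax,
                 library = if (is.null(library)) NULL else library[[k]],
                 alpha1 = alpha1, alpha2 = alpha2, theta_n = theta_n))
  structure(list(fits = fits, headline = 3L), class = "symmetry_index_set")
}

#' @export
print.symmetry_index_set <- function(x, ...) {
  cat("symmetry indices (h* = 1/2 tetragonal, sqrt(3)/2 hexagonal):\n")
  for (f in x$fits)
    cat(sprintf("  Index-%d = %.4f  (p* = %g%%, E = %.6f)%s\n", f$k, f$h,
                f$p, f$E, if (f$k == x$headline) "  <- headline" else ""))
  invisible(x)
}

#' @export
as.data.frame.symmetry_index_set <- function(x, ...) {
  do.call(rbind, lapply(x$fits, function(f)
    data.frame(k = f$k, h_star = f$h, p_star = f$p, E = f$E,
               n_interior = f$n_interior, n_angles = f$n_angles)))
}

## ---- symmetry_fit methods --------------------------------------------------

#' @export
print.symmetry_fit <- function(x, ...) {
  cat(sprintf("symmetry fit (NBH-%d): Index-%d = %.4f, p* = %g%%, E = %.6f\n",
              x$k, x$k, x$h, x$p, x$E))
  cat(sprintf("  pattern: %s (h = 0.5 tetragonal, %.4f hexagonal)\n",
              if (abs(x$h - 0.5) < abs(x$h - sqrt(3) / 2)) "nearer tetragonal"
              else "nearer hexagonal", sqrt(3) / 2))
  cat(sprintf("  %s angles pooled from %s interior particles; pmax = %g\n",
              x$n_angles, x$n_interior, x$pmax))
  invisible(x)
}

#' @export
summary.symmetry_fit <- function(object, ...) {
  print(object)
  Eg <- object$E_grid
  bh <- tapply(Eg$E, Eg$h, min)
  cat("  E profile over h (min over p): best",
      sprintf("%.6f at h = %.3f;", min(Eg$E), object$h),
      sprintf("worst %.6f", max(bh)), "\n")
  invisible(object)
}

#' @export
coef.symmetry_fit <- function(object, ...) {
  c(h = object$h, p = object$p)
}

#' @export
fitted.symmetry_fit <- function(object, ...) {
  object$F_ref
}

#' @export
residuals.symmetry_fit <- function(object, ...) {
  object$ecdf_data$F - object$F_ref
}

#' Plot a symmetry fit
#'
#' Overlays the data ECDF and the fitted perturbed-lattice reference CDF on
#' `(0, pi)`.
#'
#' @param x a `symmetry_fit`.
#' @param ... passed to [plot()].
#' @export
plot.symmetry_fit <- function(x, ...) {
  deg <- x$theta * 180 / pi
  graphics::plot(deg, x$ecdf_data$F, type = "l", col = "darkgreen", lwd = 2,
                 xlab = "angle (degrees)", ylab = "cumulative distribution",
                 main = sprintf("NBH-%d: h* = %.3f, p* = %g%%", x$k, x$h, x$p),
                 ylim = c(0, 1), ...)
  lines(deg, x$F_ref, col = "magenta", lwd = 2, lty = 2)
  legend("bottomright", c("data", "fitted lattice"), lwd = 2, lty = c(1, 2),
         col = c("darkgreen", "magenta"), bty = "n")
  invisible(x)
}
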