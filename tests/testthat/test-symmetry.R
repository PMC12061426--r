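test_that("home-particle rule keeps exactly the interior of a square patch", {
  sq <- point_set(rep(1:20, times = 20), rep(1:20, each = 20))
  kept <- interior_particles(sq)
  expect_equal(nrow(kept), 324)            # inner 18 x 18
  # corners (3 in range) and edges (5) are excluded; the second ring (8) stays
  expect_setequal(attr(kept, "interior_index"),
                  which(sq$x > 1 & sq$x < 20 & sq$y > 1 & sq$y < 20))
})

test_that("degenerate sets have no home particles, small sets error", {
  line <- point_set(1:7, rep(0, 7))
  expect_equal(nrow(suppressWarnings(interior_particles(line))), 0)
  expect_error(interior_particles(point_set(1:6, rep(0, 6))), "7 points")
})

test_that("NBH-1 gap angles on the reference lattices", {
  sq <- generate_lattice(0.5, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(angles_nbh1(sq, 25, degrees = TRUE), rep(90, 4))
  hex <- generate_lattice(sqrt(3) / 2, rows = 10, cols = 10, wrap = TRUE)
  a <- sort(angles_nbh1(hex, 25, degrees = TRUE))
  expect_equal(sum(a), 360)
  expect_true(all(vapply(a, function(v)
    min(abs(v - c(60, 120, 180))) < 1e-9, TRUE)))
  expect_error(angles_nbh1(point_set(1:4, rep(0, 4)), 1), "4 other")
})

test_that("NBH-2 on the square lattice is independent of the diagonal tie", {
  # 4 diagonal neighbours tie for ranks 5-6; every choice of 2 gives the same
  # multiset {45, 45, 45, 45, 90, 90}
  base <- generate_lattice(0.5, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(sort(angles_nbh2(base, 13, degrees = TRUE)),
               c(45, 45, 45, 45, 90, 90))
  # relabelling the points changes which tied diagonals are picked
  for (perm in list(nrow(base):1, c(2:nrow(base), 1))) {
    shuffled <- point_set(base$x[perm], base$y[perm], box = attr(base, "box"))
    home <- which(perm == 13)
    expect_equal(sort(angles_nbh2(shuffled, home, degrees = TRUE)),
                 c(45, 45, 45, 45, 90, 90))
  }
  hex <- generate_lattice(sqrt(3) / 2, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(angles_nbh2(hex, 13, degrees = TRUE), rep(60, 6))
})

test_that("NBH-3 adaptive neighbourhood: 8 at 45 (square), 6 at 60 (hexagonal)", {
  sq <- generate_lattice(0.5, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(angles_nbh3(sq, 13, degrees = TRUE), rep(45, 8))
  hex <- generate_lattice(sqrt(3) / 2, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(angles_nbh3(hex, 13, degrees = TRUE), rep(60, 6))
  # scale invariance: d_ave rescales with the pattern
  sq2 <- generate_lattice(0.5, spacing = 7.3, rows = 10, cols = 10, wrap = TRUE)
  expect_equal(angles_nbh3(sq2, 13, degrees = TRUE), rep(45, 8))
})

test_that("gap angles always sum to a full turn", {
  set.seed(31)
  for (rep in 1:5) {
    pts <- perturb_points(generate_lattice(runif(1, 0.5, 1), rows = 8,
                                           cols = 8, wrap = TRUE),
                          25, seed = rep)
    for (home in sample(nrow(pts), 4)) {
      expect_equal(sum(angles_nbh1(pts, home)), 2 * pi, tolerance = 1e-12)
      expect_equal(sum(angles_nbh2(pts, home)), 2 * pi, tolerance = 1e-12)
      a3 <- suppressMessages(angles_nbh3(pts, home))
      if (length(a3)) expect_equal(sum(a3), 2 * pi, tolerance = 1e-12)
    }
  }
})

test_that("compiled pooling agrees with the per-home reference path", {
  set.seed(32)
  for (k in 1:3) {
    # torus
    tor <- perturb_points(generate_lattice(0.72, rows = 8, cols = 8,
                                           wrap = TRUE), 15, seed = 40 + k)
    expect_equal(sort(angle_ecdf(tor, k)$angles), sort(pool_angles_r(tor, k)),
                 tolerance = 1e-12)
    # finite patch with edge exclusion
    pl <- perturb_points(generate_lattice(0.60, rows = 9, cols = 9), 10,
                         seed = 50 + k)
    expect_equal(sort(angle_ecdf(pl, k)$angles), sort(pool_angles_r(pl, k)),
                 tolerance = 1e-12)
  }
})

test_that("pooling is invariant under duplicating the pattern far away", {
  lat <- perturb_points(generate_lattice(0.65, rows = 8, cols = 8), 10,
                        seed = 77)
  far <- point_set(c(lat$x, lat$x + 1000), c(lat$y, lat$y))
  e1 <- angle_ecdf(lat, 1)
  e2 <- angle_ecdf(far, 1)
  expect_equal(e2$F, e1$F)
})

test_that("ECDF L2 distance: closed forms and symmetry", {
  s45 <- aratile:::angle_ecdf_from_sample(rep(pi / 4, 10))
  s60 <- aratile:::angle_ecdf_from_sample(rep(pi / 3, 10))
  expect_equal(ecdf_l2(s45, s45), 0)
  expect_equal(ecdf_l2(s45, s60), sqrt(pi / 12), tolerance = 2e-3)
  expect_equal(ecdf_l2(s45, s60), ecdf_l2(s60, s45))
  short <- aratile:::angle_ecdf_from_sample(rep(pi / 4, 10), theta_n = 512)
  expect_error(ecdf_l2(s45, short), "grids")
})

test_that("perfect lattices are classified exactly", {
  lib <- build_reference_library(3, h_grid = seq(0.5, 1, by = 0.025),
                                 p_grid = c(0, 5, 10), n_particles = 1024)
  sq <- generate_lattice(0.5, rows = 14, cols = 14, wrap = TRUE)
  fit <- symmetry_fit(sq, k = 3, pmax = 10, library = lib)
  expect_equal(fit$h, 0.5)
  expect_equal(fit$p, 0)
  expect_equal(fit$E, 0, tolerance = 1e-12)
  hexa <- generate_lattice(sqrt(3) / 2, rows = 14, cols = 14, wrap = TRUE)
  fh <- symmetry_fit(hexa, k = 3, pmax = 10, library = lib)
  expect_lt(abs(fh$h - sqrt(3) / 2), 0.025 + 1e-9)   # within one h-grid step
  expect_equal(coef(fit), c(h = 0.5, p = 0))
  expect_equal(length(fitted(fit)), 2048)
  expect_equal(residuals(fit), fit$ecdf_data$F - fit$F_ref)
})

test_that("indices are invariant under similarity transforms of the pattern", {
  lib <- build_reference_library(3, h_grid = seq(0.5, 1, by = 0.025),
                                 p_grid = c(0, 5, 10), n_particles = 1024)
  pts <- perturb_points(generate_lattice(0.6, rows = 10, cols = 10), 8,
                        seed = 3)
  f0 <- symmetry_fit(pts, k = 3, pmax = 10, library = lib)
  th <- 0.83
  rot <- point_set(3 * (cos(th) * pts$x - sin(th) * pts$y) + 11,
                   3 * (sin(th) * pts$x + cos(th) * pts$y) - 4)
  f1 <- symmetry_fit(rot, k = 3, pmax = 10, library = lib)
  refl <- point_set(-pts$x, pts$y)
  f2 <- symmetry_fit(refl, k = 3, pmax = 10, library = lib)
  expect_equal(coef(f1), coef(f0))
  expect_equal(coef(f2), coef(f0))
  expect_equal(f1$E, f0$E, tolerance = 1e-9)
})

test_that("the fit error is smallest near the generating lattice height", {
  lib <- build_reference_library(3, h_grid = seq(0.5, 1, by = 0.05),
                                 p_grid = c(0, 10), n_particles = 1024)
  for (h0 in c(0.5, 0.7, 0.9)) {
    dat <- angle_ecdf(perturb_points(
      generate_lattice(h0, rows = 32, cols = 32, wrap = TRUE), 10,
      seed = 321), 3)
    fit <- fit_index(dat, 3, library = lib, pmax = 10)
    Eg <- fit$E_grid
    e_at <- min(Eg$E[abs(Eg$h - h0) < 1e-9])
    far <- Eg$E[abs(Eg$h - h0) >= 0.1]
    expect_true(all(e_at <= far))
  }
})

test_that("compute_indices returns all three fits with Index-3 as headline", {
  lib1 <- build_reference_library(1, h_grid = seq(0.5, 1, by = 0.05),
                                  p_grid = c(0, 5), n_particles = 576)
  lib2 <- build_reference_library(2, h_grid = seq(0.5, 1, by = 0.05),
                                  p_grid = c(0, 5), n_particles = 576)
  lib3 <- build_reference_library(3, h_grid = seq(0.5, 1, by = 0.05),
                                  p_grid = c(0, 5), n_particles = 576)
  sq <- generate_lattice(0.5, rows = 12, cols = 12, wrap = TRUE)
  idx <- compute_indices(sq, pmax = 5, library = list(lib1, lib2, lib3))
  expect_equal(vapply(idx$fits, `[[`, 0, "h"), rep(0.5, 3))
  expect_equal(idx$headline, 3L)
  df <- as.data.frame(idx)
  expect_equal(df$k, 1:3)
  expect_equal(df$h_star, rep(0.5, 3))
  expect_error(symmetry_fit(point_set(1:5, rep(0, 5)), k = 1, pmax = 5,
                            library = lib1))
})
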