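test_that("lattice family geometry: hexagonal and centered-square limits", {
  hex <- generate_lattice(sqrt(3) / 2, spacing = 1, rows = 8, cols = 8,
                          wrap = TRUE)
  expect_equal(nrow(hex), 64)
  D <- aratile:::point_dist(hex)
  diag(D) <- Inf
  sorted <- apply(D, 1, sort)
  expect_true(all(abs(sorted[1:6, ] - 1) < 1e-12))     # 6 neighbours at 1
  expect_true(all(sorted[7, ] > 1.2))
  sq <- generate_lattice(0.5, spacing = 1, rows = 8, cols = 8, wrap = TRUE)
  Ds <- aratile:::point_dist(sq)
  diag(Ds) <- Inf
  ss <- apply(Ds, 1, sort)
  expect_true(all(abs(ss[1:4, ] - sqrt(2) / 2) < 1e-12))  # 4 at s/sqrt(2)
  expect_true(all(ss[5, ] > sqrt(2) / 2 + 1e-9))
  expect_error(generate_lattice(0.4, rows = 8, cols = 8), "0.5")
  expect_error(generate_lattice(1.2, rows = 8, cols = 8), "0.5")
  expect_error(generate_lattice(0.7, rows = 2, cols = 2), "16")
})

test_that("perturbation is bounded, seeded and leaves p = 0 untouched", {
  lat <- generate_lattice(0.7, rows = 10, cols = 10, wrap = TRUE)
  expect_identical(perturb_points(lat, 0), lat)
  p1 <- perturb_points(lat, 20, seed = 5)
  p2 <- perturb_points(lat, 20, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(perturb_points(lat, 20, seed = 6), p1))
  # displacement bound: 20% of the interparticle (nearest-neighbour) distance
  nnd <- attr(lat, "nn_dist")
  dx <- p1$x - lat$x
  dx <- dx - attr(lat, "box")[1] * round(dx / attr(lat, "box")[1])
  dy <- p1$y - lat$y
  dy <- dy - attr(lat, "box")[2] * round(dy / attr(lat, "box")[2])
  expect_true(all(sqrt(dx^2 + dy^2) <= 0.20 * nnd + 1e-12))
  expect_error(perturb_points(lat, -3), ">= 0")
})

test_that("perturbation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(perturb_points(generate_lattice(0.6, rows = 6, cols = 6), 10,
                           seed = 3))
  expect_identical(runif(1), a)
})

test_that("unperturbed reference CDFs are unit steps at the lattice angles", {
  # tetragonal NBH-3: all angles exactly 45 degrees
  r45 <- reference_cdf(3, 0.5, 0, n_particles = 1024)
  expect_true(all(r45$F[r45$theta < pi / 4] == 0))
  expect_true(all(r45$F[r45$theta >= pi / 4 + 1e-9] == 1))
  # hexagonal NBH-2: step at 60 degrees
  r60 <- reference_cdf(2, sqrt(3) / 2, 0, n_particles = 1024)
  expect_true(all(r60$F[r60$theta < pi / 3 - 1e-9] == 0))
  expect_true(all(r60$F[r60$theta >= pi / 3 + 1e-9] == 1))
  # slightly perturbed tetragonal NBH-1 concentrates near 90 degrees
  r90 <- reference_cdf(1, 0.5, 0.1, n_particles = 1024, seed = 2)
  deg <- r90$angles * 180 / pi
  expect_true(all(deg > 85 & deg < 95))
})

test_that("p = 0 references depend only on geometry, and scaling changes nothing", {
  a <- reference_cdf(3, 0.7, 0, n_particles = 576, seed = 1)
  b <- reference_cdf(3, 0.7, 0, n_particles = 576, seed = 12345)
  expect_identical(a$F, b$F)
  lat1 <- generate_lattice(0.65, spacing = 1, rows = 12, cols = 12, wrap = TRUE)
  lat2 <- generate_lattice(0.65, spacing = 2, rows = 12, cols = 12, wrap = TRUE)
  e1 <- angle_ecdf(perturb_points(lat1, 10, seed = 4), 3)
  e2 <- angle_ecdf(perturb_points(lat2, 10, seed = 4), 3)
  expect_equal(sort(e1$angles), sort(e2$angles), tolerance = 1e-12)
})

test_that("torus lattices have no edge particles", {
  lat <- generate_lattice(0.8, rows = 10, cols = 10, wrap = TRUE)
  kept <- interior_particles(lat)
  expect_equal(nrow(kept), nrow(lat))
})

test_that("reference libraries are reproducible and persist bit-identically", {
  lib <- build_reference_library(3, h_grid = c(0.5, sqrt(3) / 2),
                                 p_grid = 0, n_particles = 576)
  # the two entries step at 45 and 60 degrees respectively
  F45 <- lib$Fmat[lib$h == 0.5, ]
  F60 <- lib$Fmat[lib$h != 0.5, ]
  expect_equal(F45[max(which(lib$theta < pi / 4))], 0)
  expect_equal(F45[min(which(lib$theta > pi / 4 + 1e-9))], 1)
  expect_equal(F60[max(which(lib$theta < pi / 3 - 1e-9))], 0)
  expect_equal(F60[min(which(lib$theta > pi / 3 + 1e-9))], 1)
  lib2 <- build_reference_library(3, h_grid = c(0.5, sqrt(3) / 2),
                                  p_grid = 0, n_particles = 576)
  expect_identical(lib$Fmat, lib2$Fmat)
  expect_error(build_reference_library(3, p_grid = numeric(0)), "empty p grid")
  path <- tempfile(fileext = ".rds")
  save_reference_library(lib, path)
  expect_identical(load_reference_library(path), lib)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_warning(expect_null(load_reference_library(bad)), "corrupt")
})
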