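# grids below R0/3 resolution trigger a (deliberate) coarse-grid warning;
# the nonlocal term itself is well defined at any resolution
quiet_nonlocal <- function(...) suppressWarnings(nonlocal_term(...))

test_that("nonlocal term vanishes for constant densities", {
  g <- ara_grid(48, 2.8)
  k <- reference_kernel("A")
  st <- ara_state(list(u = matrix(0.3, 48, 48)), g)
  K <- quiet_nonlocal(st, k)
  expect_lt(max(abs(K[[1]]$Kx)), 1e-10)
  expect_lt(max(abs(K[[1]]$Ky)), 1e-10)
})

test_that("a point mass in the attraction band pulls toward itself, scaled by Fa", {
  g <- ara_grid(56, 2.8)
  u <- matrix(0, 56, 56)
  probe <- c(28L, 28L)
  # place mass ~0.6 to the +x of the probe cell: the attraction band
  dcell <- round(0.6 / g$dx)
  u[probe[1] + dcell, probe[2]] <- 1
  st <- ara_state(list(u = u), g)
  k1 <- ara_kernel(F0 = 5000, Fr = -5000, Fa = 500, R0 = 0.14, R1 = 0.55, R2 = 0.58)
  k2 <- ara_kernel(F0 = 5000, Fr = -5000, Fa = 1000, R0 = 0.14, R1 = 0.55, R2 = 0.58)
  K1 <- quiet_nonlocal(st, k1, method = "direct")[[1]]
  K2 <- quiet_nonlocal(st, k2, method = "direct")[[1]]
  expect_gt(K1$Kx[probe[1], probe[2]], 0)              # toward the mass
  expect_lt(abs(K1$Ky[probe[1], probe[2]]), 1e-12)     # purely radial
  expect_equal(K2$Kx[probe[1], probe[2]] / K1$Kx[probe[1], probe[2]], 2,
               tolerance = 1e-12)                      # magnitude ~ Fa
})

test_that("FFT convolution matches the direct quadrature sum and the R oracle", {
  set.seed(11)
  for (N in c(24, 32)) {
    g <- ara_grid(N, 2.8)
    k <- ara_kernel(F0 = 1, Fr = -1, Fa = 0.5, R0 = 0.2, R1 = 0.5, R2 = 0.7)
    st <- ara_state(list(u = matrix(runif(N * N), N, N)), g)
    a <- quiet_nonlocal(st, k, method = "fft")[[1]]
    b <- quiet_nonlocal(st, k, method = "direct")[[1]]
    o <- brute_nonlocal(st$fields$u, k, g)
    expect_lt(max(abs(a$Kx - b$Kx), abs(a$Ky - b$Ky)), 1e-12)
    expect_lt(max(abs(a$Kx - o$Kx), abs(a$Ky - o$Ky)), 1e-12)
  }
})

test_that("three-species nonlocal term sums the pairwise contributions", {
  set.seed(12)
  N <- 24
  g <- ara_grid(N, 2.8)
  m <- suppressWarnings(interaction_matrix())
  fl <- lapply(1:3, function(i) matrix(runif(N * N, 0, 0.3), N, N))
  st <- ara_state(fl, g)
  K <- quiet_nonlocal(st, m)
  for (i in 1:3) {
    acc <- matrix(0, N, N)
    for (j in 1:3)
      acc <- acc + brute_nonlocal(fl[[j]], m[[i, j]], g)$Kx
    expect_lt(max(abs(K[[i]]$Kx - acc)), 1e-10)
  }
})

test_that("zero and uniform states are fixed points of the step", {
  g <- ara_grid(64)
  k <- reference_kernel("A")
  z <- ara_state(list(u = matrix(0, 64, 64)), g)
  expect_equal(suppressWarnings(ara_step(z, k))$fields$u, z$fields$u)
  uni <- ara_state(list(u = matrix(0.25, 64, 64)), g)
  s1 <- suppressWarnings(ara_step(uni, k))
  expect_lt(max(abs(s1$fields$u - 0.25)), 1e-10)
})

test_that("the explicit step conserves mass and keeps densities nonnegative", {
  set.seed(21)
  g <- ara_grid(64)
  m <- interaction_matrix()
  fl <- lapply(1:3, function(i) matrix(runif(64 * 64, 0, 0.25), 64, 64))
  st <- ara_state(fl, g)
  m0 <- species_mass(st)
  for (q in 1:20) st <- suppressWarnings(ara_step(st, m))
  m1 <- species_mass(st)
  expect_true(all(abs(m1 - m0) < 1e-12 * m0))
  expect_true(all(vapply(st$fields, min, 0) >= 0))
})

test_that("an explicit dt beyond the stability restriction aborts", {
  g <- ara_grid(64)
  k <- reference_kernel("A")
  st <- ara_state(list(u = disk_initial(g)), g)
  expect_error(suppressWarnings(ara_step(st, k, dt = 10)), "admissible")
})

test_that("an already-steady uniform field converges at the first check", {
  g <- ara_grid(64)
  k <- reference_kernel("A")
  st <- ara_state(list(u = matrix(0.2, 64, 64)), g)
  r <- suppressWarnings(ara_simulate(st, k, tol = 1e-5, t_max = 50))
  expect_true(r$converged)
  expect_equal(r$state$t, 1)           # first one-time-unit comparison
  expect_equal(nrow(r$residuals), 1)
})

test_that("fourfold-symmetric initial data evolve fourfold-symmetrically", {
  g <- ara_grid(64)
  k <- reference_kernel("A")
  st <- ara_state(list(u = disk_initial(g)), g)
  r <- suppressWarnings(ara_simulate(st, k, tol = 1e-12, t_max = 1.5))
  u <- r$state$fields$u
  rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), ]   # grid maps onto itself
  expect_lt(max(abs(u - rot90(u))), 1e-9)
})

test_that("disk initial condition has the right mass, support and linearity", {
  g <- ara_grid(128)
  u <- disk_initial(g)
  # mass = level * pi * r^2 up to boundary-cell quantisation
  quant <- 0.1 * (2 * pi * 0.2 * g$dx + pi * g$dx^2)
  expect_lt(abs(sum(u) * g$dx^2 - 0.1 * pi * 0.2^2), quant)
  expect_equal(disk_initial(g, radius = 0), matrix(0, 128, 128))
  expect_equal(disk_initial(g, level = 0.2), 2 * u)
})

test_that("initial_from_points builds disjoint concentric bands", {
  g <- ara_grid(128)
  st <- initial_from_points(point_set(0, 0), g)
  u <- st$fields$u; v <- st$fields$v; w <- st$fields$w
  expect_true(all(u * v == 0) && all(u * w == 0) && all(v * w == 0))
  expect_setequal(unique(as.vector(u)), c(0, 0.2))
  expect_setequal(unique(as.vector(v)), c(0, 0.1))
  expect_setequal(unique(as.vector(w)), c(0, 0.04))
  # every cell belongs to exactly one band
  expect_true(all((u > 0) + (v > 0) + (w > 0) == 1))
  # w vanishes only within r_v of a centre
  d <- sqrt(outer(g$centers^2, g$centers^2, `+`))
  expect_true(all((w == 0) == (d < 0.12)))
  expect_error(point_set(numeric(0), numeric(0)))   # empty sets cannot exist
  # two centres: near-field of either centre has no w
  st2 <- initial_from_points(point_set(c(0, 0.61), c(0, 0)), g)
  i0 <- which.min(abs(g$centers))
  i1 <- which.min(abs(g$centers - 0.61))
  expect_equal(st2$fields$w[i0, i0], 0)
  expect_equal(st2$fields$w[i1, i0], 0)
})
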