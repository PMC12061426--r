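# Independent oracles and shared fixtures for the test suite.

# Brute-force evaluation of the nonlocal drift by direct summation over the
# quadrature nodes (cell centres inside the unit disk), organised per target
# cell.  Independent of the package's stencil/FFT machinery.
brute_nonlocal <- function(u, kernel, grid) {
  N <- grid$N
  dx <- grid$dx
  m <- 0:(N - 1)
  off <- ifelse(m < N / 2, m, m - N) * dx
  Kx <- Ky <- matrix(0, N, N)
  idx <- which(outer(off^2, off^2, `+`) < 1 & outer(off, off, function(a, b) a != 0 | b != 0),
               arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    yx <- off[i]; yy <- off[j]
    r <- sqrt(yx^2 + yy^2)
    w <- kernel_eval(kernel, r) * dx^2
    if (w == 0) next
    shifted <- u[c(i:N, seq_len(i - 1)), c(j:N, seq_len(j - 1)), drop = FALSE]
    Kx <- Kx + shifted * (w * yx / r)
    Ky <- Ky + shifted * (w * yy / r)
  }
  list(Kx = Kx, Ky = Ky)
}

# Pool NBH-k angles through the per-home R implementations (the slow
# reference path, independent of the compiled engine).
pool_angles_r <- function(points, k, alpha1 = 1.1, alpha2 = 1.2) {
  keep <- attr(interior_particles(points, alpha2 = alpha2), "interior_index")
  fn <- switch(k, `1` = angles_nbh1, `2` = angles_nbh2,
               `3` = function(p, i) angles_nbh3(p, i, alpha1 = alpha1))
  unlist(lapply(keep, function(i) suppressMessages(fn(points, i))),
         use.names = FALSE)
}

# Shared heavy fixtures, computed once per test session.
fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name, expr) {
    if (is.null(cache[[name]])) cache[[name]] <- force(expr)
    cache[[name]]
  }
})

reference_run <- function(variant) {
  fixture(paste0("refrun_", variant), {
    g <- ara_grid(128)
    s <- ara_state(list(u = disk_initial(g)), g)
    r <- ara_simulate(s, reference_kernel(variant), tol = 1e-5, t_max = 200)
    list(run = r, grid = g,
         centers = extract_cluster_centers(r$state$fields$u, g))
  })
}

# main NBH-3 reference library, shared across fit tests (session-cached in
# the package as well)
lib3_full <- function() {
  fixture("lib3_full", aratile:::cached_reference_library(3, 30))
}
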