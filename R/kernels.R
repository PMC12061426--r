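#' Piecewise-constant interaction kernel
#'
#' An ARA (adhesion-repulsion-attraction) kernel is the radial force profile
#' felt by a cell from the density at distance `r`, in units of the sensing
#' radius (normalised to 1):
#' \deqn{\omega(r) = F_0 \; [0,R_0),\ F_r \; [R_0,R_1),\ 0 \; [R_1,R_2),\
#'       F_a \; [R_2,1),\ 0 \; [1,\infty).}
#' All intervals are half-open on the right; a radius lying exactly on a
#' breakpoint takes the constant of the band to its right.  The zero band
#' `[R1, R2)` is the "terrace" of the corresponding piecewise-linear
#' potential; its width drives the square/triangular selection of the
#' emerging cluster lattice.  Pure-adhesion kernels (used for every species
#' pair except R7-R7) are represented in the same form with
#' `Fr = Fa = 0` and `R1 = R2 = R0`.
#'
#' @param F0 adhesion strength, `> 0`.
#' @param Fr repulsion strength, `<= 0` (default 0).
#' @param Fa attraction strength, `>= 0` (default 0).
#' @param R0 outer radius of the adhesion band, in `(0, 1]`.
#' @param R1 outer radius of the repulsion band (default `R0`).
#' @param R2 outer radius of the terrace (default `R1`).
#' @return an object of class `ara_kernel`.
#' @examples
#' k <- ara_kernel(F0 = 5000, Fr = -5000, Fa = 500, R0 = 0.14, R1 = 0.55, R2 = 0.58)
#' kernel_eval(k, c(0.1, 0.3, 0.56, 0.6, 1.2))
#' @export
ara_kernel <- function(F0, Fr = 0, Fa = 0, R0, R1 = R0, R2 = R1) {
  k <- structure(list(F0 = as.numeric(F0), Fr = as.numeric(Fr),
                      Fa = as.numeric(Fa), R0 = as.numeric(R0),
                      R1 = as.numeric(R1), R2 = as.numeric(R2)),
                 class = "ara_kernel")
  validate_kernel(k)
  k
}

validate_kernel <- function(k) {
  with(k, {
    if (!(F0 > 0)) stop("invalid kernel: F0 must be > 0 (adhesion strength)")
    if (!(Fr <= 0)) stop("invalid kernel: Fr must be <= 0 (repulsion strength)")
    if (!(Fa >= 0)) stop("invalid kernel: Fa must be >= 0 (attraction strength)")
    if (!(R0 > 0)) stop("invalid kernel: R0 must be > 0")
    if (!(R0 <= R1)) stop("invalid kernel: breakpoints must satisfy R0 <= R1")
    if (!(R1 <= R2)) stop("invalid kernel: breakpoints must satisfy R1 <= R2")
    if (!(R2 <= 1)) stop("invalid kernel: R2 must be <= 1 (sensing radius)")
    if (R2 >= 1 && Fa > 0)
      warning("R2 = 1 leaves no attraction band although Fa > 0")
  })
  invisible(k)
}

#' Evaluate an interaction kernel
#'
#' @param kernel an [ara_kernel()].
#' @param r vector of radii, `>= 0`.
#' @return signed force values; positive toward the source density.
#' @export
kernel_eval <- function(kernel, r) {
  validate_kernel(kernel)
  stopifnot(all(r >= 0))
  out <- numeric(length(r))
  out[r < kernel$R0] <- kernel$F0
  out[r >= kernel$R0 & r < kernel$R1] <- kernel$Fr
  out[r >= kernel$R2 & r < 1] <- kernel$Fa
  out
}

#' Interaction potential
#'
#' The continuous piecewise-linear antiderivative `U(r)` of the kernel, with
#' `U(0) = 0`.  `U` is constant on the terrace `[R1, R2)` and beyond the
#' sensing radius (`1 <= r`).
#'
#' @inheritParams kernel_eval
#' @return potential values `U(r)`.
#' @export
kernel_potential <- function(kernel, r) {
  validate_kernel(kernel)
  stopifnot(all(r >= 0))
  b <- c(0, kernel$R0, kernel$R1, kernel$R2, 1)
  v <- c(kernel$F0, kernel$Fr, 0, kernel$Fa)
  Ub <- c(0, cumsum(v * diff(b)))   # potential at the breakpoints
  seg <- pmin(findInterval(r, b), 5L)  # 1..5, breakpoints belong to the right band
  Ub[seg] + c(v, 0)[seg] * (r - b[seg])
}

#' @export
print.ara_kernel <- function(x, ...) {
  cat("ARA interaction kernel (sensing radius 1)\n")
  cat(sprintf("  adhesion  : F0 = %g on [0, %g)\n", x$F0, x$R0))
  if (x$R1 > x$R0)
    cat(sprintf("  repulsion : Fr = %g on [%g, %g)\n", x$Fr, x$R0, x$R1))
  if (x$R2 > x$R1)
    cat(sprintf("  terrace   : 0 on [%g, %g)\n", x$R1, x$R2))
  if (x$R2 < 1)
    cat(sprintf("  attraction: Fa = %g on [%g, 1)\n", x$Fa, x$R2))
  invisible(x)
}

## ---- three-species interaction matrix -------------------------------------

# Default parameter block for the R7/R8/Mi1 system.  Adhesion strengths are
# ordered F0_11 > F0_12 > F0_22 > F0_23 > F0_33 (stronger adhesion sits deeper
# inside the column); R8 wraps around R7, hence the larger R0_12.  Fa_11 and
# R2_11 default to the fixed values used when sweeping the adhesion/repulsion
# parameters (the control-state attraction).
default_interaction_config <- function() {
  list(F0_11 = 2000, Fr_11 = -2000, Fa_11 = 300,
       R0_11 = 0.14, R1_11 = 0.55, R2_11 = 0.64,
       F0_12 = 50, F0_13 = 20, F0_22 = 25, F0_23 = 15, F0_33 = 10,
       R0_12 = 0.3, R0_13 = 0.14, R0_22 = 0.14, R0_23 = 0.14, R0_33 = 0.14)
}

#' Three-species interaction matrix
#'
#' Builds the symmetric 3x3 table of interaction kernels for the species
#' R7 (1), R8 (2) and Mi1 (3).  The R7-R7 entry is a full ARA kernel; every
#' other pair interacts through pure adhesion (`Fr = Fa = 0`,
#' `R1 = R2 = R0`).  Unspecified entries take the default parameter block
#' (see Details).  Cross-species parameters may be given under either index
#' order (`F0_12` or `F0_21`); giving both with different values is rejected,
#' since forces between two populations must obey the action-reaction law.
#'
#' @param ... named parameter overrides such as `Fa_11 = 850`, `R2_11 = 0.85`,
#'   `F0_12 = 60`.  Valid names are `F0_ij`, `R0_ij` for all pairs and
#'   `Fr_11`, `Fa_11`, `R1_11`, `R2_11` for the R7-R7 entry.
#' @param config optionally, a named list of overrides (merged with `...`).
#' @return an object of class `ara_kernel_matrix`: a 3x3 list of
#'   [ara_kernel()] objects with the resolved parameter block attached.
#' @examples
#' m <- interaction_matrix()                      # default block
#' m_tet <- interaction_matrix(Fa_11 = 850, R2_11 = 0.85)
#' @export
interaction_matrix <- function(..., config = list()) {
  user <- c(config, list(...))
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop("all interaction parameters must be named, e.g. Fa_11 = 850")

  # canonicalise ij -> ji duplicates, enforcing action-reaction symmetry
  canon <- list()
  for (nm in names(user)) {
    m <- regmatches(nm, regexec("^(F0|Fr|Fa|R0|R1|R2)_([123])([123])$", nm))[[1]]
    if (length(m) == 0)
      stop("unknown interaction parameter '", nm, "'")
    i <- as.integer(m[3]); j <- as.integer(m[4])
    if (m[2] %in% c("Fr", "Fa", "R1", "R2") && !(i == 1 && j == 1))
      stop("parameter '", nm, "' is only defined for the R7-R7 pair (11): ",
           "all other pairs are pure adhesion")
    cn <- paste0(m[2], "_", min(i, j), max(i, j))
    if (!is.null(canon[[cn]]) && canon[[cn]] != user[[nm]])
      stop("asymmetric interaction parameters for pair ", min(i, j), max(i, j),
           " violate the action-reaction law (", m[2], "_", i, j, " must equal ",
           m[2], "_", j, i, ")")
    canon[[cn]] <- as.numeric(user[[nm]])
  }
  cfg <- modifyList(default_interaction_config(), canon)

  kern <- vector("list", 9)
  dim(kern) <- c(3, 3)
  for (i in 1:3) for (j in 1:3) {
    a <- min(i, j); b <- max(i, j)
    if (a == 1 && b == 1) {
      kern[[i, j]] <- ara_kernel(F0 = cfg$F0_11, Fr = cfg$Fr_11, Fa = cfg$Fa_11,
                                 R0 = cfg$R0_11, R1 = cfg$R1_11, R2 = cfg$R2_11)
    } else {
      F0 <- cfg[[paste0("F0_", a, b)]]
      R0 <- cfg[[paste0("R0_", a, b)]]
      kern[[i, j]] <- ara_kernel(F0 = F0, R0 = R0)
    }
  }
  structure(kern, class = "ara_kernel_matrix", config = cfg)
}

#' @export
print.ara_kernel_matrix <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("3x3 interaction matrix (species 1 = R7, 2 = R8, 3 = Mi1)\n")
  cat(sprintf("  (1,1) ARA: F0 = %g, Fr = %g, Fa = %g, R0 = %g, R1 = %g, R2 = %g\n",
              cfg$F0_11, cfg$Fr_11, cfg$Fa_11, cfg$R0_11, cfg$R1_11, cfg$R2_11))
  for (p in c("12", "13", "22", "23", "33"))
    cat(sprintf("  (%s,%s) adhesion: F0 = %g, R0 = %g\n",
                substr(p, 1, 1), substr(p, 2, 2),
                cfg[[paste0("F0_", p)]], cfg[[paste0("R0_", p)]]))
  invisible(x)
}

#' Read and write interaction-kernel configurations
#'
#' Configurations are stored as JSON with one `kernel.ij` section per species
#' pair, each holding the six parameters `F0, Fr, Fa, R0, R1, R2`.  Values
#' are written at full double precision so a matrix round-trips bit-exactly.
#'
#' @param path file path.
#' @param matrix an `ara_kernel_matrix`.
#' @return `read_kernel_config()` returns an `ara_kernel_matrix`.
#' @export
write_kernel_config <- function(matrix, path) {
  stopifnot(inherits(matrix, "ara_kernel_matrix"))
  sec <- list()
  for (i in 1:3) for (j in i:3) {
    k <- matrix[[i, j]]
    sec[[paste0(i, j)]] <- unclass(k)
  }
  jsonlite::write_json(list(kernel = sec), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_kernel_config
#' @export
read_kernel_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$kernel)) stop("no [kernel] sections in config file ", path)
  over <- list()
  for (p in names(cfg$kernel)) {
    k <- cfg$kernel[[p]]
    over[[paste0("F0_", p)]] <- k$F0
    over[[paste0("R0_", p)]] <- k$R0
    if (p == "11") {
      over$Fr_11 <- k$Fr; over$Fa_11 <- k$Fa
      over$R1_11 <- k$R1; over$R2_11 <- k$R2
    }
  }
  interaction_matrix(config = over)
}
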