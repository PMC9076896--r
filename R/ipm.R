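# Discretized integral projection models: mesh construction, kernel assembly,
# population growth rates.

#' Construct an integration mesh over the size range
#'
#' Builds the midpoint mesh on which IPM kernels are discretized. The state
#' variable is plant size on the log-biomass scale. Bounds are taken from the
#' observed (or supplied) size range, extended on each side by a fraction of
#' the range so that the growth and offspring distributions are not truncated
#' at the observed extremes.
#'
#' @param sizes Numeric vector of observed sizes, or a length-2 numeric
#'   `c(lower, upper)` giving the range directly.
#' @param n_bins Number of mesh cells (default 100).
#' @param extension Fraction of the size range added below the minimum and
#'   above the maximum (default 0.1).
#' @return An object of class `ipm_mesh`: list with `lower`, `upper`,
#'   `mids` (bin midpoints) and `h` (bin width).
#' @examples
#' m <- make_mesh(c(0, 1), n_bins = 100)
#' m$lower; m$upper  # -0.1, 1.1
#' @export
make_mesh <- function(sizes, n_bins = 100L, extension = 0.1) {
  sizes <- sizes[is.finite(sizes)]
  if (length(sizes) < 1L) stop("no finite sizes supplied")
  lo <- min(sizes); hi <- max(sizes)
  if (hi <= lo) stop("size range is degenerate (constant sizes)")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  pad <- extension * (hi - lo)
  lower <- lo - pad
  upper <- hi + pad
  h <- (upper - lower) / n_bins
  mids <- lower + h * (seq_len(n_bins) - 0.5)
  structure(list(lower = lower, upper = upper, mids = mids, h = h,
                 n_bins = as.integer(n_bins)),
            class = "ipm_mesh")
}

#' Assemble a discretized IPM kernel from a set of vital-rate functions
#'
#' Builds the survival-growth kernel P and the fecundity kernel F on a mesh
#' by the midpoint rule, and returns K = P + F. Column b of P is
#' `s(z_b) * dnorm(z_a; mu_G(z_b), sd_G) * h`; column b of F is
#' `p_fl(z_b) * f(z_b) * g * e * dnorm(z_a; mu_R, sd_R) * h`. Both the growth
#' and offspring-size densities are renormalized per column to integrate to 1
#' on the mesh, so probability mass falling outside the size range (eviction)
#' is returned to the column rather than lost.
#'
#' @param vr A vital-rate set: a list with functions `surv(z)`, `grow_mean(z)`,
#'   `flower(z)`, `fec(z)` (expected seeds, >= 0) and scalars `grow_sd`,
#'   `germ`, `estab`, `rec_mean`, `rec_sd`. See [vital_rate_set()].
#' @param mesh An `ipm_mesh` from [make_mesh()].
#' @return An object of class `ipm_kernel`: list with `P`, `F`, `K`, `mesh`
#'   and `n_clipped_fec` (count of mesh points where a negative fecundity
#'   prediction was clipped to zero).
#' @export
build_kernel <- function(vr, mesh) {
  stopifnot(inherits(mesh, "ipm_mesh"))
  z <- mesh$mids
  parts <- .kernel_matrices(
    s = pmin(pmax(vr$surv(z), 0), 1),
    mu = vr$grow_mean(z), grow_sd = vr$grow_sd,
    pfl = pmin(pmax(vr$flower(z), 0), 1), fec = vr$fec(z),
    germ = vr$germ, estab = vr$estab,
    rec_mean = vr$rec_mean, rec_sd = vr$rec_sd, mesh = mesh)
  structure(c(parts, list(mesh = mesh)), class = "ipm_kernel")
}

# kernel assembly core shared by build_kernel and the bootstrap fast path:
# takes the vital rates already evaluated on the mesh midpoints
.kernel_matrices <- function(s, mu, grow_sd, pfl, fec, germ, estab,
                             rec_mean, rec_sd, mesh) {
  z <- mesh$mids
  h <- mesh$h
  n <- mesh$n_bins
  if (!is.finite(grow_sd) || grow_sd <= 0) stop("growth sd must be positive")
  if (!is.finite(rec_sd) || rec_sd <= 0) stop("offspring size sd must be positive")

  # growth density, column-normalized (eviction correction)
  G <- outer(z, mu, function(za, m) stats::dnorm(za, mean = m, sd = grow_sd)) * h
  cs <- .colSums(G, n, n)
  cs[cs < .Machine$double.eps] <- 1  # fully evicted column: leave at zero mass
  P <- G * rep(s / cs, each = n)

  n_clipped <- sum(fec < 0)
  fec <- pmax(fec, 0)
  phi <- stats::dnorm(z, mean = rec_mean, sd = rec_sd) * h
  sphi <- sum(phi)
  if (sphi > .Machine$double.eps) phi <- phi / sphi
  Fm <- outer(phi, pfl * fec * germ * estab)

  K <- P + Fm
  if (any(!is.finite(K))) stop("kernel contains non-finite entries")
  list(P = P, F = Fm, K = K, n_clipped_fec = n_clipped)
}

# dominant eigenvalue by power iteration (non-negative kernels), with an
# eigen() fallback for non-converging (e.g. imprimitive) matrices
.lambda_fast <- function(K, tol = 1e-13, maxit = 10000L) {
  n <- ncol(K)
  v <- rep.int(1 / n, n)
  lam <- -1
  hits <- 0L
  for (i in seq_len(maxit)) {
    w <- K %*% v
    s <- sum(w)
    if (s <= 0) return(0)
    v <- w / s
    if (abs(s - lam) <= tol * s) {
      hits <- hits + 1L
      if (hits >= 2L) return(s)
    } else hits <- 0L
    lam <- s
  }
  lambda_of(K)$lambda
}

#' Population growth rate of a kernel
#'
#' Computes lambda as the dominant eigenvalue (spectral radius) of the
#' discretized kernel, i.e. the discrete per-capita growth rate in
#' N_{t+1} = lambda N_t, together with the stable size distribution (the
#' associated right eigenvector, normalized to sum to 1).
#'
#' @param kernel An `ipm_kernel`, or a non-negative square matrix.
#' @return List with `lambda`, `ln_lambda` and `stable_dist`.
#' @examples
#' lambda_of(matrix(c(0, 0.5, 2, 0), 2, 2))$lambda  # 1
#' @export
lambda_of <- function(kernel) {
  K <- if (inherits(kernel, "ipm_kernel")) kernel$K else as.matrix(kernel)
  if (any(!is.finite(K))) stop("kernel contains non-finite entries")
  ev <- eigen(K)
  i <- which.max(Mod(ev$values))
  lambda <- Re(ev$values[i])
  if (lambda < 0) lambda <- abs(lambda)  # spectral radius of non-negative K
  w <- Re(ev$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- pmax(w, 0)
  sw <- sum(w)
  if (sw > 0) w <- w / sw
  list(lambda = lambda,
       ln_lambda = if (lambda > 0) log(lambda) else -Inf,
       stable_dist = w)
}

#' Classify a resident monoculture relative to demographic equilibrium
#'
#' The invasion analysis assumes resident monocultures are at equilibrium
#' density, i.e. that the resident-on-resident growth rate is lambda = 1.
#' This check classifies a monoculture kernel by the sign and magnitude of
#' ln(lambda): within `tolerance` of 0 the monoculture is "at" equilibrium;
#' ln(lambda) > tolerance means the monoculture would still grow ("below"
#' equilibrium density); ln(lambda) < -tolerance means it would decline
#' ("above" equilibrium density).
#'
#' @param kernel An `ipm_kernel` for an intraspecific (resident-on-resident)
#'   context, or a precomputed lambda (positive scalar).
#' @param tolerance Half-width of the "at equilibrium" band on the ln(lambda)
#'   scale (default 0.05).
#' @return One of `"above"`, `"at"`, `"below"`.
#' @export
check_equilibrium <- function(kernel, tolerance = 0.05) {
  stopifnot(tolerance >= 0)
  lam <- if (is.numeric(kernel) && length(kernel) == 1L) kernel
         else lambda_of(kernel)$lambda
  if (lam <= 0) return("above")
  ll <- log(lam)
  if (abs(ll) <= tolerance) "at" else if (ll > 0) "below" else "above"
}

#' Bundle vital-rate functions into a set usable by [build_kernel()]
#'
#' @param surv,grow_mean,flower,fec Vectorized functions of size z: survival
#'   probability, expected size at t+1, flowering probability, expected seed
#'   number.
#' @param grow_sd Residual SD of the growth regression (> 0).
#' @param germ,estab Size-independent germination and establishment
#'   probabilities.
#' @param rec_mean,rec_sd Mean and SD of the offspring (recruit) size
#'   distribution.
#' @return List of class `vital_rate_set`.
#' @export
vital_rate_set <- function(surv, grow_mean, grow_sd, flower, fec,
                           germ, estab, rec_mean, rec_sd) {
  stopifnot(is.function(surv), is.function(grow_mean), is.function(flower),
            is.function(fec), grow_sd > 0, rec_sd > 0,
            germ >= 0, germ <= 1, estab >= 0, estab <= 1)
  structure(list(surv = surv, grow_mean = grow_mean, grow_sd = grow_sd,
                 flower = flower, fec = fec, germ = germ, estab = estab,
                 rec_mean = rec_mean, rec_sd = rec_sd),
            class = "vital_rate_set")
}
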