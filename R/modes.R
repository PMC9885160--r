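#' Elastic-network model configuration
#'
#' @param cutoff Contact cutoff, Angstrom (default 12, a conventional
#'   bead-model value).
#' @param gamma Uniform spring constant, kcal/mol/A^2 (default 1).
#' @param tol_zero Absolute eigenvalue tolerance below which a mode counts
#'   as a rigid-body null mode; `NULL` (default) means
#'   `1e-7 * max(|eigenvalue|)` at diagonalization time.
#' @return Object of class `enm_config`.
#' @export
enm_config <- function(cutoff = 12, gamma = 1, tol_zero = NULL) {
  if (cutoff <= 0 || gamma <= 0) stop("cutoff and gamma must be > 0")
  structure(list(cutoff = cutoff, gamma = gamma, tol_zero = tol_zero),
            class = "enm_config")
}

#' Anisotropic-network (ANM) Hessian
#'
#' For each bead pair within the cutoff the off-diagonal 3x3 block is
#' \eqn{-\gamma \hat r \hat r^T}; diagonal blocks are minus the sum of the
#' row's off-diagonal blocks, so every row sums to zero (translation
#' invariance) and the matrix is symmetric positive semidefinite by
#' construction.
#'
#' @param structure An [md_structure()].
#' @param config An [enm_config()].
#' @return 3N x 3N Hessian, kcal/mol/A^2.
#' @export
build_enm_hessian <- function(structure, config = enm_config()) {
  stopifnot(inherits(config, "enm_config"))
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 atoms")
  H <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d < config$cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no pairs within cutoff: Hessian is zero")
    return(H)
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    rij <- xyz[j, ] - xyz[i, ]
    rhat <- rij / sqrt(sum(rij^2))
    blk <- -config$gamma * tcrossprod(rhat)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Numerical Hessian of the toy potential
#'
#' Central finite differences of the analytic gradient, symmetrized as
#' (H + H^T)/2.  Intended for structures at (or very near) a force-field
#' minimum; warns if the gradient norm exceeds `grad_tol`.
#'
#' @param params [force_field_params()].
#' @param xyz N x 3 coordinates at the expansion point.
#' @param delta Finite-difference step, Angstrom (default 1e-4).
#' @param grad_tol Warn if max |gradient| exceeds this, kcal/mol/A.
#' @return List: `hessian` (3N x 3N, symmetrized), `asymmetry` (relative
#'   Frobenius asymmetry before symmetrization).
#' @export
build_numerical_hessian <- function(params, xyz, delta = 1e-4,
                                    grad_tol = 1e-4) {
  if (delta <= 0) stop("domain error: delta must be > 0")
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  g0 <- -potential_energy(params, xyz)$forces
  if (max(abs(g0)) > grad_tol)
    warning(sprintf("structure is not at a minimum (max |grad| = %.3g); Hessian may mix in gradient terms",
                    max(abs(g0))))
  H <- matrix(0, 3 * n, 3 * n)
  for (c in seq_len(3 * n)) {
    atom <- (c - 1L) %/% 3L + 1L
    comp <- (c - 1L) %% 3L + 1L
    xp <- xyz; xp[atom, comp] <- xp[atom, comp] + delta
    xm <- xyz; xm[atom, comp] <- xm[atom, comp] - delta
    gp <- -t(potential_energy(params, xp)$forces)   # 3 x N, column-major = x1y1z1...
    gm <- -t(potential_energy(params, xm)$forces)
    H[, c] <- as.vector((gp - gm)) / (2 * delta)
  }
  asym <- norm(H - t(H), "F") / max(norm(H, "F"), .Machine$double.eps)
  list(hessian = (H + t(H)) / 2, asymmetry = asym)
}

#' Diagonalize a mass-weighted Hessian
#'
#' Computes the eigendecomposition of \eqn{M^{-1/2} H M^{-1/2}}.
#' Eigenvalues are returned ascending in kcal/mol/A^2/amu; eigenvectors are
#' orthonormal columns in mass-weighted coordinates.  Eigenvalues with
#' magnitude below the zero tolerance are clamped to 0 and counted as
#' rigid-body null modes (`n_zero`; 6 for a free non-collinear 3D system).
#'
#' @param hessian Symmetric 3N x 3N matrix, kcal/mol/A^2.
#' @param masses Per-atom masses, amu (length N).
#' @param tol_zero Absolute zero-mode tolerance; default
#'   `1e-7 * max(|eigenvalue|)`.
#' @param sym_tol Symmetry validation tolerance (relative), default 1e-6.
#' @return Object of class `mode_set`: `values`, `vectors`, `masses`,
#'   `n_zero`, `tol_zero`.
#' @export
diagonalize_hessian <- function(hessian, masses, tol_zero = NULL,
                                sym_tol = 1e-6) {
  n3 <- nrow(hessian)
  stopifnot(n3 == 3 * length(masses), all(masses > 0))
  scale <- max(abs(hessian), .Machine$double.eps)
  if (max(abs(hessian - t(hessian))) > sym_tol * scale)
    stop("validation error: Hessian is not symmetric within tolerance")
  minv <- 1 / sqrt(rep(masses, each = 3))
  Hmw <- hessian * tcrossprod(minv)      # M^-1/2 H M^-1/2
  Hmw <- (Hmw + t(Hmw)) / 2
  e <- eigen(Hmw, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  tz <- tol_zero %||% (1e-7 * max(abs(vals), .Machine$double.eps))
  nz <- sum(vals <= tz)
  vals[abs(vals) <= tz] <- 0
  structure(list(values = vals, vectors = vecs, masses = masses,
                 n_zero = nz, tol_zero = tz),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes (%d zero), lowest nonzero eigenvalue %.4g kcal/mol/A^2/amu\n",
              length(x$values), x$n_zero,
              if (x$n_zero < length(x$values)) x$values[x$n_zero + 1] else NA))
  invisible(x)
}

#' Per-mode, per-atom thermal RMSF contributions
#'
#' For nonzero mode k, atom i contributes positional variance
#' \eqn{(k_B T / \lambda_k)\, |a_{k,i}|^2 / m_i} (the three Cartesian
#' components of the mass-weighted eigenvector summed); the RMSF is its
#' square root.  Rigid-body null modes contribute exactly zero.
#'
#' @param modes A [diagonalize_hessian()] mode set.
#' @param temperature K (> 0).
#' @return N x n_modes matrix of RMSF contributions, Angstrom (zero
#'   columns for the null modes).
#' @export
mode_rmsf_contributions <- function(modes, temperature = 300) {
  if (temperature <= 0) stop("domain error: temperature must be > 0")
  n <- length(modes$masses)
  nm <- length(modes$values)
  out <- matrix(0, n, nm)
  kT <- KB_KCALMOL * temperature
  for (k in seq_len(nm)) {
    if (k <= modes$n_zero || modes$values[k] <= 0) next
    a2 <- rowSums(matrix(modes$vectors[, k]^2, ncol = 3, byrow = TRUE))
    out[, k] <- sqrt(kT / modes$values[k] * a2 / modes$masses)
  }
  out
}

#' Select low-frequency modes by regional RMSF contribution
#'
#' Among the `pool` lowest-frequency nonzero modes, returns the `k` modes
#' whose RMSF contribution summed over the region is largest, sorted by
#' frequency (ties broken by lower mode index).
#'
#' @param modes A mode set.
#' @param region Atom indices of the region of interest (e.g. the tail).
#' @param k Number of modes to select.
#' @param pool Size of the low-frequency candidate pool (default 20).
#' @param temperature K, used for the RMSF weighting (cancels in the
#'   ranking but kept for interpretability).
#' @return Integer mode indices (into the full mode set), ascending.
#' @export
select_modes <- function(modes, region, k, pool = 20, temperature = 300) {
  region <- as.integer(region)
  if (length(region) == 0) stop("domain error: empty region")
  n_nonzero <- length(modes$values) - modes$n_zero
  if (k > n_nonzero) stop("k exceeds the number of nonzero modes")
  pool_idx <- modes$n_zero + seq_len(min(pool, n_nonzero))
  contrib <- mode_rmsf_contributions(modes, temperature)
  score <- colSums(contrib[region, pool_idx, drop = FALSE])
  ord <- order(-score, pool_idx)         # deterministic tie-break: lower index
  sort(pool_idx[ord[seq_len(k)]])
}

#' Write / read a mode set as plain CSV files
#'
#' `path` is used as a stem: `<path>_values.csv` holds eigenvalues, masses
#' and n_zero; `<path>_vectors.csv` the eigenvector matrix.
#'
#' @param modes A mode set.
#' @param path File stem.
#' @export
write_modes <- function(modes, path) {
  utils::write.csv(data.frame(eigenvalue = modes$values,
                              n_zero = modes$n_zero,
                              tol_zero = modes$tol_zero),
                   paste0(path, "_values.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mass = modes$masses),
                   paste0(path, "_masses.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(modes$vectors),
                   paste0(path, "_vectors.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  v <- utils::read.csv(paste0(path, "_values.csv"))
  m <- utils::read.csv(paste0(path, "_masses.csv"))
  vec <- as.matrix(utils::read.csv(paste0(path, "_vectors.csv")))
  dimnames(vec) <- NULL
  structure(list(values = v$eigenvalue, vectors = vec, masses = m$mass,
                 n_zero = v$n_zero[1], tol_zero = v$tol_zero[1]),
            class = "mode_set")
}
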