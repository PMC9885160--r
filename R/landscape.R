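#' Per-atom RMSF over a trajectory
#'
#' Each frame is rigidly superposed onto the reference over the selection,
#' then RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).  With `reference =
#' "mean"` the frames are first fitted to frame 1, the fitted mean is
#' taken as reference, and the frames are refitted to it (one pass).
#'
#' @param trajectory An [md_trajectory()] (>= 2 frames).
#' @param selection Atom indices used both for the fit and for the
#'   reported RMSF; default all atoms.
#' @param reference `"mean"` (default) or `"frame0"`.
#' @return Named numeric vector of RMSF values (Angstrom), one per
#'   selected atom.
#' @export
rmsf <- function(trajectory, selection = NULL,
                 reference = c("mean", "frame0")) {
  reference <- match.arg(reference)
  nf <- n_frames(trajectory)
  if (nf < 2) stop("insufficient data: need >= 2 frames for RMSF")
  na <- dim(trajectory$coords)[2]
  sel <- selection %||% seq_len(na)

  fit_to <- function(ref) {
    out <- array(NA_real_, dim = c(nf, length(sel), 3))
    for (f in seq_len(nf)) {
      fr <- get_frame(trajectory, f)
      tr <- superpose(fr, ref, selection = sel)$transform
      out[f, , ] <- apply_transform(fr, tr)[sel, , drop = FALSE]
    }
    out
  }
  ref <- get_frame(trajectory, 1)
  fitted <- fit_to(ref)
  if (reference == "mean") {
    mean1 <- apply(fitted, c(2, 3), mean)
    ref2 <- ref
    ref2[sel, ] <- mean1
    fitted <- fit_to(ref2)
  }
  mu <- apply(fitted, c(2, 3), mean)
  dev2 <- sweep(fitted, c(2, 3), mu)^2
  out <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & coords, x3 -> per-atom
  names(out) <- sel
  out
}

#' Best-fit RMSD time series with plateau detection
#'
#' Per-frame Kabsch RMSD to a reference over a selection.  The plateau
#' detector fits a line to each trailing window of `window` frames and
#' reports the first frame at which the absolute fitted slope drops below
#' `slope_tol` (Angstrom per frame); `NA` if never.
#'
#' @param trajectory An [md_trajectory()].
#' @param reference [md_structure()] or N x 3 matrix.
#' @param selection Atom indices; default all.
#' @param window Trailing window length, frames (default 20).
#' @param slope_tol Plateau slope threshold, Angstrom/frame (default 0.01).
#' @return List: `rmsd` (numeric per frame), `plateau_frame`.
#' @export
rmsd_series <- function(trajectory, reference, selection = NULL,
                        window = 20L, slope_tol = 0.01) {
  ref <- if (inherits(reference, "md_structure")) coords(reference) else as.matrix(reference)
  nf <- n_frames(trajectory)
  sel <- selection %||% seq_len(nrow(ref))
  r <- vapply(seq_len(nf), function(f)
    superpose(get_frame(trajectory, f), ref, selection = sel)$rmsd,
    numeric(1))
  plateau <- NA_integer_
  if (nf >= window) {
    tidx <- seq_len(window)
    for (f in seq(window, nf)) {
      y <- r[(f - window + 1L):f]
      slope <- stats::cov(tidx, y) / stats::var(tidx)
      if (abs(slope) < slope_tol) { plateau <- f; break }
    }
  }
  list(rmsd = r, plateau_frame = plateau)
}

## Mass-weighted inertia tensor about the COM of a point set.
inertia_tensor <- function(xyz, masses) {
  com <- colSums(xyz * masses) / sum(masses)
  rc <- sweep(xyz, 2, com)
  r2 <- rowSums(rc^2)
  I <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2))) -
    crossprod(rc * sqrt(masses))        # sum m r r^T
  ## crossprod(rc*sqrt(m)) = sum m r r^T
  I
}

#' Anchor/inertia analysis frame
#'
#' Builds the coordinate frame used to track the tail: origin at the
#' anchor residue's bead, z-axis along the eigenvector of the domain's
#' inertia tensor with the LARGEST principal moment, sign chosen to point
#' from the domain's COM toward the anchor ("away from the domain");
#' x-axis is the middle principal axis (sign fixed intrinsically by the
#' first domain atom), y completes the right-handed frame.
#'
#' @param structure An [md_structure()] (or N x 3 matrix plus `masses`).
#' @param anchor_residue Residue number whose (first) bead is the origin.
#' @param domain_selection Atom indices of the globular domain (>= 3
#'   non-collinear atoms).
#' @param masses Needed only when `structure` is a bare matrix.
#' @param degeneracy_tol Relative tolerance below which the two largest
#'   moments count as degenerate (error; default 1e-6).
#' @return Object of class `frame_transform`: `origin` (length 3),
#'   `rotation` (3 x 3, rows = x, y, z axes).  Transformed coordinates are
#'   `rotation %*% (r - origin)`.
#' @export
build_anchor_frame <- function(structure, anchor_residue, domain_selection,
                               masses = NULL, degeneracy_tol = 1e-6) {
  if (inherits(structure, "md_structure")) {
    xyz <- coords(structure)
    masses <- structure$atoms$mass
    anchor_idx <- which(structure$atoms$resid == anchor_residue)[1]
  } else {
    xyz <- as.matrix(structure)
    stopifnot(!is.null(masses))
    anchor_idx <- as.integer(anchor_residue)
  }
  if (is.na(anchor_idx)) stop("anchor residue not found")
  dom <- as.integer(domain_selection)
  stopifnot(length(dom) >= 3)
  I <- inertia_tensor(xyz[dom, , drop = FALSE], masses[dom])
  e <- eigen(I, symmetric = TRUE)        # values descending
  if ((e$values[1] - e$values[2]) < degeneracy_tol * e$values[1])
    stop("ambiguity error: two largest principal moments are degenerate; choose the axis explicitly")
  zhat <- e$vectors[, 1]
  com <- colSums(xyz[dom, , drop = FALSE] * masses[dom]) / sum(masses[dom])
  away <- xyz[anchor_idx, ] - com
  if (sum(zhat * away) < 0) zhat <- -zhat
  xhat <- e$vectors[, 2]
  xhat <- xhat - sum(xhat * zhat) * zhat
  xhat <- xhat / sqrt(sum(xhat^2))
  ## intrinsic sign convention for x: first domain atom on the +x side
  for (cand in dom) {
    dtest <- sum(xhat * (xyz[cand, ] - com))
    if (abs(dtest) > 1e-10) { if (dtest < 0) xhat <- -xhat; break }
  }
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  out <- list(origin = xyz[anchor_idx, ], rotation = rbind(xhat, yhat, zhat))
  class(out) <- "frame_transform"
  out
}

#' Apply a frame transform to coordinates
#' @param frame A `frame_transform`.
#' @param xyz N x 3 matrix.
#' @return N x 3 matrix in the new frame.
#' @export
transform_coords <- function(frame, xyz) {
  sweep(as.matrix(xyz), 2, frame$origin) %*% t(frame$rotation)
}

#' Track the helix center of mass in the anchor/inertia frame
#'
#' For every frame the analysis frame is rebuilt from that frame's
#' coordinates (so the track is a pure function of each frame), and the
#' mass-weighted COM of the helix selection is expressed in it: z > 0
#' means the helix has moved away from the domain, x-y give the side of
#' the domain it is on.  Flips of the z-axis relative to the previous
#' frame are counted in attribute `n_sign_flips`.
#'
#' @param trajectory An [md_trajectory()].
#' @param structure Template [md_structure()] (masses, residue numbers).
#' @param anchor_residue Residue number anchoring the origin.
#' @param domain_selection,helix_selection Atom index vectors.
#' @return data.frame (class `com_track`) with columns frame, x, y, z.
#' @export
com_track <- function(trajectory, structure, anchor_residue,
                      domain_selection, helix_selection) {
  m <- structure$atoms$mass
  anchor_idx <- which(structure$atoms$resid == anchor_residue)[1]
  if (is.na(anchor_idx)) stop("anchor residue not found")
  hel <- as.integer(helix_selection)
  nf <- n_frames(trajectory)
  out <- matrix(NA_real_, nf, 3)
  prev_z <- NULL
  flips <- 0L
  for (f in seq_len(nf)) {
    xyz <- get_frame(trajectory, f)
    fr <- tryCatch(
      build_anchor_frame(xyz, anchor_idx, domain_selection, masses = m),
      error = function(e) stop(sprintf("frame %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    if (!is.null(prev_z) && sum(fr$rotation[3, ] * prev_z) < 0)
      flips <- flips + 1L
    prev_z <- fr$rotation[3, ]
    com <- colSums(xyz[hel, , drop = FALSE] * m[hel]) / sum(m[hel])
    out[f, ] <- fr$rotation %*% (com - fr$origin)
  }
  df <- data.frame(frame = seq_len(nf), x = out[, 1], y = out[, 2], z = out[, 3])
  class(df) <- c("com_track", "data.frame")
  attr(df, "n_sign_flips") <- flips
  df
}

#' Residue-pair nonbonded interaction-energy map
#'
#' For each sampled frame and each residue pair (a in A, b in B), sums the
#' switched electrostatic and Lennard-Jones energies over the atom pairs,
#' then reports the trajectory mean per residue pair plus the component
#' matrices.  Uses the simulation's own nonbonded parameters and
#' truncation.
#'
#' @param trajectory An [md_trajectory()] or a single [md_structure()].
#' @param structure Template [md_structure()] (residue numbers).
#' @param set_A,set_B Disjoint atom index vectors.
#' @param params [force_field_params()].
#' @param stride Sample every `stride`-th frame.
#' @return Object of class `interaction_map`: matrices `total`, `elec`,
#'   `vdw` (rows = residues of A, cols = residues of B, kcal/mol),
#'   `n_frames_used`.
#' @export
interaction_map <- function(trajectory, structure, set_A, set_B, params,
                            stride = 1L) {
  if (inherits(trajectory, "md_structure"))
    trajectory <- md_trajectory(list(coords(trajectory)), dt = 0)
  A <- as.integer(set_A); B <- as.integer(set_B)
  if (length(intersect(A, B)))
    stop("validation error: set_A and set_B must be disjoint")
  resA <- sort(unique(structure$atoms$resid[A]))
  resB <- sort(unique(structure$atoms$resid[B]))
  ridxA <- match(structure$atoms$resid[A], resA)
  ridxB <- match(structure$atoms$resid[B], resB)
  pairs <- expand.grid(ia = seq_along(A), ib = seq_along(B))
  i <- A[pairs$ia]; j <- B[pairs$ib]
  ## column-major cell index into the (resA x resB) matrices
  cell <- (ridxB[pairs$ib] - 1L) * length(resA) + ridxA[pairs$ia]

  elec <- matrix(0, length(resA), length(resB),
                 dimnames = list(resA, resB))
  vdw <- elec
  frames <- seq(1L, n_frames(trajectory), by = stride)
  qq0 <- params$coulomb_constant * params$charge[i] * params$charge[j] /
    params$dielectric
  epsij <- sqrt(params$eps[i] * params$eps[j])
  rmin <- params$rmin_half[i] + params$rmin_half[j]
  for (f in frames) {
    xyz <- get_frame(trajectory, f)
    rv <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
    r <- sqrt(rowSums(rv^2))
    sw <- switch_fn(r, params$switch_on, params$switch_off)
    sr6 <- (rmin / r)^6
    e_lj <- epsij * (sr6^2 - 2 * sr6) * sw$S
    e_el <- (qq0 / r) * sw$S
    se <- rowsum(e_el, cell); sv <- rowsum(e_lj, cell)
    idx <- as.integer(rownames(se))
    elec[idx] <- elec[idx] + se
    vdw[idx] <- vdw[idx] + sv
  }
  nfu <- length(frames)
  elec <- elec / nfu; vdw <- vdw / nfu
  out <- list(total = elec + vdw, elec = elec, vdw = vdw,
              residues_A = resA, residues_B = resB, n_frames_used = nfu)
  class(out) <- "interaction_map"
  out
}

#' Ranked strongest residue-pair contacts
#' @param map An `interaction_map`.
#' @param n Number of pairs to report.
#' @return data.frame: resid_A, resid_B, total, elec, vdw; ascending total.
#' @export
top_contacts <- function(map, n = 10) {
  ord <- order(map$total)[seq_len(min(n, length(map$total)))]
  ij <- arrayInd(ord, dim(map$total))
  data.frame(resid_A = map$residues_A[ij[, 1]],
             resid_B = map$residues_B[ij[, 2]],
             total = map$total[ord], elec = map$elec[ord],
             vdw = map$vdw[ord])
}

#' Coverage statistics of a COM track
#'
#' Convex-hull area of the (x, y) point set (0 for fewer than 3 distinct
#' points or collinear sets), the radius of gyration of the points, and
#' bounding extents.
#'
#' @param track A `com_track` (or any data.frame with x, y columns).
#' @return List: `hull_area` (A^2), `rgyr` (A), `extent_x`, `extent_y`.
#' @export
coverage_stats <- function(track) {
  x <- track$x; y <- track$y
  stopifnot(length(x) >= 1)
  pts <- unique(cbind(x, y))
  area <- 0
  if (nrow(pts) >= 3) {
    h <- grDevices::chull(pts)
    hx <- pts[h, 1]; hy <- pts[h, 2]
    k <- length(h)
    area <- abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
  }
  rg <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
  list(hull_area = area, rgyr = rg,
       extent_x = range(x), extent_y = range(y))
}

#' Write analysis products as CSV
#' @param x A `com_track` or `interaction_map`.
#' @param path Output path (for maps, a stem producing
#'   `<path>_total.csv` etc.).
#' @export
write_csv_output <- function(x, path) {
  if (inherits(x, "com_track")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "interaction_map")) {
    utils::write.csv(x$total, paste0(path, "_total.csv"))
    utils::write.csv(x$elec, paste0(path, "_elec.csv"))
    utils::write.csv(x$vdw, paste0(path, "_vdw.csv"))
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Scatter plot of a COM track (x-y plane, shaded by z)
#' @param track A `com_track`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_com_track <- function(track, ...) {
  z <- track$z
  shade <- grDevices::gray(1 - (z - min(z)) / max(diff(range(z)), 1e-12) * 0.8 - 0.1)
  graphics::plot(track$x, track$y, col = shade, pch = 16,
                 xlab = "x (A)", ylab = "y (A)", ...)
  invisible(track)
}

#' Heat map of an interaction-energy map
#' @param map An `interaction_map`.
#' @param component `"total"`, `"elec"` or `"vdw"`.
#' @export
plot_interaction_map <- function(map, component = "total") {
  m <- map[[component]]
  graphics::image(x = seq_along(map$residues_A), y = seq_along(map$residues_B),
                  z = m, xlab = "residue (A set)", ylab = "residue (B set)",
                  axes = FALSE)
  graphics::axis(1, at = seq_along(map$residues_A), labels = map$residues_A)
  graphics::axis(2, at = seq_along(map$residues_B), labels = map$residues_B)
  invisible(map)
}
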