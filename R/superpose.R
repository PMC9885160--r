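#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 proper orthogonal matrix (det = +1).
#' @param translation Length-3 numeric, Angstrom.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthogonal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

## Kabsch fit of P (mobile) onto Q (reference); both n x 3.
## Returns x -> R x + t minimizing |R P + t - Q|.
kabsch <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))          # P^T Q = U D V^T
  if (sv$d[2] < 1e-12)
    stop("degenerate fit: fewer than 3 non-collinear atoms")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Apply a rigid transform
#' @param x An `md_structure` or an N x 3 coordinate matrix.
#' @param transform A [rigid_transform()].
#' @return Same type as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  tf <- function(m) sweep(m %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (inherits(x, "md_structure")) {
    coords(x) <- tf(coords(x))
    x
  } else tf(as.matrix(x))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation that minimizes the RMSD of the
#' mobile structure onto the reference over a selection.  The reflection
#' branch of the SVD is resolved by sign-flipping the smallest singular
#' vector, so the returned rotation always has det = +1.
#'
#' @param mobile,reference [md_structure()]s (or N x 3 matrices).
#' @param selection Atom indices used for the fit; default all atoms.  The
#'   same indices are applied to both inputs and must address equal-length
#'   atom lists.
#' @return List with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, over the selection after the fit).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  P <- if (inherits(mobile, "md_structure")) coords(mobile) else as.matrix(mobile)
  Q <- if (inherits(reference, "md_structure")) coords(reference) else as.matrix(reference)
  sel <- selection %||% seq_len(nrow(P))
  if (max(sel) > nrow(P) || max(sel) > nrow(Q))
    stop("shape error: selection out of range in one input")
  Ps <- P[sel, , drop = FALSE]; Qs <- Q[sel, , drop = FALSE]
  if (nrow(Ps) != nrow(Qs))
    stop("shape error: selection maps to unequal atom lists")
  if (nrow(Ps) < 3) stop("degenerate fit: need >= 3 atoms")
  fit <- kabsch(Ps, Qs)
  tr <- rigid_transform(fit$R, fit$t)
  rmsd <- rmsd_coords(apply_transform(Ps, tr), Qs)
  list(transform = tr, rmsd = rmsd)
}

#' Graft a donor segment onto a base structure
#'
#' The donor is rigidly superposed onto the base over an overlap residue
#' window, then the requested donor residues are copied (transformed) into
#' the result.  This is how a missing terminal segment is completed from a
#' second crystal structure.
#'
#' @param base,donor [md_structure()]s.
#' @param overlap_resids Inclusive residue range (length-2) present in both.
#' @param graft_resids Inclusive residue range present in the donor and
#'   absent from the base; may be `NULL`/empty for a no-op.
#' @return An [md_structure()] whose residue numbering is the sorted union;
#'   attributes `overlap_rmsd` (the superposition RMSD) and `junction`
#'   (distance in Angstrom between the last base residue bead and the first
#'   grafted residue bead) report the graft geometry.
#' @export
graft_segment <- function(base, donor, overlap_resids, graft_resids = NULL) {
  ov <- range_to_vec(overlap_resids)
  sel_b <- which(base$atoms$resid %in% ov)
  sel_d <- which(donor$atoms$resid %in% ov)
  if (length(sel_b) == 0 || length(sel_d) == 0)
    stop("range error: overlap residues absent from base or donor")
  if (length(sel_b) != length(sel_d))
    stop("range error: overlap selects unequal atom counts")
  fit <- kabsch(coords(donor)[sel_d, , drop = FALSE],
                coords(base)[sel_b, , drop = FALSE])
  tr <- rigid_transform(fit$R, fit$t)
  rmsd <- rmsd_coords(apply_transform(coords(donor)[sel_d, , drop = FALSE], tr),
                      coords(base)[sel_b, , drop = FALSE])

  gr <- if (is.null(graft_resids)) integer(0) else range_to_vec(graft_resids)
  if (length(gr)) {
    if (any(gr %in% base$atoms$resid))
      stop("conflict error: graft residues already present in base")
    if (!all(gr %in% donor$atoms$resid))
      stop("range error: graft residues absent from donor")
  }
  out <- base$atoms
  if (length(gr)) {
    keep <- donor$atoms$resid %in% gr
    add <- donor$atoms[keep, , drop = FALSE]
    newxyz <- apply_transform(as.matrix(add[, c("x", "y", "z")]), tr)
    add$x <- newxyz[, 1]; add$y <- newxyz[, 2]; add$z <- newxyz[, 3]
    out <- rbind(out, add)
  }
  out <- out[order(out$resid), , drop = FALSE]
  res <- md_structure(out$name, out$resid, as.matrix(out[, c("x", "y", "z")]),
                      out$resname, out$chain, out$mass, out$charge,
                      out$eps, out$rmin_half)
  junction <- NA_real_
  if (length(gr)) {
    last_base <- which(res$atoms$resid == max(base$atoms$resid[base$atoms$resid < min(gr)]))[1]
    first_graft <- which(res$atoms$resid == min(gr))[1]
    junction <- sqrt(sum((coords(res)[last_base, ] - coords(res)[first_graft, ])^2))
  }
  attr(res, "overlap_rmsd") <- rmsd
  attr(res, "junction") <- junction
  res
}

range_to_vec <- function(r) {
  if (length(r) == 2) seq(r[1], r[2]) else as.integer(r)
}
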