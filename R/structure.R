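#' Bead/atom structure container
#'
#' The common currency of the package: an ordered atom table with
#' coordinates, author residue numbering, per-atom mass, charge and
#' Lennard-Jones parameters.  One bead per residue is the typical use
#' (a single "CA" record per residue), but nothing requires it.
#'
#' @param name Atom names (character).
#' @param resid Residue numbers, 1-based author numbering (integer).
#' @param xyz N x 3 numeric matrix of coordinates, Angstrom.
#' @param resname Residue names; recycled.
#' @param chain Chain identifiers; recycled.
#' @param mass Atomic/bead masses, amu; recycled. Default 110 amu, a
#'   residue-sized bead.
#' @param charge Point charges, elementary units; recycled.
#' @param eps LJ well depths, kcal/mol; recycled.
#' @param rmin_half LJ rmin/2, Angstrom; recycled.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(name, resid, xyz, resname = "BEA", chain = "A",
                         mass = 110, charge = 0, eps = 0.05, rmin_half = 2.25) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3L, length(name) == n, length(resid) == n)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  atoms <- data.frame(
    name = as.character(name),
    resid = as.integer(resid),
    resname = rep_len(as.character(resname), n),
    chain = rep_len(as.character(chain), n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    eps = rep_len(as.numeric(eps), n),
    rmin_half = rep_len(as.numeric(rmin_half), n),
    stringsAsFactors = FALSE
  )
  if (any(atoms$mass <= 0)) stop("masses must be > 0")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) stop("(chain, resid, atom name) triplets must be unique")
  structure(list(atoms = atoms), class = "md_structure")
}

#' Number of atoms in a structure
#' @param x An `md_structure`.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Get or set coordinates of a structure
#' @param x An `md_structure`.
#' @return `coords()` returns the N x 3 coordinate matrix.
#' @export
coords <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @rdname coords
#' @param value N x 3 coordinate matrix.
#' @export
`coords<-` <- function(x, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == n_atoms(x), ncol(value) == 3L, all(is.finite(value)))
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' @export
print.md_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<md_structure> %d atoms, residues %d..%d, chains: %s\n",
              nrow(a), min(a$resid), max(a$resid),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Trajectory container
#'
#' An ordered stack of coordinate frames with a frame time step.
#'
#' @param frames Either a list of N x 3 matrices or an array with
#'   dim = c(n_frames, n_atoms, 3).
#' @param dt Time between stored frames, ps.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, dt = 1) {
  if (is.list(frames)) {
    n <- length(frames)
    stopifnot(n >= 1L)
    na <- nrow(frames[[1]])
    arr <- array(NA_real_, dim = c(n, na, 3))
    for (i in seq_len(n)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  if (!all(is.finite(frames))) stop("trajectory frames must be finite")
  structure(list(coords = frames, dt = dt), class = "md_trajectory")
}

#' @rdname md_trajectory
#' @param x An `md_trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Extract a single frame as an N x 3 matrix
#' @param x An `md_trajectory`.
#' @param i Frame index (1-based).
#' @export
get_frame <- function(x, i) {
  stopifnot(i >= 1, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3)
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<md_trajectory> %d frames x %d atoms, dt = %g ps\n", d[1], d[2], x$dt))
  invisible(x)
}
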