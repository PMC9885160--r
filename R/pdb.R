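#' Read a PDB file
#'
#' Fixed-column parser for ATOM/HETATM records.  First altloc is kept;
#' insertion codes are rejected (out of scope here — fail loudly).  Masses,
#' charges and LJ parameters are not stored in PDB files; they are filled
#' with the package's bead defaults (110 amu, 0 e, 0.05 kcal/mol, 2.25 A)
#' and can be overwritten afterwards.
#'
#' @param path Path to a PDB file.
#' @param model For multi-model files, which MODEL to read (default 1).
#' @return An [md_structure()].
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 1) {
    if (model > length(model_starts)) stop("model index out of range")
    from <- model_starts[model]
    to <- c(model_starts, length(lines) + 1L)[model + 1L] - 1L
    keep <- seq(from, to)
  } else keep <- seq_along(lines)
  sel <- keep[rec[keep] %in% c("ATOM  ", "HETATM")]
  if (length(sel) == 0) stop("no ATOM/HETATM records in ", path)

  parse_num <- function(str, lineno, what) {
    v <- suppressWarnings(as.numeric(trimws(str)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error at line %d: non-numeric %s field '%s'",
                   lineno[bad[1]], what, str[bad[1]]))
    v
  }
  ln <- lines[sel]
  altloc <- substr(ln, 17, 17)
  icode <- substr(ln, 27, 27)
  if (any(icode != " "))
    stop(sprintf("parse error at line %d: insertion codes are not supported",
                 sel[which(icode != " ")[1]]))
  first_alt <- altloc %in% c(" ", "A", "1")
  ln <- ln[first_alt]; sel <- sel[first_alt]

  name <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resid <- parse_num(substr(ln, 23, 26), sel, "residue number")
  x <- parse_num(substr(ln, 31, 38), sel, "x coordinate")
  y <- parse_num(substr(ln, 39, 46), sel, "y coordinate")
  z <- parse_num(substr(ln, 47, 54), sel, "z coordinate")
  md_structure(name = name, resid = as.integer(resid), xyz = cbind(x, y, z),
               resname = resname, chain = ifelse(chain == " ", "A", chain))
}

format_atom_line <- function(i, a) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L,
          if (nchar(a$name) < 4) paste0(" ", a$name) else a$name,
          " ", a$resname, a$chain, a$resid %% 10000L, " ",
          a$x, a$y, a$z, 1.0, 0.0, "C")
}

#' Write a structure as a PDB file
#'
#' @param structure An [md_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)),
                  function(i) format_atom_line(i, a[i, ]), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory An [md_trajectory()].
#' @param structure Template [md_structure()] providing atom metadata.
#' @param path Output path.
#' @param stride Write every `stride`-th frame.
#' @export
write_pdb_trajectory <- function(trajectory, structure, path, stride = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- structure
  frames <- seq(1L, n_frames(trajectory), by = stride)
  for (m in seq_along(frames)) {
    coords(s) <- get_frame(trajectory, frames[m])
    a <- s$atoms
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(vapply(seq_len(nrow(a)),
                      function(i) format_atom_line(i, a[i, ]), character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#' @param path Path to a multi-model PDB.
#' @param dt Frame spacing to record, ps.
#' @return An [md_trajectory()].
#' @export
read_pdb_trajectory <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  nmod <- sum(trimws(substr(lines, 1, 6)) == "MODEL")
  if (nmod == 0) nmod <- 1L
  frames <- lapply(seq_len(nmod), function(m) coords(read_pdb(path, model = m)))
  md_trajectory(frames, dt = dt)
}
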