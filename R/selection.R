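#' Select atoms by a small expression grammar
#'
#' Grammar (case-insensitive keywords):
#' \preformatted{
#'   expr      := term ("or" term)*
#'   term      := factor ("and" factor)*
#'   factor    := "(" expr ")" | primitive
#'   primitive := "resid" RANGE ("," RANGE)*   with RANGE = a | a:b (inclusive)
#'              | "name" NAME+
#'              | "all"
#' }
#' e.g. `"resid 1:172"`, `"resid 173:216 and name CA"`,
#' `"resid 1:10,40:44 or name CB"`.
#'
#' @param structure An [md_structure()].
#' @param expr Selection expression (character scalar).
#' @return Sorted unique atom indices (possibly empty), class `atom_selection`.
#' @export
select_atoms <- function(structure, expr) {
  stopifnot(inherits(structure, "md_structure"), is.character(expr))
  toks <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- parse_sel_expr(st, structure)
  if (st$pos <= length(st$toks))
    stop("selection parse error: unexpected token '", st$toks[st$pos], "'")
  as_atom_selection(which(mask), structure)
}

as_atom_selection <- function(idx, structure) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) && (min(idx) < 1 || max(idx) > n_atoms(structure)))
    stop("selection indices out of range")
  structure(idx, class = "atom_selection")
}

tokenize_selection <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) stop("selection parse error: empty expression")
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

parse_sel_expr <- function(st, s) {
  m <- parse_sel_term(st, s)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    m <- m | parse_sel_term(st, s)
  }
  m
}

parse_sel_term <- function(st, s) {
  m <- parse_sel_factor(st, s)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    m <- m & parse_sel_factor(st, s)
  }
  m
}

parse_sel_factor <- function(st, s) {
  tok <- peek(st)
  if (is.na(tok)) stop("selection parse error: unexpected end of expression")
  if (tok == "(") {
    advance(st)
    m <- parse_sel_expr(st, s)
    if (is.na(peek(st)) || peek(st) != ")")
      stop("selection parse error: missing ')'")
    advance(st)
    return(m)
  }
  kw <- tolower(advance(st))
  if (kw == "all") return(rep(TRUE, n_atoms(s)))
  if (kw == "resid") {
    arg <- peek(st)
    if (is.na(arg) || !grepl("^[0-9]+(:[0-9]+)?(,[0-9]+(:[0-9]+)?)*$", arg))
      stop("selection parse error: 'resid' expects ranges like 1:172")
    advance(st)
    resids <- integer(0)
    for (piece in strsplit(arg, ",")[[1]]) {
      ab <- as.integer(strsplit(piece, ":")[[1]])
      resids <- c(resids, if (length(ab) == 1) ab else seq(ab[1], ab[2]))
    }
    return(s$atoms$resid %in% resids)
  }
  if (kw == "name") {
    nms <- character(0)
    while (!is.na(peek(st)) &&
           !tolower(peek(st)) %in% c("and", "or", ")")) nms <- c(nms, advance(st))
    if (length(nms) == 0) stop("selection parse error: 'name' expects atom names")
    return(s$atoms$name %in% nms)
  }
  stop("selection parse error: unknown keyword '", kw, "'")
}
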