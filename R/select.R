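#' Select atoms with a small selection language
#'
#' Supported grammar (documented also in the README):
#' \preformatted{
#'   expr    := term ("or" term)*
#'   term    := factor ("and" factor)*
#'   factor  := "not" factor | "(" expr ")" | primary
#'   primary := key value+
#'   key     := "name" | "resname" | "resid" | "element" | "segid"
#'   value   := bare token; for "resid" also inclusive ranges "a:b"
#' }
#' Multiple values after one key are a union ("name CA CB"). Residue numbers
#' are 1-based; ranges are inclusive ("resid 15:185"). Matching is exact and
#' case-sensitive for names, case-insensitive for keywords.
#'
#' @param topology a `Topology` (or a `Trajectory`, whose topology is used).
#' @param expression selection string.
#' @return an AtomSet: sorted integer vector of atom indices. An empty result
#'   is returned as `integer(0)` with a message, not an error.
#' @examples
#' top <- topology(name = c("P", "CA"), resname = c("POPC", "ALA"),
#'                 resid = c(1, 1), segid = c("MEMB", "PROT"))
#' select_atoms(top, "element P and resname POPC")
#' @export
select_atoms <- function(topology, expression) {
  if (inherits(topology, "Trajectory")) topology <- topology$topology
  stopifnot(inherits(topology, "Topology"))
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- sel_parse_expr(st, topology$atoms)
  if (st$pos <= length(st$toks))
    stop("selection parse error: unexpected token '", st$toks[st$pos],
         "' in \"", expression, "\"")
  idx <- which(mask)
  if (length(idx) == 0L)
    message("selection \"", expression, "\" matched no atoms")
  idx
}

sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || !nzchar(expression))
    stop("selection parse error: expression must be a non-empty string")
  x <- gsub("\\(", " ( ", expression)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(toks) == 0L) stop("selection parse error: empty expression")
  toks
}

.sel_keys <- c("name", "resname", "resid", "element", "segid")
.sel_reserved <- c(.sel_keys, "and", "or", "not", "(", ")")

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

sel_parse_expr <- function(st, atoms) {
  m <- sel_parse_term(st, atoms)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    m <- m | sel_parse_term(st, atoms)
  }
  m
}

sel_parse_term <- function(st, atoms) {
  m <- sel_parse_factor(st, atoms)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    m <- m & sel_parse_factor(st, atoms)
  }
  m
}

sel_parse_factor <- function(st, atoms) {
  tok <- sel_peek(st)
  if (is.na(tok)) stop("selection parse error: unexpected end of expression")
  if (tolower(tok) == "not") {
    sel_next(st)
    return(!sel_parse_factor(st, atoms))
  }
  if (tok == "(") {
    sel_next(st)
    m <- sel_parse_expr(st, atoms)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      stop("selection parse error: missing ')'")
    sel_next(st)
    return(m)
  }
  sel_parse_primary(st, atoms)
}

sel_parse_primary <- function(st, atoms) {
  key <- tolower(sel_next(st))
  if (!key %in% .sel_keys)
    stop("selection parse error: expected a keyword (",
         paste(.sel_keys, collapse = "/"), "), got '", key, "'")
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !tolower(sel_peek(st)) %in% .sel_reserved) {
    vals <- c(vals, sel_next(st))
  }
  if (length(vals) == 0L)
    stop("selection parse error: keyword '", key, "' needs at least one value")
  if (key == "resid") {
    ids <- integer(0)
    for (v in vals) {
      if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
        ab <- as.integer(strsplit(v, ":")[[1]])
        ids <- c(ids, seq.int(ab[1], ab[2]))
      } else if (grepl("^-?[0-9]+$", v)) {
        ids <- c(ids, as.integer(v))
      } else {
        stop("selection parse error: bad resid value '", v, "'")
      }
    }
    return(atoms$resid %in% ids)
  }
  col <- switch(key, name = atoms$name, resname = atoms$resname,
                element = atoms$element, segid = atoms$segid)
  col %in% vals
}
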