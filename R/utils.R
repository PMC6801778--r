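#' Run an expression with a private RNG state
#'
#' Saves and restores `.Random.seed` so that generators are deterministic given
#' their own `seed` without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# standard atomic masses (amu) for the elements the pseudo-systems use
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

#' Infer element from an atom name
#'
#' Uses the leading alphabetic character of the atom name (PDB-style naming:
#' "CA" is carbon, "H15R" hydrogen, "P" phosphorus, "O3" oxygen).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
guess_element <- function(name) {
  lead <- sub("^[0-9]*", "", toupper(name))
  substr(lead, 1L, 1L)
}

#' Mass lookup for an element vector
#' @keywords internal
element_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no mass table entry for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Split `n` items into `k` contiguous blocks
#'
#' Used for block averaging of trajectory observables (uncertainty estimates).
#'
#' @return integer vector of block ids, length `n`.
#' @keywords internal
block_ids <- function(n, k) {
  if (k < 1L || n < k) stop("need at least as many items as blocks")
  sort(rep_len(seq_len(k), n))
}

#' Second Legendre polynomial P2(x) = (3 x^2 - 1) / 2
#' @param x numeric.
#' @return numeric.
#' @export
legendre_p2 <- function(x) (3 * x^2 - 1) / 2

#' Convert a diffusion coefficient between internal and reported units
#'
#' Internal unit is nm^2/ns; tables report 1e-7 cm^2/s.
#' 1 nm^2/ns = 1e-5 cm^2/s = 100 x 1e-7 cm^2/s.
#'
#' @param d numeric diffusion coefficient(s).
#' @name diffusion-units
#' @return converted value(s).
#' @export
nm2ns_to_1e7cm2s <- function(d) d * 100

#' @rdname diffusion-units
#' @export
e7cm2s_to_nm2ns <- function(d) d / 100
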