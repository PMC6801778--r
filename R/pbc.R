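#' Minimum-image displacement under periodic boundaries
#'
#' Maps a displacement into `(-L/2, +L/2]`. The boundary case `|dx| = L/2` is
#' kept at `+L/2` (documented tie-break). Vectorized over `dx`; `box_length`
#' is recycled.
#'
#' @param dx displacement(s), nm.
#' @param box_length box length(s), nm, > 0.
#' @return minimum-image displacement(s), nm.
#' @examples
#' wrap_displacement(9.8, 10)  # -0.2
#' wrap_displacement(5.0, 10)  #  5.0 (boundary kept positive)
#' @export
wrap_displacement <- function(dx, box_length) {
  if (any(box_length <= 0)) stop("box_length must be > 0")
  dx - box_length * ceiling(dx / box_length - 0.5)
}

#' Wrap positions into the primary box [0, L)
#' @param x coordinate(s), nm.
#' @param box_length box length(s), nm.
#' @return wrapped coordinate(s) in `[0, L)`.
#' @export
wrap_position <- function(x, box_length) {
  if (any(box_length <= 0)) stop("box_length must be > 0")
  x - box_length * floor(x / box_length)
}

#' Assign bilayer leaflets by median-z split
#'
#' Labels each atom of the set "upper" if its z coordinate exceeds the median
#' z of the set, else "lower". The bilayer normal is fixed to +z (membranes
#' are built in the x,y-plane). Invariant under a common z-translation.
#'
#' Molecules without a phosphate (cholesterol) should be assigned by passing
#' the z of a reference atom (e.g. the hydroxyl oxygen) through the same
#' median plane via `leaflet_of`.
#'
#' @param frame a `Frame`.
#' @param atoms AtomSet of reference atoms (e.g. phospholipid P atoms).
#' @return factor of "upper"/"lower", one per atom in `atoms`, with the
#'   median plane z as attribute `midplane`.
#' @export
assign_leaflets <- function(frame, atoms) {
  if (length(atoms) < 2L) stop("leaflet assignment needs at least 2 atoms")
  z <- frame_coords(frame, atoms)[, 3]
  mid <- stats::median(z)
  lab <- factor(ifelse(z > mid, "upper", "lower"), levels = c("upper", "lower"))
  attr(lab, "midplane") <- mid
  lab
}

#' Leaflet of arbitrary z values relative to a median plane
#' @param z numeric z coordinates (nm).
#' @param midplane median plane z (nm), e.g. from [assign_leaflets()].
#' @return factor of "upper"/"lower".
#' @export
leaflet_of <- function(z, midplane) {
  factor(ifelse(z > midplane, "upper", "lower"), levels = c("upper", "lower"))
}
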