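#' Topology: per-atom table plus molecule table
#'
#' A `Topology` is a data-frame-backed description of the atoms in a system:
#' columns `name`, `element`, `mass` (amu), `resname`, `resid`, `segid`,
#' `molid`, plus a `molecules` attribute mapping `molid` to a species label
#' (lipid species such as POPC/CHOL, or "protein"). Molecules are derived from
#' (segid, resid) for lipid segments and collapse a whole protein segment
#' ("PROT") into one molecule.
#'
#' @param name,resname character vectors, one entry per atom.
#' @param resid integer residue numbers (1-based, unique within a segment).
#' @param segid character segment ids; segment "PROT" is treated as a single
#'   protein molecule.
#' @param element optional element symbols; guessed from `name` if missing.
#' @param mass optional masses (amu); looked up from `element` if missing.
#' @return object of class `Topology`.
#' @export
topology <- function(name, resname, resid, segid = "MEMB",
                     element = NULL, mass = NULL) {
  n <- length(name)
  segid <- rep_len(segid, n)
  if (is.null(element)) element <- guess_element(name)
  if (is.null(mass)) mass <- element_mass(element)
  if (any(mass <= 0)) stop("all atom masses must be > 0")
  atoms <- data.frame(name = as.character(name), element = element,
                      mass = mass, resname = as.character(resname),
                      resid = as.integer(resid), segid = segid,
                      stringsAsFactors = FALSE)
  key <- ifelse(atoms$segid == "PROT", "PROT",
                paste(atoms$segid, atoms$resid, sep = ":"))
  atoms$molid <- match(key, unique(key))
  species <- ifelse(atoms$segid == "PROT", "protein", atoms$resname)
  molecules <- data.frame(molid = atoms$molid, species = species,
                          stringsAsFactors = FALSE)
  molecules <- molecules[!duplicated(molecules$molid), , drop = FALSE]
  # residue numbers must identify one molecule (and species) per segment
  per <- unique(atoms[, c("segid", "resid", "resname")])
  if (anyDuplicated(per[, c("segid", "resid")]))
    stop("residue_index must be unique within a segment ",
         "(conflicting residue names found)")
  structure(list(atoms = atoms, molecules = molecules), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,", nrow(x$molecules), "molecules\n")
  sp <- table(x$molecules$species)
  cat(" species:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a Topology or Trajectory
#' @param x `Topology` or `Trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) return(nrow(x$topology$atoms))
  nrow(x$atoms)
}

#' Trajectory: topology plus ordered coordinate frames
#'
#' Coordinates are stored as an array `[frame, atom, xyz]` in nm; `box` is an
#' `n_frames x 3` matrix of orthorhombic box lengths (nm); `time` is a strictly
#' increasing vector in ns.
#'
#' @param topology a `Topology`.
#' @param coords numeric array `n_frames x n_atoms x 3` (nm).
#' @param box numeric `n_frames x 3` matrix or length-3 vector (nm).
#' @param time numeric vector of frame times (ns); defaults to 0,1,2,...
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, box, time = NULL) {
  stopifnot(inherits(topology, "Topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  nf <- dim(coords)[1]
  if (nf < 1L) stop("a Trajectory needs at least one frame")
  if (dim(coords)[2] != n_atoms(topology))
    stop("consistency error: coordinate atom count (", dim(coords)[2],
         ") does not match topology atom count (", n_atoms(topology), ")")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3) stop("box must be n_frames x 3")
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) stop("time must have one entry per frame")
  if (nf > 1 && any(diff(time) <= 0)) stop("frame times must strictly increase")
  structure(list(topology = topology, coords = coords, box = box,
                 time = as.numeric(time)), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms; ",
      sprintf("t = %g..%g ns; box %g x %g x %g nm\n", min(x$time), max(x$time),
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a Trajectory
#'
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return object of class `Frame`: list with `coords` (`n_atoms x 3` nm),
#'   `box` (length-3 nm), `time` (ns) and the parent `topology`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  structure(list(coords = traj$coords[i, , , drop = TRUE],
                 box = traj$box[i, ], time = traj$time[i],
                 topology = traj$topology), class = "Frame")
}

#' Build a single-frame object from raw parts
#'
#' @param coords `n_atoms x 3` matrix (nm).
#' @param box length-3 box (nm).
#' @param topology optional `Topology`.
#' @param time time stamp (ns).
#' @return a `Frame`.
#' @export
make_frame <- function(coords, box, topology = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (!is.null(topology) && nrow(coords) != n_atoms(topology))
    stop("consistency error: coords do not match topology atom count")
  structure(list(coords = coords, box = as.numeric(box), time = time,
                 topology = topology), class = "Frame")
}

#' Coordinates of an atom selection in one frame
#' @param frame a `Frame`.
#' @param atoms integer atom indices (an AtomSet); NULL for all atoms.
#' @return matrix `length(atoms) x 3` (nm).
#' @export
frame_coords <- function(frame, atoms = NULL) {
  if (is.null(atoms)) frame$coords else frame$coords[atoms, , drop = FALSE]
}
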