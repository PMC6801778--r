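#' Load a trajectory from topology + coordinate files
#'
#' Topology formats: PDB or GRO (decided by file extension). Coordinate
#' format: DCD (CHARMM/NAMD). All coordinates are normalized to nm
#' internally (PDB and DCD are Angstrom on disk, GRO is nm); times are ns.
#' DCD time metadata is ignored (its AKMA encoding is tool-dependent); the
#' frame interval is taken from `dt`.
#'
#' @param topology_path path to a .pdb or .gro file.
#' @param trajectory_path optional path to a .dcd file; if omitted the
#'   topology coordinates become a single frame.
#' @param dt frame interval in ns (default 1).
#' @param box optional length-3 box (nm) overriding any box found on file.
#' @return a `Trajectory`.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL, dt = 1,
                            box = NULL) {
  if (!file.exists(topology_path))
    stop("format error: topology file not found: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
    pdb = read_topology_pdb(topology_path),
    gro = read_topology_gro(topology_path),
    stop("format error: unsupported topology format '.", ext,
         "' (PDB and GRO are supported)"))
  if (is.null(box)) box <- top$box
  if (is.null(trajectory_path)) {
    if (is.null(box)) {
      span <- apply(top$coords, 2, function(v) diff(range(v)))
      box <- pmax(span, 1e-6) + 2
    }
    return(trajectory(top$topology,
                      array(top$coords, c(1, nrow(top$coords), 3)),
                      box, time = 0))
  }
  if (!file.exists(trajectory_path))
    stop("format error: trajectory file not found: ", trajectory_path)
  text <- tolower(tools::file_ext(trajectory_path))
  if (text != "dcd")
    stop("format error: unsupported trajectory format '.", text,
         "' (DCD is supported)")
  xyz <- tryCatch(
    bio3d::read.dcd(trajectory_path, verbose = FALSE),
    error = function(e) stop("format error reading DCD: ", conditionMessage(e)))
  cell <- tryCatch(
    bio3d::read.dcd(trajectory_path, verbose = FALSE, cell = TRUE),
    error = function(e) NULL)
  na <- ncol(xyz) / 3
  if (na != n_atoms(top$topology))
    stop("consistency error: trajectory has ", na,
         " atoms but topology has ", n_atoms(top$topology))
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, by = 3, length.out = na)] / 10
  if (is.null(box)) {
    if (!is.null(cell)) box <- cell[, 1:3, drop = FALSE] / 10
    else stop("format error: no box information in DCD and none supplied")
  }
  trajectory(top$topology, coords, box, time = (seq_len(nf) - 1) * dt)
}

read_topology_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error reading PDB: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  segid <- a$segid
  if (is.null(segid) || all(is.na(segid)) || all(segid == "")) {
    segid <- ifelse(is.na(a$chain) | a$chain == "", "MEMB", a$chain)
    segid <- ifelse(segid == "P", "PROT", segid)
  }
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- guess_element(a$elety)
  top <- topology(name = a$elety, resname = a$resid, resid = a$resno,
                  segid = segid, element = elesy)
  box <- NULL
  if (!is.null(pdb$cryst1) && !is.null(pdb$cryst1$abc) &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    box <- pdb$cryst1$abc / 10
  list(topology = top, coords = cbind(a$x, a$y, a$z) / 10, box = box)
}

read_topology_gro <- function(path) {
  lines <- tryCatch(readLines(path), error = function(e)
    stop("format error reading GRO: ", conditionMessage(e)))
  if (length(lines) < 3) stop("format error: GRO file too short")
  na <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(na) || length(lines) < 2 + na + 1)
    stop("format error: bad GRO atom count line")
  al <- lines[3:(2 + na)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(c(resid, x, y, z))) stop("format error: malformed GRO atom line")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + na]),
                                               "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && all(is.finite(boxv[1:3])) &&
             all(boxv[1:3] > 0)) boxv[1:3] else NULL
  # GRO carries no segment field; protein residues are recognized by CA-only
  # naming convention is not attempted -- callers can re-segment if needed.
  top <- topology(name = name, resname = resname, resid = resid,
                  segid = "MEMB")
  list(topology = top, coords = cbind(x, y, z), box = box)
}

#' Write a trajectory as PDB (or GRO) topology + DCD coordinates
#'
#' The topology file carries frame 1; the DCD carries all frames (Angstrom,
#' with the orthorhombic cell in each frame's cell record). These files are
#' readable by [load_trajectory()] and by standard MD tooling.
#'
#' @param traj a `Trajectory`.
#' @param topology_path output .pdb or .gro path.
#' @param trajectory_path optional output .dcd path.
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, topology_path, trajectory_path = NULL) {
  ext <- tolower(tools::file_ext(topology_path))
  f1 <- get_frame(traj, 1)
  a <- traj$topology$atoms
  if (ext == "pdb") {
    write_pdb(traj, topology_path)
  } else if (ext == "gro") {
    write_gro(traj, topology_path)
  } else stop("format error: unsupported topology output '.", ext, "'")
  if (!is.null(trajectory_path)) write_dcd(traj, trajectory_path)
  invisible(c(topology_path, trajectory_path))
}

# fixed-column PDB writer (frame 1, Angstrom, CRYST1 box); names < 4 chars
# get the conventional leading-space placement in columns 13-16
write_pdb <- function(traj, path) {
  f1 <- get_frame(traj, 1)
  a <- traj$topology$atoms
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  xyz <- f1$coords * 10
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            f1$box[1] * 10, f1$box[2] * 10, f1$box[3] * 10, 90, 90, 90),
    sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
            seq_len(nrow(a)) %% 100000, name4, substr(a$resname, 1, 4),
            a$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
            substr(a$segid, 1, 4), a$element),
    "END")
  writeLines(lines, path)
}

write_gro <- function(traj, path) {
  f1 <- get_frame(traj, 1)
  a <- traj$topology$atoms
  lines <- c("synthetic configuration", sprintf("%5d", nrow(a)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000, substr(a$resname, 1, 5),
                     substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000,
                     f1$coords[, 1], f1$coords[, 2], f1$coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f", f1$box[1], f1$box[2], f1$box[3]))
  writeLines(lines, path)
}

#' Write the coordinate frames of a Trajectory as a CHARMM-style DCD file
#'
#' Coordinates are written in Angstrom with the orthorhombic cell stored in
#' each frame's crystal record. No installed R package writes DCD; this
#' writer produces files that `bio3d::read.dcd` (and NAMD/CHARMM tooling)
#' read back.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[8] <- 3L * na
  icntrl[10] <- readBin(writeBin(1.0, raw(), size = 4), "integer", 1, size = 4)
  icntrl[11] <- 1L; icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "memanchor synthetic trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4), 4)
  for (i in seq_len(nf)) {
    b <- traj$box[i, ] * 10
    rec(function() writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])),
                            con, size = 8), 48)
    for (d in 1:3)
      rec(function() writeBin(as.double(traj$coords[i, , d] * 10),
                              con, size = 4), 4L * na)
  }
  invisible(path)
}
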