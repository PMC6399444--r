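#' Read a structure file (PDB)
#'
#' Parses ATOM/HETATM records through bio3d, converts coordinates from the
#' PDB's native angstroms to nanometres, and assigns each atom a category
#' (protein / lipid / water / ion) from its residue name.
#'
#' @param path PDB file.
#' @param segments optional named segment map (see [read_segment_map()]).
#' @return list with elements \code{topology} (an [md_topology()]) and
#'   \code{frame} (an [md_frame()], coordinates in nm).
#' @export
read_structure <- function(path, segments = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty-input error: no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 47, 54))))) {
      stop(sprintf("format error: unparseable coordinate record at line %d of %s", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  # derive element from the atom name when the element column is blank
  element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[blank])
  chain <- at$chain
  chain[is.na(chain)] <- ""
  atoms <- data.frame(
    atom_id = at$eleno,
    atom_name = trimws(at$elety),
    element = toupper(trimws(element)),
    residue_name = trimws(at$resid),
    residue_id = at$resno,
    chain_id = chain,
    category = categorize_residue(at$resid, is_het = at$type == "HETATM"),
    stringsAsFactors = FALSE
  )
  topo <- md_topology(atoms, segments = segments)
  coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10  # angstrom -> nm
  list(topology = topo, frame = md_frame(coords, time = 0))
}

#' Write a structure as PDB
#'
#' Coordinates are converted from nanometres back to angstroms. The writer
#' preserves atom order, names, residue ids and chain ids so that a
#' write/read round trip is the identity on topology metadata.
#'
#' @param topology an [md_topology()].
#' @param frame an [md_frame()] with matching atom count.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_structure <- function(topology, frame, path) {
  stopifnot(inherits(topology, "md_topology"), inherits(frame, "md_frame"))
  if (nrow(frame$coords) != nrow(topology$atoms)) {
    stop("shape error: frame atom count does not match topology")
  }
  at <- topology$atoms
  chain <- substr(ifelse(at$chain_id == "", " ", at$chain_id), 1, 1)
  xyz <- frame$coords * 10  # nm -> angstrom
  # PDB fixed columns; atom names shorter than 4 characters start in column
  # 14, residue names occupy 18-21 (4-character lipid names included)
  name4 <- ifelse(nchar(at$atom_name) < 4,
                  sprintf(" %-3s", at$atom_name),
                  sprintf("%-4s", at$atom_name))
  lines <- sprintf("%-6s%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(at$category == "protein", "ATOM", "HETATM"),
                   at$atom_id, name4, at$residue_name, chain, at$residue_id,
                   xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read a trajectory file
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{xyz}{Plain multi-frame XYZ-style text: an atom-count line, a
#'     comment line carrying \code{time_ns= <t>}, then one
#'     \code{name x y z} line per atom with coordinates in nanometres.}
#'   \item{dcd}{The CHARMM/NAMD DCD binary dialect written by
#'     [write_trajectory()]: little-endian Fortran unformatted records,
#'     single-precision coordinates in angstroms (converted to nm on read),
#'     no unit-cell records.}
#' }
#'
#' @param path trajectory file.
#' @param topology the [md_topology()] the frames belong to.
#' @param frame_interval declared saving interval in picoseconds; attached as
#'   metadata and used to reconstruct times when the file carries none.
#' @param format \code{"auto"} (by extension), \code{"xyz"} or \code{"dcd"}.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, topology, frame_interval = NULL,
                            format = c("auto", "xyz", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  }
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    n_atoms <- ncol(xyz) / 3
    if (n_atoms != nrow(topology$atoms)) {
      stop(sprintf("shape error: frame 1 has %d atoms but topology has %d",
                   n_atoms, nrow(topology$atoms)))
    }
    nf <- nrow(xyz)
    coords <- array(NA_real_, dim = c(n_atoms, 3, nf))
    for (i in seq_len(nf)) coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    return(md_trajectory(topology, coords, frame_interval = frame_interval))
  }
  lines <- readLines(path, warn = FALSE)
  n_top <- nrow(topology$atoms)
  frames <- list()
  times <- numeric(0)
  pos <- 1L
  fidx <- 0L
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop(sprintf("format error: bad atom-count line at frame %d", fidx))
    if (n != n_top) {
      stop(sprintf("shape error: frame %d declares %d atoms but topology has %d",
                   fidx, n, n_top))
    }
    comment <- if (pos + 1L <= length(lines)) lines[pos + 1L] else ""
    t_ns <- NA_real_
    m <- regmatches(comment, regexec("time_ns=\\s*([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) t_ns <- as.numeric(m[2])
    if (pos + 1L + n > length(lines)) {
      stop(sprintf("shape error: truncated coordinates at frame %d", fidx))
    }
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(vapply(parts, length, 1L) < 4)) {
      stop(sprintf("shape error: truncated coordinates at frame %d", fidx))
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) {
      stop(sprintf("format error: non-numeric coordinates at frame %d", fidx))
    }
    frames[[fidx]] <- xyz
    times[fidx] <- t_ns
    pos <- pos + 2L + n
  }
  if (fidx == 0L) stop("empty-input error: no frames in ", path)
  coords <- array(NA_real_, dim = c(n_top, 3, fidx))
  for (i in seq_len(fidx)) coords[, , i] <- frames[[i]]
  if (any(is.na(times))) times <- NULL
  md_trajectory(topology, coords, times = times, frame_interval = frame_interval)
}

#' Write a trajectory file
#'
#' Writes either the multi-frame XYZ-style text dialect (nanometres; one
#' atom-count line, one \code{time_ns=} comment line and one atom line per
#' frame) or the DCD binary dialect (little-endian, single-precision,
#' angstroms, CHARMM header version 24, no unit-cell records).
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"xyz"} or \code{"dcd"}.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "xyz", "dcd")) {
  stopifnot(inherits(traj, "md_trajectory"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "xyz"
  }
  if (format == "dcd") return(.write_dcd(traj, path))
  n <- nrow(traj$topology$atoms)
  names_col <- traj$topology$atoms$atom_name
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d time_ns= %.9g", i, traj$times[i]), con)
    xyz <- traj$coords[, , i, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-4s %14.9f %14.9f %14.9f",
                       names_col, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

# DCD writer: little-endian Fortran unformatted records; coordinates stored
# as float32 in angstroms. Header follows the CHARMM convention (icntrl[20]
# = 24) so standard readers accept the file.
.write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- nrow(traj$topology$atoms)
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf          # frames in file
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # step interval
  icntrl[4] <- nf
  icntrl[20] <- 24L        # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    # slot 10 carries the timestep as float32 in the CHARMM layout
    writeBin(as.integer(icntrl[1:9]), con, size = 4, endian = "little")
    dt <- if (is.null(traj$frame_interval)) 0 else traj$frame_interval
    writeBin(as.numeric(dt), con, size = 4, endian = "little")
    writeBin(as.integer(icntrl[11:20]), con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "sercatraj DCD dialect: float32 angstrom, little-endian")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"), 4)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i, drop = TRUE] * 10  # nm -> angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(xyz[, d]), con, size = 4, endian = "little"),
          4 * na)
    }
  }
  invisible(path)
}
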