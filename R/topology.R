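# Standard amino-acid residue names (CHARMM-style protonation variants included).
.AA_NAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "ASH", "GLH", "LYN", "CYX", "MSE"
)
.WATER_NAMES <- c("HOH", "TIP3", "TIP", "WAT", "SPC", "SOL", "TP3")
.ION_NAMES <- c("K", "CL", "NA", "POT", "SOD", "CLA", "CA", "MG", "ZN", "K+", "CL-", "NA+")
.LIPID_NAMES <- c("POPC", "DOPC", "DPPC", "DMPC", "POPE", "POPS", "PC", "PE", "LPC")

#' Assign a chemical category to residue names
#'
#' Residues are mapped to one of the four categories the trajectory model
#' recognises: standard amino acids to \code{protein}, phosphatidylcholine-like
#' residue names to \code{lipid}, common water models to \code{water} and
#' monatomic salt species to \code{ion}. Unrecognised residue names fall back
#' to \code{protein} (ATOM-style records) so that modified residues in real
#' structures do not abort parsing; a warning names them.
#'
#' @param residue_name character vector of residue names.
#' @param is_het logical vector, \code{TRUE} where the record was HETATM.
#' @return character vector of categories.
#' @keywords internal
categorize_residue <- function(residue_name, is_het = rep(FALSE, length(residue_name))) {
  rn <- toupper(residue_name)
  cat <- rep(NA_character_, length(rn))
  cat[rn %in% .AA_NAMES] <- "protein"
  cat[rn %in% .WATER_NAMES] <- "water"
  cat[rn %in% .ION_NAMES] <- "ion"
  cat[rn %in% .LIPID_NAMES] <- "lipid"
  unknown <- is.na(cat)
  if (any(unknown)) {
    warning(sprintf(
      "unrecognised residue name(s) %s; assigning %s",
      paste(unique(rn[unknown]), collapse = ", "),
      ifelse(any(is_het[unknown]), "'lipid' (HETATM) / 'protein' (ATOM)", "'protein'")
    ), call. = FALSE)
    cat[unknown] <- ifelse(is_het[unknown], "lipid", "protein")
  }
  cat
}

#' Construct a topology
#'
#' A topology records per-atom metadata (1-based id, atom name, element,
#' residue name, 1-based residue id, chain id, category) plus an optional
#' named segment map from labels such as \code{"M2"} or \code{"N-domain"} to
#' residue-id vectors. Residue numbering follows the structure file verbatim
#' (for SERCA work, SERCA1a numbering, so labels such as Glu309 apply
#' directly).
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{element}, \code{residue_name}, \code{residue_id}, \code{chain_id},
#'   \code{category}.
#' @param segments named list mapping segment labels to integer residue-id
#'   vectors.
#' @return an object of class \code{md_topology}.
#' @export
md_topology <- function(atoms, segments = list()) {
  required <- c("atom_id", "atom_name", "element", "residue_name",
                "residue_id", "chain_id", "category")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("topology atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (nrow(atoms) == 0) stop("empty-input error: topology has zero atoms")
  if (any(diff(atoms$atom_id) <= 0)) {
    stop("atom_ids must be strictly increasing and unique")
  }
  bad_cat <- setdiff(unique(atoms$category), c("protein", "lipid", "water", "ion"))
  if (length(bad_cat) > 0) {
    stop("invalid atom category: ", paste(bad_cat, collapse = ", "))
  }
  topo <- structure(list(atoms = atoms, segments = list()), class = "md_topology")
  if (length(segments) > 0) topo <- set_segments(topo, segments)
  topo
}

#' Attach a segment map to a topology
#'
#' @param topology an \code{md_topology}.
#' @param segments named list of integer residue-id vectors.
#' @return the topology with segments validated and attached.
#' @export
set_segments <- function(topology, segments) {
  stopifnot(inherits(topology, "md_topology"))
  if (length(segments) > 0 && (is.null(names(segments)) || any(names(segments) == ""))) {
    stop("segment map entries must be named")
  }
  known <- unique(topology$atoms$residue_id)
  segments <- lapply(segments, function(r) as.integer(r))
  for (label in names(segments)) {
    resids <- segments[[label]]
    if (length(resids) == 0) stop("segment '", label, "' is empty")
    absent <- setdiff(resids, known)
    if (length(absent) > 0) {
      stop("segment '", label, "' refers to residue id(s) absent from the topology: ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
  }
  topology$segments <- segments
  topology
}

#' Read a segment map from a YAML configuration file
#'
#' The file maps segment labels to residue ranges, each range written either
#' as a two-element \code{[start, stop]} list or a list of such ranges, e.g.
#' \preformatted{
#' M2: [89, 120]
#' A-domain:
#'   - [1, 48]
#'   - [121, 245]
#' }
#'
#' @param path YAML file path.
#' @return named list of integer residue-id vectors.
#' @export
read_segment_map <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(entry) {
    if (is.list(entry)) {
      unlist(lapply(entry, function(rng) seq.int(rng[[1]], rng[[2]])))
    } else if (is.numeric(entry) && length(entry) == 2) {
      seq.int(entry[[1]], entry[[2]])
    } else if (is.numeric(entry)) {
      as.integer(entry)
    } else {
      stop("cannot interpret segment entry: ", deparse(entry))
    }
  })
  lapply(out, function(x) sort(unique(as.integer(x))))
}

#' Default SERCA1a segment map
#'
#' Conventional residue ranges for the ten transmembrane helices M1--M10 and
#' the cytosolic N/P/A domains of SERCA1a, shipped as a configuration file.
#' The ranges follow the structural literature on the pump; they are a
#' convention, not a crystallographic assignment, and can be overridden by
#' supplying another file to [read_segment_map()].
#'
#' @return named list of integer residue-id vectors.
#' @export
serca_segment_map <- function() {
  path <- system.file("extdata", "serca_segments.yaml", package = "sercatraj",
                      mustWork = TRUE)
  read_segment_map(path)
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("md_topology: %d atoms, %d residues",
              nrow(x$atoms), length(unique(x$atoms$residue_id))))
  tab <- table(x$atoms$category)
  cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n", sep = "")
  if (length(x$segments) > 0) {
    cat("segments:", paste(names(x$segments), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z in
#'   nanometres.
#' @param time frame time in nanoseconds.
#' @param box optional 3 orthorhombic edge lengths, nanometres.
#' @return an object of class \code{md_frame}.
#' @export
md_frame <- function(coords, time = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("frame coordinates must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("frame coordinates contain non-finite values")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive edge lengths (nm)")
    }
  }
  structure(list(coords = unname(coords), time = as.numeric(time), box = box),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' The single substrate every analysis consumes: a topology plus an ordered
#' stack of coordinate frames. Coordinates are stored as an
#' \code{n_atoms x 3 x n_frames} array in nanometres; times in nanoseconds.
#'
#' @param topology an \code{md_topology}.
#' @param coords \code{n_atoms x 3 x n_frames} numeric array (nm), or a list
#'   of \code{md_frame}s.
#' @param times numeric vector of frame times (ns); derived from
#'   \code{frame_interval} when omitted.
#' @param frame_interval declared saving interval in picoseconds (optional
#'   metadata; never assumed).
#' @param box optional \code{n_frames x 3} matrix of box edges (nm).
#' @return an object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, coords, times = NULL, frame_interval = NULL,
                          box = NULL) {
  stopifnot(inherits(topology, "md_topology"))
  if (is.list(coords) && !is.array(coords)) {
    frames <- coords
    n <- length(frames)
    if (n == 0) stop("empty-input error: trajectory has zero frames")
    arr <- array(NA_real_, dim = c(nrow(frames[[1]]$coords), 3, n))
    tms <- numeric(n)
    bx <- NULL
    for (i in seq_len(n)) {
      arr[, , i] <- frames[[i]]$coords
      tms[i] <- frames[[i]]$time
      if (!is.null(frames[[i]]$box)) {
        if (is.null(bx)) bx <- matrix(NA_real_, n, 3)
        bx[i, ] <- frames[[i]]$box
      }
    }
    coords <- arr
    if (is.null(times)) times <- tms
    if (is.null(box)) box <- bx
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (n_atoms != nrow(topology$atoms)) {
    stop(sprintf("shape error: %d coordinate rows per frame but topology has %d atoms",
                 n_atoms, nrow(topology$atoms)))
  }
  if (!all(is.finite(coords))) stop("trajectory coordinates contain non-finite values")
  if (is.null(times)) {
    if (is.null(frame_interval)) {
      times <- seq_len(n_frames) - 1  # frame index as pseudo-time
    } else {
      times <- (seq_len(n_frames) - 1) * frame_interval / 1000
    }
  }
  times <- as.numeric(times)
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!is.null(frame_interval) && n_frames > 2) {
    dt <- diff(times) * 1000
    if (any(abs(dt - frame_interval) > 1e-9 * max(frame_interval, 1))) {
      stop("frame times are not uniformly spaced at the declared frame_interval")
    }
  }
  structure(list(topology = topology, coords = coords, times = times,
                 frame_interval = frame_interval, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms", n_frames(x), nrow(x$topology$atoms)))
  if (!is.null(x$frame_interval)) cat(sprintf(", %g ps/frame", x$frame_interval))
  cat(sprintf(", t = [%g, %g] ns\n", x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{md_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame of a trajectory
#' @param traj an \code{md_trajectory}.
#' @param i frame index (1-based).
#' @return an \code{md_frame}.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  md_frame(traj$coords[, , i, drop = TRUE], time = traj$times[i],
           box = if (!is.null(traj$box)) traj$box[i, ] else NULL)
}
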