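#' Per-frame RMSD time series against a reference structure
#'
#' Each frame is first superposed on the reference over \code{fit_sel}
#' (rigid-body motion removed), then the RMSD is measured over
#' \code{measure_sel}. With \code{fit_sel == measure_sel} this is the
#' classical aligned RMSD trace, e.g. of the cytosolic headpiece backbone
#' against the crystal structure.
#'
#' @param traj an [md_trajectory()].
#' @param reference an [md_frame()] with the same atom count as the
#'   trajectory topology.
#' @param fit_sel selection used for superposition.
#' @param measure_sel selection over which RMSD is reported (defaults to
#'   \code{fit_sel}).
#' @return numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_timeseries <- function(traj, reference, fit_sel, measure_sel = fit_sel) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(reference, "md_frame"))
  n <- nrow(traj$topology$atoms)
  fit_idx <- .as_indices(fit_sel, n)
  meas_idx <- .as_indices(measure_sel, n)
  ref <- reference$coords
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    sp <- superpose(xyz, ref, fit_idx)
    coord_rmsd(sp$coords, ref, meas_idx)
  }, numeric(1))
}

#' Per-segment RMSD profile
#'
#' The comparison device behind per-helix stability analysis: every frame is
#' superposed on the reference over a common fit selection (e.g. the
#' all-transmembrane backbone) and the RMSD of each named segment is measured
#' over that segment's atoms, yielding a mean and standard deviation per
#' segment across frames.
#'
#' @param traj an [md_trajectory()].
#' @param reference an [md_frame()].
#' @param segments character vector of segment labels (must exist in the
#'   topology's segment map).
#' @param fit_sel selection for the per-frame superposition.
#' @param measure_expr selection-expression template applied per segment;
#'   \code{"segment \%s"} by default, so e.g. backbone-only profiles use
#'   \code{"segment \%s and name N CA C O"}.
#' @return data.frame with columns \code{segment}, \code{mean_rmsd},
#'   \code{sd_rmsd} (nm).
#' @export
segment_rmsd_profile <- function(traj, reference, segments, fit_sel,
                                 measure_expr = "segment %s") {
  stopifnot(inherits(traj, "md_trajectory"))
  topo <- traj$topology
  unknown <- setdiff(segments, names(topo$segments))
  if (length(unknown) > 0) {
    stop("lookup error: undefined segment label(s): ", paste(unknown, collapse = ", "))
  }
  seg_idx <- lapply(segments, function(s) {
    select_atoms(topo, sprintf(measure_expr, s))$indices
  })
  n <- nrow(topo$atoms)
  fit_idx <- .as_indices(fit_sel, n)
  ref <- reference$coords
  nf <- n_frames(traj)
  rmsds <- matrix(NA_real_, nf, length(segments))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    sp <- superpose(xyz, ref, fit_idx)
    for (s in seq_along(segments)) {
      rmsds[f, s] <- coord_rmsd(sp$coords, ref, seg_idx[[s]])
    }
  }
  data.frame(
    segment = segments,
    mean_rmsd = colMeans(rmsds),
    sd_rmsd = apply(rmsds, 2, stats::sd),
    stringsAsFactors = FALSE
  )
}

#' Leader/medoid conformational clustering
#'
#' Deterministic leader clustering on pairwise coordinate RMSD over a
#' selection: frames are scanned in order and assigned to the first cluster
#' whose leader frame lies within \code{cutoff}; otherwise they open a new
#' cluster. Afterwards each cluster's representative is recomputed as the
#' medoid (the member minimizing the summed in-cluster RMSD). Frames are
#' assumed pre-aligned on a common fit selection; no refitting happens
#' during the scan, which keeps the metric a true pairwise RMSD of the
#' selected atoms (e.g. lipid-headgroup heavy atoms).
#'
#' @param traj an [md_trajectory()] with frames already aligned.
#' @param sel [select_atoms()] result over which RMSD is computed.
#' @param cutoff RMSD cutoff in nm (default 0.1 nm).
#' @return object of class \code{cluster_result}: data.frame
#'   \code{clusters} with columns \code{cluster}, \code{population},
#'   \code{n_frames}, \code{representative} (frame index), plus
#'   \code{assignment}, the per-frame cluster id.
#' @export
cluster_conformations <- function(traj, sel, cutoff = 0.1) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (cutoff <= 0) stop("cutoff must be positive")
  idx <- .as_indices(sel, nrow(traj$topology$atoms))
  nf <- n_frames(traj)
  # flatten selected coordinates once: nf x (3 * n_sel)
  X <- t(apply(traj$coords[idx, , , drop = FALSE], 3, identity))
  if (nf == 1) X <- matrix(X, nrow = 1)
  n_sel <- length(idx)
  rmsd_rows <- function(i, js) {
    # RMSD between frame i and frames js from the flattened matrix
    d2 <- (X[js, , drop = FALSE] - matrix(X[i, ], length(js), ncol(X), byrow = TRUE))^2
    sqrt(rowSums(d2) / n_sel)
  }
  leaders <- integer(0)
  assignment <- integer(nf)
  for (f in seq_len(nf)) {
    placed <- FALSE
    if (length(leaders) > 0) {
      d <- rmsd_rows(f, leaders)
      hit <- which(d <= cutoff)
      if (length(hit) > 0) {
        assignment[f] <- hit[1]
        placed <- TRUE
      }
    }
    if (!placed) {
      leaders <- c(leaders, f)
      assignment[f] <- length(leaders)
    }
  }
  k <- length(leaders)
  reps <- integer(k)
  for (c in seq_len(k)) {
    members <- which(assignment == c)
    if (length(members) == 1) { reps[c] <- members; next }
    sums <- vapply(members, function(m) sum(rmsd_rows(m, members)), numeric(1))
    reps[c] <- members[which.min(sums)]
  }
  ord <- order(tabulate(assignment, k), decreasing = TRUE)
  remap <- match(seq_len(k), ord)
  assignment <- remap[assignment]
  sizes <- tabulate(assignment, k)
  clusters <- data.frame(
    cluster = seq_len(k),
    population = sizes / nf,
    n_frames = sizes,
    representative = reps[ord]
  )
  structure(list(clusters = clusters, assignment = assignment, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters (cutoff %g nm)\n",
              nrow(x$clusters), x$cutoff))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
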