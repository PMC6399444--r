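# Seeded synthetic-trajectory generators with planted ground truth. Each
# generator is a pure function of its spec: it seeds a local RNG stream and
# restores the caller's RNG state on exit, and it returns the planted
# quantities alongside the fixture so tests recover parameters rather than
# re-derive them.

# Run code under a local seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Two-state (or k-state) hidden-Markov distance process
#'
#' Emulates the bimodal inter-atomic distance processes seen in
#' residue--lipid contact analysis: a hidden state chain where each frame
#' switches with probability \code{transition_rate} (the new state drawn from
#' \code{stationary_weights}, making those weights the exact stationary
#' distribution), and a Gaussian emission per state. With the default two
#' states at 0.5 and 0.8 nm this reproduces the double-peaked distance
#' distributions characteristic of the lipid-bound M2--M4 interface.
#'
#' @param state_means per-state mean distances, nm.
#' @param state_sigmas per-state emission standard deviations, nm (>= 0).
#' @param transition_rate per-frame switch probability in [0, 1].
#' @param stationary_weights state probabilities summing to 1.
#' @param n_frames number of frames.
#' @param seed RNG seed (one seeded stream per call).
#' @return list: \code{values} (per-frame distances, nm), \code{states}
#'   (planted hidden states) and \code{spec} (the arguments).
#' @export
make_distance_process <- function(state_means = c(0.5, 0.8),
                                  state_sigmas = c(0.03, 0.03),
                                  transition_rate = 0.05,
                                  stationary_weights = c(0.5, 0.5),
                                  n_frames = 10000, seed = 1) {
  k <- length(state_means)
  stopifnot(length(state_sigmas) == k, length(stationary_weights) == k)
  if (abs(sum(stationary_weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(state_sigmas < 0)) stop("sigmas must be >= 0")
  if (transition_rate < 0 || transition_rate > 1) stop("transition_rate must be in [0, 1]")
  .with_seed(seed, {
    states <- integer(n_frames)
    states[1] <- sample.int(k, 1, prob = stationary_weights)
    if (n_frames > 1) {
      switch_draw <- stats::runif(n_frames - 1) < transition_rate
      new_states <- sample.int(k, n_frames - 1, replace = TRUE, prob = stationary_weights)
      for (i in 2:n_frames) {
        states[i] <- if (switch_draw[i - 1]) new_states[i - 1] else states[i - 1]
      }
    }
    values <- stats::rnorm(n_frames, mean = state_means[states], sd = state_sigmas[states])
    values <- pmax(values, 0)  # distances are non-negative
    list(values = values, states = states,
         spec = list(state_means = state_means, state_sigmas = state_sigmas,
                     transition_rate = transition_rate,
                     stationary_weights = stationary_weights,
                     n_frames = n_frames, seed = seed))
  })
}

#' Trajectory with a planted principal-component spectrum
#'
#' Frames are \eqn{mean + \sum_k a_k(t) v_k} with a random orthonormal basis
#' \eqn{v_k} and independent scores \eqn{a_k}: Gaussian with variance equal
#' to the planted eigenvalue, except for components flagged non-Gaussian,
#' which draw from a symmetric two-well mixture (wells at
#' \eqn{\pm}offset, per-well sigma = offset/3, so the planted total variance
#' still equals the eigenvalue and a one-Gaussian fit fails the 0.9
#' r-squared band). The true basis, spectrum and scores are returned for
#' recovery testing.
#'
#' @param n_atoms number of pseudo-atoms (each contributes 3 coordinates).
#' @param eigenvalues strictly positive, descending planted variances, nm^2.
#' @param nongaussian_components indices of components given two-well scores.
#' @param n_frames number of frames (recovery tests want
#'   \code{n_frames >> 3 n_atoms}).
#' @param seed RNG seed.
#' @return list: \code{trajectory} (an [md_trajectory()] of C-alpha-like
#'   protein atoms), \code{basis} (3N x k planted orthonormal columns),
#'   \code{eigenvalues}, \code{scores} (n_frames x k), \code{spec}.
#' @export
make_planted_pca_trajectory <- function(n_atoms = 30,
                                        eigenvalues = c(4, 2, 1, 0.5) * 1e-3,
                                        nongaussian_components = integer(0),
                                        n_frames = 20000, seed = 1) {
  D <- 3L * n_atoms
  k <- length(eigenvalues)
  if (k > D) stop("dimension error: more eigenvalues than coordinates (3 * n_atoms)")
  if (any(eigenvalues < 0) || any(diff(eigenvalues) > 0)) {
    stop("eigenvalues must be non-negative and descending")
  }
  .with_seed(seed, {
    basis <- qr.Q(qr(matrix(stats::rnorm(D * k), D, k)))
    mean_coords <- as.vector(t(matrix(stats::rnorm(D, sd = 1), n_atoms, 3)))
    scores <- matrix(0, n_frames, k)
    for (j in seq_len(k)) {
      lam <- eigenvalues[j]
      if (lam == 0) next
      if (j %in% nongaussian_components) {
        offset <- sqrt(0.9 * lam)       # wells at +/- offset, sigma = offset/3:
        sig <- offset / 3               # total variance offset^2 + sig^2 = lam
        well <- sample(c(-1, 1), n_frames, replace = TRUE)
        scores[, j] <- well * offset + stats::rnorm(n_frames, sd = sig)
      } else {
        scores[, j] <- stats::rnorm(n_frames, sd = sqrt(lam))
      }
    }
    X <- matrix(mean_coords, n_frames, D, byrow = TRUE) + scores %*% t(basis)
    coords <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      coords[, , f] <- matrix(X[f, ], n_atoms, 3, byrow = TRUE)
    }
    topo <- md_topology(data.frame(
      atom_id = seq_len(n_atoms), atom_name = "CA", element = "C",
      residue_name = "ALA", residue_id = seq_len(n_atoms), chain_id = "A",
      category = "protein", stringsAsFactors = FALSE
    ))
    traj <- md_trajectory(topo, coords, frame_interval = 20)
    list(trajectory = traj, basis = basis, eigenvalues = eigenvalues,
         scores = scores,
         spec = list(n_atoms = n_atoms, eigenvalues = eigenvalues,
                     nongaussian_components = nongaussian_components,
                     n_frames = n_frames, seed = seed))
  })
}

#' Synthetic water-wire system with a planted on/off schedule
#'
#' Builds a minimal pore model: a source site (two carboxyl-like oxygens of a
#' glutamate), a sink site (carboxamide-like atoms of an asparagine) 1.12 nm
#' away along z, three chain waters and a set of decoy bulk waters. During
#' each on-window the chain waters sit on the source-sink axis at 0.28 nm
#' successive O--O spacing (safely inside the 0.35 nm H-bond cutoff), forming
#' the three-water hydrogen-bonded wire; outside the windows all waters are
#' parked on a coarse grid with > 0.6 nm mutual spacing, safely outside
#' H-bond range of each other and of the endpoints.
#'
#' @param on_windows integer matrix / data.frame with columns
#'   \code{start_frame}, \code{end_frame} (inclusive, 1-based,
#'   non-overlapping).
#' @param n_frames total frames.
#' @param n_waters_bulk number of decoy waters.
#' @param frame_interval ps per frame.
#' @param seed RNG seed (jitters bulk-water rest positions by < 0.02 nm).
#' @return list: \code{trajectory}, \code{config} (a ready [wire_config()]),
#'   \code{windows} (the planted schedule), \code{chain_residues}.
#' @export
make_wire_system <- function(on_windows = matrix(numeric(0), ncol = 2),
                             n_frames = 100, n_waters_bulk = 10,
                             frame_interval = 20, seed = 1) {
  win <- matrix(as.integer(as.matrix(on_windows)), ncol = 2)
  if (nrow(win) > 0) {
    if (any(win[, 1] > win[, 2]) || any(win < 1) || any(win > n_frames)) {
      stop("on_windows must be within [1, n_frames] with start <= end")
    }
    ord <- order(win[, 1])
    win <- win[ord, , drop = FALSE]
    if (nrow(win) > 1 && any(win[-1, 1] <= win[-nrow(win), 2])) {
      stop("on_windows must be non-overlapping")
    }
  }
  n_chain <- 3L
  atoms <- data.frame(
    atom_id = integer(0), atom_name = character(0), element = character(0),
    residue_name = character(0), residue_id = integer(0), chain_id = character(0),
    category = character(0), stringsAsFactors = FALSE
  )
  add <- function(atoms, name, el, resname, resid, cat) {
    rbind(atoms, data.frame(
      atom_id = nrow(atoms) + 1L, atom_name = name, element = el,
      residue_name = resname, residue_id = resid, chain_id = "A",
      category = cat, stringsAsFactors = FALSE
    ))
  }
  atoms <- add(atoms, "CD", "C", "GLU", 309L, "protein")
  atoms <- add(atoms, "OE1", "O", "GLU", 309L, "protein")
  atoms <- add(atoms, "OE2", "O", "GLU", 309L, "protein")
  atoms <- add(atoms, "CG", "C", "ASN", 101L, "protein")
  atoms <- add(atoms, "OD1", "O", "ASN", 101L, "protein")
  atoms <- add(atoms, "ND2", "N", "ASN", 101L, "protein")
  chain_resid <- 1000L + seq_len(n_chain)
  for (r in chain_resid) atoms <- add(atoms, "O", "O", "HOH", r, "water")
  bulk_resid <- 2000L + seq_len(n_waters_bulk)
  for (r in bulk_resid) atoms <- add(atoms, "O", "O", "HOH", r, "water")
  topo <- md_topology(atoms)

  # geometry: source carboxyl oxygens near the origin, sink carboxamide at
  # z = 1.12 nm (= 4 x 0.28 nm), wire along +z
  base <- matrix(0, nrow(atoms), 3)
  base[1, ] <- c(0.10, 0, -0.10)   # CD
  base[2, ] <- c(0, 0, 0)          # OE1
  base[3, ] <- c(0.20, 0, 0)       # OE2
  base[4, ] <- c(0.10, 0, 1.22)    # CG
  base[5, ] <- c(0.20, 0, 1.12)    # OD1
  base[6, ] <- c(0, 0, 1.12)       # ND2
  chain_on <- cbind(0, 0, c(0.28, 0.56, 0.84))
  # rest grid: parked far from the axis with > 0.6 nm mutual spacing
  n_park <- n_chain + n_waters_bulk
  grid_side <- ceiling(sqrt(n_park))
  gx <- 3 + 0.7 * ((seq_len(n_park) - 1) %% grid_side)
  gy <- 0.7 * ((seq_len(n_park) - 1) %/% grid_side)
  park <- cbind(gx, gy, 0.5)
  .with_seed(seed, {
    jitter <- matrix(stats::runif(n_park * 3, -0.02, 0.02), n_park, 3)
    park <- park + jitter
    on_frame <- logical(n_frames)
    for (i in seq_len(nrow(win))) on_frame[win[i, 1]:win[i, 2]] <- TRUE
    coords <- array(NA_real_, dim = c(nrow(atoms), 3, n_frames))
    widx <- 7:(6 + n_park)
    for (f in seq_len(n_frames)) {
      xyz <- base
      xyz[widx, ] <- park
      if (on_frame[f]) xyz[7:(6 + n_chain), ] <- chain_on
      coords[, , f] <- xyz
    }
    traj <- md_trajectory(topo, coords, frame_interval = frame_interval)
    cfg <- wire_config(
      source_sel = select_atoms(topo, "resid 309 and name OE1 OE2"),
      sink_sel = select_atoms(topo, "resid 101 and name OD1 ND2"),
      max_bridging_waters = 4
    )
    colnames(win) <- c("start_frame", "end_frame")
    list(trajectory = traj, config = cfg, windows = as.data.frame(win),
         chain_residues = chain_resid)
  })
}

#' Multi-state conformational fixture for clustering
#'
#' A small rigid group of atoms whose frames occupy a few well-separated
#' states (whole-group translations chosen so that inter-state RMSD is
#' \code{separation}), plus isotropic per-atom noise. Emulates the distinct
#' spatial orientations a lipid headgroup samples in a binding site,
#' including a rare minority state.
#'
#' @param populations state probabilities (sum to 1), e.g.
#'   \code{c(0.45, 0.30, 0.18, 0.07)}.
#' @param separation pairwise inter-state RMSD floor, nm.
#' @param noise_sd per-atom isotropic noise, nm.
#' @param n_atoms atoms in the group.
#' @param n_frames frames.
#' @param seed RNG seed.
#' @return list: \code{trajectory}, \code{states} (planted per-frame state),
#'   \code{spec}.
#' @export
make_multistate_trajectory <- function(populations = c(0.45, 0.30, 0.18, 0.07),
                                       separation = 0.3, noise_sd = 0.005,
                                       n_atoms = 8, n_frames = 400, seed = 1) {
  if (abs(sum(populations) - 1) > 1e-9) stop("populations must sum to 1")
  k <- length(populations)
  # whole-group state offsets on orthogonal axes: pairwise distance
  # >= separation (axes pairs are separation * sqrt(2) apart)
  offsets <- rbind(c(0, 0, 0),
                   diag(3) * separation,
                   -diag(3) * separation)[seq_len(k), , drop = FALSE]
  .with_seed(seed, {
    base <- matrix(stats::rnorm(n_atoms * 3, sd = 0.3), n_atoms, 3)
    states <- sample.int(k, n_frames, replace = TRUE, prob = populations)
    coords <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      noise <- matrix(stats::rnorm(n_atoms * 3, sd = noise_sd), n_atoms, 3)
      coords[, , f] <- base + matrix(offsets[states[f], ], n_atoms, 3, byrow = TRUE) + noise
    }
    topo <- md_topology(data.frame(
      atom_id = seq_len(n_atoms), atom_name = "C1", element = "C",
      residue_name = "POPC", residue_id = 1L, chain_id = "L",
      category = "lipid", stringsAsFactors = FALSE
    ))
    traj <- md_trajectory(topo, coords, frame_interval = 20)
    list(trajectory = traj, states = states,
         spec = list(populations = populations, separation = separation,
                     noise_sd = noise_sd, n_atoms = n_atoms,
                     n_frames = n_frames, seed = seed))
  })
}

#' Small mixed-composition test structure
#'
#' Builds a toy system (a stretch of protein residues, one POPC headgroup
#' fragment, a set of waters) with deterministic geometry, useful for
#' exercising structure I/O and the selection language. Written/read through
#' the same PDB pathway the package uses for real structures.
#'
#' @param n_protein_residues alanine-like residues (N, CA, C, O per residue).
#' @param n_waters water count.
#' @param seed RNG seed for coordinate scatter.
#' @return list: \code{topology}, \code{frame}.
#' @export
make_test_structure <- function(n_protein_residues = 10, n_waters = 20, seed = 1) {
  atoms <- data.frame(
    atom_id = integer(0), atom_name = character(0), element = character(0),
    residue_name = character(0), residue_id = integer(0), chain_id = character(0),
    category = character(0), stringsAsFactors = FALSE
  )
  aid <- 0L
  for (r in seq_len(n_protein_residues)) {
    for (nm in c("N", "CA", "C", "O")) {
      aid <- aid + 1L
      atoms <- rbind(atoms, data.frame(
        atom_id = aid, atom_name = nm, element = substr(nm, 1, 1),
        residue_name = "ALA", residue_id = r, chain_id = "A",
        category = "protein", stringsAsFactors = FALSE
      ))
    }
  }
  lipid_resid <- n_protein_residues + 1L
  for (nm in c("N", "P", "C2")) {
    aid <- aid + 1L
    atoms <- rbind(atoms, data.frame(
      atom_id = aid, atom_name = nm, element = substr(nm, 1, 1),
      residue_name = "POPC", residue_id = lipid_resid, chain_id = "L",
      category = "lipid", stringsAsFactors = FALSE
    ))
  }
  for (w in seq_len(n_waters)) {
    aid <- aid + 1L
    atoms <- rbind(atoms, data.frame(
      atom_id = aid, atom_name = "O", element = "O",
      residue_name = "HOH", residue_id = lipid_resid + w, chain_id = "W",
      category = "water", stringsAsFactors = FALSE
    ))
  }
  topo <- md_topology(atoms)
  coords <- .with_seed(seed, matrix(stats::rnorm(aid * 3, sd = 1), aid, 3))
  list(topology = topo, frame = md_frame(round(coords, 3)))
}
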