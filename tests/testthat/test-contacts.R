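# Small two-group trajectory with controllable coordinates.
two_group_traj <- function(coords_list, box = NULL, names_a = c("OE1", "CB"),
                           resname_b = "POPC") {
  n <- nrow(coords_list[[1]])
  half <- n %/% 2
  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = c(rep(names_a, length.out = half), rep("P", n - half)),
    element = substr(c(rep(names_a, length.out = half), rep("P", n - half)), 1, 1),
    residue_name = c(rep("GLU", half), rep(resname_b, n - half)),
    residue_id = c(rep(1L, half), rep(2L, n - half)),
    chain_id = "A",
    category = c(rep("protein", half), rep("lipid", n - half)),
    stringsAsFactors = FALSE
  )
  topo <- md_topology(atoms)
  coords <- array(NA_real_, dim = c(n, 3, length(coords_list)))
  for (i in seq_along(coords_list)) coords[, , i] <- coords_list[[i]]
  bx <- if (is.null(box)) NULL else matrix(box, length(coords_list), 3, byrow = TRUE)
  md_trajectory(topo, coords, frame_interval = 20, box = bx)
}

test_that("named-atom distances and the minimum-image convention are exact", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0.5))
  atoms <- data.frame(atom_id = 1:2, atom_name = c("NE2", "P"), element = c("N", "P"),
                      residue_name = c("GLN", "POPC"), residue_id = 1:2,
                      chain_id = "A", category = c("protein", "lipid"),
                      stringsAsFactors = FALSE)
  topo <- md_topology(atoms)
  traj <- md_trajectory(topo, array(xyz, dim = c(2, 3, 3)), frame_interval = 20)
  ds <- distance_series(traj, select_atoms(topo, "name NE2"),
                        select_atoms(topo, "name P"), mode = "named-atom")
  expect_equal(ds$values, rep(0.5, 3))
  # 0.6 nm apart along z in a 1.0 nm periodic box -> minimum image 0.4 nm
  xyz2 <- rbind(c(0, 0, 0), c(0, 0, 0.6))
  trajp <- md_trajectory(topo, array(xyz2, dim = c(2, 3, 1)),
                         box = matrix(c(1, 1, 1), 1, 3))
  dp <- distance_series(trajp, select_atoms(topo, "name NE2"),
                        select_atoms(topo, "name P"), mode = "named-atom")
  expect_equal(dp$values, 0.4, tolerance = 1e-12)
  expect_error(distance_series(traj, select_atoms(topo, "category protein or category lipid"),
                               select_atoms(topo, "name P"), mode = "named-atom"),
               "cardinality")
})

test_that("min-heavy-atom distances equal the brute-force pairwise minimum", {
  set.seed(21)
  frames <- lapply(1:50, function(i) matrix(runif(12 * 3, 0, 2), 12, 3))
  traj <- two_group_traj(frames)
  selA <- select_atoms(traj$topology, "category protein")
  selB <- select_atoms(traj$topology, "category lipid")
  ds <- distance_series(traj, selA, selB, mode = "min-heavy-atom")
  for (f in 1:50) {
    expect_equal(ds$values[f],
                 brute_min_dist(frames[[f]], selA$indices, selB$indices),
                 tolerance = 1e-9)
  }
})

test_that("occupancy uses a closed interval and counts exactly", {
  oc <- occupancy(rep(0.5, 10), c(0, 0.5))
  expect_equal(oc$fraction, 1.0)  # boundary inclusive: R <= 0.5 holds at 0.5
  expect_equal(occupancy(c(0.1, 0.8), c(0.9, 1.0))$fraction, 0)
  expect_error(occupancy(numeric(0), c(0, 1)), "empty-input")
  # full axis occupancy is 1; disjoint partition fractions sum to 1
  p <- make_distance_process(n_frames = 2000, seed = 3)
  expect_equal(occupancy(p$values, c(0, Inf))$fraction, 1)
  cuts <- c(0, 0.4, 0.65, 0.75, Inf)
  parts <- vapply(seq_len(length(cuts) - 1), function(i) {
    v <- p$values
    sum(v >= cuts[i] & v < cuts[i + 1]) / length(v)
  }, numeric(1))
  expect_equal(sum(parts), 1, tolerance = 1e-12)
})

test_that("planted two-state occupancy is recovered within the binomial bound", {
  failures <- 0
  for (seed in 1:20) {
    p <- make_distance_process(state_means = c(0.5, 0.8), state_sigmas = c(0.03, 0.03),
                               transition_rate = 1, stationary_weights = c(0.6, 0.4),
                               n_frames = 10000, seed = seed)
    oc <- occupancy(p$values, c(0, 0.65))  # bracket state A
    if (abs(oc$fraction - 0.6) > 0.03) failures <- failures + 1
  }
  expect_lte(failures, 0)
})

test_that("histograms are density-normalized and resolve planted peaks", {
  h <- distance_histogram(rep(0.5, 1000), bin_width = 0.025)
  expect_equal(sum(h$densities > 0), 1)
  expect_equal(max(h$densities), 40, tolerance = 1e-9)  # 1 / 0.025
  p <- make_distance_process(state_means = c(0.5, 0.8), state_sigmas = c(0.03, 0.03),
                             transition_rate = 0.05, stationary_weights = c(0.5, 0.5),
                             n_frames = 20000, seed = 2)
  h2 <- distance_histogram(p$values, bin_width = 0.025)
  mids <- (h2$bin_edges[-1] + h2$bin_edges[-length(h2$bin_edges)]) / 2
  # local maxima within one bin of the planted peaks
  is_peak <- function(target) {
    k <- which.min(abs(mids - target))
    lo <- max(1, k - 1); hi <- min(length(mids), k + 1)
    any(vapply(lo:hi, function(j) {
      d <- h2$densities
      j > 1 && j < length(d) && d[j] >= d[j - 1] && d[j] >= d[j + 1]
    }, logical(1)))
  }
  expect_true(is_peak(0.5))
  expect_true(is_peak(0.8))
  expect_equal(sum(h2$densities * diff(h2$bin_edges)), 1, tolerance = 1e-9)
})

test_that("hydrogen-bond verdicts follow distance and angle criteria", {
  # donor O with collinear H at 0.28 nm from acceptor O -> satisfied
  mk <- function(d_oo, h_between = TRUE) {
    atoms <- data.frame(
      atom_id = 1:3,
      atom_name = c("OG1", "HG1", "O13"),
      element = c("O", "H", "O"),
      residue_name = c("THR", "THR", "POPC"),
      residue_id = c(316L, 316L, 400L),
      chain_id = "A",
      category = c("protein", "protein", "lipid"),
      stringsAsFactors = FALSE
    )
    topo <- md_topology(atoms)
    hx <- if (h_between) 0.1 else -0.1
    xyz <- rbind(c(0, 0, 0), c(hx, 0, 0), c(d_oo, 0, 0))
    md_trajectory(topo, array(xyz, dim = c(3, 3, 1)))
  }
  t1 <- mk(0.28)
  res <- hbond_occupancy(t1, select_atoms(t1$topology, "name OG1"),
                         select_atoms(t1$topology, "name O13"))
  expect_equal(res$fraction, 1)
  # 0.36 nm exceeds the 0.35 nm cutoff even with a perfect angle
  t2 <- mk(0.36)
  expect_equal(hbond_occupancy(t2, select_atoms(t2$topology, "name OG1"),
                               select_atoms(t2$topology, "name O13"))$fraction, 0)
  # hydrogen pointing away fails the angle criterion
  t3 <- mk(0.28, h_between = FALSE)
  expect_equal(hbond_occupancy(t3, select_atoms(t3$topology, "name OG1"),
                               select_atoms(t3$topology, "name O13"))$fraction, 0)
  # no hydrogens in the topology -> distance-only fallback, recorded
  ws <- make_wire_system(on_windows = rbind(c(1, 2)), n_frames = 2)
  r <- hbond_occupancy(ws$trajectory,
                       select_atoms(ws$trajectory$topology, "resid 309 and name OE1"),
                       select_atoms(ws$trajectory$topology, "resid 1001"))
  expect_match(r$criterion, "fallback")
  expect_equal(r$fraction, 1)
})

test_that("frame hydrogen-bond verdicts match brute-force pair evaluation", {
  set.seed(31)
  n_frames <- 200
  atoms <- data.frame(
    atom_id = 1:8,
    atom_name = c(rep("OD1", 4), rep("O13", 4)),
    element = "O",
    residue_name = c(rep("ASN", 4), rep("POPC", 4)),
    residue_id = c(rep(1L, 4), rep(2L, 4)),
    chain_id = "A", category = c(rep("protein", 4), rep("lipid", 4)),
    stringsAsFactors = FALSE
  )
  topo <- md_topology(atoms)
  coords <- array(runif(8 * 3 * n_frames, 0, 0.8), dim = c(8, 3, n_frames))
  traj <- md_trajectory(topo, coords)
  res <- hbond_occupancy(traj, select_atoms(topo, "resid 1"),
                         select_atoms(topo, "resid 2"), angle_min = NULL)
  brute <- vapply(seq_len(n_frames), function(f) {
    any(vapply(1:4, function(i) any(vapply(5:8, function(j) {
      sqrt(sum((coords[i, , f] - coords[j, , f])^2)) <= 0.35
    }, logical(1))), logical(1)))
  }, logical(1))
  expect_identical(res$per_frame, brute)
})

test_that("contact/RMSD correlation behaves at its extremes and under the null", {
  x <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  expect_equal(contact_rmsd_correlation(x, x)$r, 1.0)
  expect_equal(contact_rmsd_correlation(x, -x)$r, -1.0)
  set.seed(7)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(contact_rmsd_correlation(a, b)$r), 0.03)
  expect_error(contact_rmsd_correlation(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("crystal fragment distance machinery applies the shipped atom map", {
  frag <- read_structure(system.file("extdata", "e2_m2m4_fragment_synthetic.pdb",
                                     package = "sercatraj"))
  d <- frame_distance(frag$topology, frag$frame,
                      "resid 108 and name OE1 NE2", "resid 316 and name OG1")
  expect_equal(d, 0.65, tolerance = 0.01)
})
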