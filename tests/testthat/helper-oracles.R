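# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, exhaustive enumeration) and never call the code paths they
# check.

# Random topology of n atoms spread over a few residues/names, for selection
# set-algebra property tests.
random_topology <- function(n = 200, seed = 1) {
  set.seed(seed)
  data_names <- c("CA", "CB", "N", "O", "P")
  resnames <- c("ALA", "GLN", "POPC", "HOH", "K")
  rn <- sample(resnames, n, replace = TRUE)
  md_topology(data.frame(
    atom_id = seq_len(n),
    atom_name = sample(data_names, n, replace = TRUE),
    element = "C",
    residue_id = sample(1:40, n, replace = TRUE),
    residue_name = rn,
    chain_id = "A",
    category = categorize_residue(rn),
    stringsAsFactors = FALSE
  ))
}

# Brute-force per-atom evaluation of a single selection clause.
brute_clause <- function(topo, field, values) {
  at <- topo$atoms
  switch(field,
         resid = at$residue_id %in% as.integer(values),
         resname = at$residue_name %in% values,
         name = at$atom_name %in% values,
         category = at$category %in% values)
}

# Brute-force minimum heavy-atom distance between two index sets (no box).
brute_min_dist <- function(xyz, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# Exhaustive simple-path water-wire oracle: is there a path from any source
# atom to any sink atom through <= max_waters hydrogen-bonded waters?
# Recursive depth-first enumeration over water subsets, independent of the
# package's BFS.
brute_wire_present <- function(xyz, src, snk, waters, d_max, max_waters) {
  dist2 <- function(i, j) sum((xyz[i, ] - xyz[j, ])^2)
  dmax2 <- d_max^2
  # direct contact counts as a zero-water connection
  for (s in src) for (t in snk) if (dist2(s, t) <= dmax2) return(TRUE)
  reach_sink <- function(w) any(vapply(snk, function(t) dist2(w, t) <= dmax2, logical(1)))
  extend <- function(current, used, depth) {
    if (reach_sink(current)) return(TRUE)
    if (depth >= max_waters) return(FALSE)
    for (w in setdiff(waters, used)) {
      if (dist2(current, w) <= dmax2 &&
          extend(w, c(used, w), depth + 1)) return(TRUE)
    }
    FALSE
  }
  for (w in waters) {
    if (any(vapply(src, function(s) dist2(s, w) <= dmax2, logical(1))) &&
        extend(w, w, 1)) return(TRUE)
  }
  FALSE
}

# Random wire-search scene: a couple of endpoint atoms and up to n_waters
# waters scattered in a box, as a one-frame trajectory plus a wire_config.
random_wire_scene <- function(n_waters, seed, box_side = 1.5) {
  set.seed(seed)
  n_atoms <- 4 + n_waters
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    atom_name = c("OE1", "OE2", "OD1", "ND2", rep("O", n_waters)),
    element = c("O", "O", "O", "N", rep("O", n_waters)),
    residue_name = c("GLU", "GLU", "ASN", "ASN", rep("HOH", n_waters)),
    residue_id = c(309L, 309L, 101L, 101L, 500L + seq_len(n_waters)),
    chain_id = "A",
    category = c(rep("protein", 4), rep("water", n_waters)),
    stringsAsFactors = FALSE
  )
  topo <- md_topology(atoms)
  xyz <- matrix(runif(n_atoms * 3, 0, box_side), n_atoms, 3)
  list(topology = topo, xyz = xyz,
       src = 1:2, snk = 3:4, waters = if (n_waters > 0) 5:n_atoms else integer(0))
}

# Apply a random rigid-body transform (proper rotation + translation).
rigid_transform <- function(xyz, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(xyz %*% Q, 2, runif(3, -2, 2), "+")
}
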