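test_that("hbond graph reproduces the planted chain and isolates decoys", {
  ws <- make_wire_system(on_windows = rbind(c(1, 3)), n_frames = 4,
                         n_waters_bulk = 5, seed = 2)
  topo <- ws$trajectory$topology
  cfg <- ws$config
  g_on <- hbond_graph(get_frame(ws$trajectory, 2), topo, cfg)
  chain_nodes <- which(topo$atoms$residue_id[g_on$nodes] %in% ws$chain_residues)
  src_nodes <- which(g_on$node_type == "source")
  snk_nodes <- which(g_on$node_type == "sink")
  # path graph source -- w1 -- w2 -- w3 -- sink: 4 successive links
  expect_true(any(g_on$adjacency[src_nodes, chain_nodes[1]]))
  expect_true(g_on$adjacency[chain_nodes[1], chain_nodes[2]])
  expect_true(g_on$adjacency[chain_nodes[2], chain_nodes[3]])
  expect_true(any(g_on$adjacency[chain_nodes[3], snk_nodes]))
  expect_false(g_on$adjacency[chain_nodes[1], chain_nodes[3]])
  # off frame with the cylinder filter disabled: every water is isolated
  cfg_all <- wire_config(cfg$source_sel, cfg$sink_sel, cylinder_radius = Inf)
  g_off <- hbond_graph(get_frame(ws$trajectory, 4), topo, cfg_all)
  w <- which(g_off$node_type == "water")
  expect_equal(sum(g_off$adjacency[w, ]), 0)
})

test_that("graph edges match brute-force all-pairs evaluation on random frames", {
  for (seed in 1:10) {
    sc <- random_wire_scene(12, seed = seed)
    traj <- md_trajectory(sc$topology, array(sc$xyz, dim = c(nrow(sc$xyz), 3, 1)))
    cfg <- wire_config(select_atoms(sc$topology, "resid 309"),
                       select_atoms(sc$topology, "resid 101"),
                       cylinder_radius = Inf)
    g <- hbond_graph(get_frame(traj, 1), sc$topology, cfg)
    n <- length(g$nodes)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      same_site <- g$node_type[i] == g$node_type[j] && g$node_type[i] != "water"
      want <- !same_site &&
        sqrt(sum((sc$xyz[g$nodes[i], ] - sc$xyz[g$nodes[j], ])^2)) <= 0.35
      expect_identical(unname(g$adjacency[i, j]), want)
    }
  }
})

test_that("wire presence matches the planted schedule and the bridging bound", {
  ws <- make_wire_system(on_windows = rbind(c(3, 8)), n_frames = 12, seed = 1)
  topo <- ws$trajectory$topology
  res_on <- wire_present(get_frame(ws$trajectory, 5), topo, ws$config)
  expect_false(is.null(res_on))
  expect_equal(res_on$n_waters, 3)
  expect_identical(res_on$water_residues, ws$chain_residues)
  expect_null(wire_present(get_frame(ws$trajectory, 1), topo, ws$config))
  # a 5-water chain needs max_bridging_waters >= 5
  n <- 9
  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = c("OE1", "OE2", "OD1", "ND2", rep("O", 5)),
    element = c("O", "O", "O", "N", rep("O", 5)),
    residue_name = c("GLU", "GLU", "ASN", "ASN", rep("HOH", 5)),
    residue_id = c(309L, 309L, 101L, 101L, 501:505),
    chain_id = "A",
    category = c(rep("protein", 4), rep("water", 5)),
    stringsAsFactors = FALSE)
  topo5 <- md_topology(atoms)
  z <- c(0, -0.1, 1.68, 1.78, 0.28, 0.56, 0.84, 1.12, 1.40)
  xyz <- cbind(0, 0, z)
  traj5 <- md_trajectory(topo5, array(xyz, dim = c(n, 3, 1)))
  mk_cfg <- function(k) wire_config(select_atoms(topo5, "resid 309"),
                                    select_atoms(topo5, "resid 101"),
                                    max_bridging_waters = k,
                                    cylinder_radius = Inf)
  expect_null(wire_present(get_frame(traj5, 1), topo5, mk_cfg(4)))
  res5 <- wire_present(get_frame(traj5, 1), topo5, mk_cfg(5))
  expect_false(is.null(res5))
  expect_equal(res5$n_waters, 5)
})

test_that("wire presence equals exhaustive simple-path enumeration", {
  mismatches <- 0
  for (seed in 1:200) {
    sc <- random_wire_scene(sample(3:15, 1), seed = seed)
    traj <- md_trajectory(sc$topology, array(sc$xyz, dim = c(nrow(sc$xyz), 3, 1)))
    cfg <- wire_config(select_atoms(sc$topology, "resid 309"),
                       select_atoms(sc$topology, "resid 101"),
                       max_bridging_waters = 4, cylinder_radius = Inf)
    got <- !is.null(wire_present(get_frame(traj, 1), sc$topology, cfg))
    want <- brute_wire_present(sc$xyz, sc$src, sc$snk, sc$waters,
                               d_max = 0.35, max_waters = 4)
    if (got != want) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("event segmentation and gap merging follow the declared rule", {
  ws <- make_wire_system(on_windows = rbind(c(3, 8)), n_frames = 20,
                         frame_interval = 20, seed = 1)
  ev <- detect_events(ws$trajectory, ws$config)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$lifetime_ps, 120)  # 6 frames x 20 ps
  # two 3-frame windows separated by one off frame
  ws2 <- make_wire_system(on_windows = rbind(c(5, 7), c(9, 11)), n_frames = 20,
                          frame_interval = 20, seed = 1)
  ev0 <- detect_events(ws2$trajectory, ws2$config)
  expect_equal(nrow(ev0$events), 2)
  expect_equal(ev0$events$lifetime_ps, c(60, 60))
  cfg_merge <- ws2$config
  cfg_merge$gap_merge_frames <- 1
  ev1 <- detect_events(ws2$trajectory, cfg_merge)
  expect_equal(nrow(ev1$events), 1)
  expect_equal(ev1$events$start_frame, 5)
  expect_equal(ev1$events$end_frame, 11)
  expect_equal(ev1$events$lifetime_ps, 140)  # 7 frames spanned
  # empty schedule
  ws3 <- make_wire_system(n_frames = 10, seed = 1)
  expect_equal(nrow(detect_events(ws3$trajectory, ws3$config)$events), 0)
})

test_that("event spans conserve present-frame counts and survive relabeling", {
  ws <- make_wire_system(on_windows = rbind(c(2, 4), c(8, 8), c(12, 15)),
                         n_frames = 18, seed = 5)
  ev <- detect_events(ws$trajectory, ws$config)
  expect_equal(sum(ev$events$n_frames), sum(ev$per_frame))
  # relabel water residue ids: verdicts must not change
  topo <- ws$trajectory$topology
  at <- topo$atoms
  wmask <- at$category == "water"
  at$residue_id[wmask] <- rev(at$residue_id[wmask])
  topo2 <- md_topology(at)
  traj2 <- md_trajectory(topo2, ws$trajectory$coords, frame_interval = 20)
  cfg2 <- wire_config(select_atoms(topo2, "resid 309 and name OE1 OE2"),
                      select_atoms(topo2, "resid 101 and name OD1 ND2"))
  ev2 <- detect_events(traj2, cfg2)
  expect_identical(ev2$per_frame, ev$per_frame)
  expect_equal(ev2$events[c("start_frame", "end_frame", "n_frames", "lifetime_ps")],
               ev$events[c("start_frame", "end_frame", "n_frames", "lifetime_ps")])
})

test_that("raising the search bounds never loses a present frame", {
  for (seed in 1:30) {
    sc <- random_wire_scene(10, seed = 1000 + seed)
    traj <- md_trajectory(sc$topology, array(sc$xyz, dim = c(nrow(sc$xyz), 3, 1)))
    mk <- function(k, d) wire_config(select_atoms(sc$topology, "resid 309"),
                                     select_atoms(sc$topology, "resid 101"),
                                     max_bridging_waters = k, d_max = d,
                                     cylinder_radius = Inf)
    base_hit <- !is.null(wire_present(get_frame(traj, 1), sc$topology, mk(2, 0.35)))
    if (base_hit) {
      expect_false(is.null(wire_present(get_frame(traj, 1), sc$topology, mk(4, 0.35))))
      expect_false(is.null(wire_present(get_frame(traj, 1), sc$topology, mk(2, 0.45))))
    }
  }
})

test_that("lifetime statistics summarize planted schedules", {
  ev <- data.frame(start_frame = c(1L, 10L), end_frame = c(5L, 16L))
  st <- lifetime_stats(ev, frame_interval = 20)
  expect_equal(st$count, 2)
  expect_equal(st$mean_ps, 120)  # (100 + 140) / 2
  expect_equal(st$min_ps, 100)
  expect_equal(st$max_ps, 140)
  empty <- lifetime_stats(data.frame(start_frame = integer(0), end_frame = integer(0)),
                          frame_interval = 20)
  expect_equal(empty$count, 0)
  # planted lifetimes drawn from [100, 150] ps recovered inside the range
  set.seed(77)
  lens <- sample(5:7, 4, replace = TRUE)     # 100-140 ps at 20 ps/frame
  starts <- cumsum(c(2, lens[-4] + 3))
  wins <- cbind(starts, starts + lens - 1)
  ws <- make_wire_system(on_windows = wins, n_frames = max(wins) + 2,
                         frame_interval = 20, seed = 9)
  st2 <- lifetime_stats(detect_events(ws$trajectory, ws$config))
  expect_equal(st2$count, 4)
  expect_gte(st2$min_ps, 100)
  expect_lte(st2$max_ps, 150)
})
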