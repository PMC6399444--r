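# Hydrogen-bonded water-wire detection: per-frame graph construction, BFS
# path search, event segmentation and lifetime statistics.

#' Configuration for water-wire detection
#'
#' Describes one proton-release pathway: a buried source site (e.g. the
#' carboxyl oxygens of Glu309), a sink site (e.g. the carboxamide atoms of
#' Asn101, or for the C-terminal pathway the Asp800/Glu908 carboxylates), and
#' the geometric criteria under which waters count as hydrogen-bonded
#' bridges.
#'
#' @param source_sel,sink_sel [select_atoms()] results for the endpoint heavy
#'   atoms.
#' @param water_sel selection of water oxygen atoms considered as bridges;
#'   \code{NULL} selects all water-category oxygen atoms.
#' @param max_bridging_waters maximum waters allowed in a path (>= 1).
#' @param d_max H-bond donor--acceptor heavy-atom cutoff, nm.
#' @param gap_merge_frames events separated by at most this many wire-absent
#'   frames are merged (0 = maximal uninterrupted runs).
#' @param cylinder_radius candidate waters are pre-filtered to a cylinder of
#'   this radius (nm) around the source-to-sink axis; \code{Inf} disables the
#'   filter.
#' @return object of class \code{wire_config}.
#' @export
wire_config <- function(source_sel, sink_sel, water_sel = NULL,
                        max_bridging_waters = 4, d_max = 0.35,
                        gap_merge_frames = 0, cylinder_radius = 0.8) {
  if (max_bridging_waters < 1) stop("max_bridging_waters must be >= 1")
  if (gap_merge_frames < 0) stop("gap_merge_frames must be >= 0")
  structure(list(source_sel = source_sel, sink_sel = sink_sel,
                 water_sel = water_sel, max_bridging_waters = max_bridging_waters,
                 d_max = d_max, gap_merge_frames = gap_merge_frames,
                 cylinder_radius = cylinder_radius),
            class = "wire_config")
}

# Water oxygen atom indices for a config against a topology.
.wire_waters <- function(topology, config) {
  if (!is.null(config$water_sel)) {
    idx <- .as_indices(config$water_sel, nrow(topology$atoms))
  } else {
    at <- topology$atoms
    idx <- which(at$category == "water" & at$element == "O")
  }
  if (length(idx) == 0) stop("selection error: no water oxygens available")
  idx
}

# Restrict water indices to a cylinder around the source->sink axis.
.cylinder_filter <- function(xyz, waters, src, snk, radius) {
  if (!is.finite(radius)) return(waters)
  a <- colMeans(xyz[src, , drop = FALSE])
  b <- colMeans(xyz[snk, , drop = FALSE])
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(waters)
  w <- xyz[waters, , drop = FALSE]
  rel <- sweep(w, 2, a)
  t_par <- (rel %*% ab) / len2
  # allow a margin of one H-bond length beyond each endpoint along the axis
  margin <- 0.35 / sqrt(len2)
  perp <- rel - (t_par %*% t(ab))
  keep <- t_par >= -margin & t_par <= 1 + margin & sqrt(rowSums(perp^2)) <= radius
  waters[as.vector(keep)]
}

#' Hydrogen-bond adjacency of waters and endpoint atoms in one frame
#'
#' Builds the undirected graph whose nodes are candidate water oxygens plus
#' the source and sink endpoint atoms, with an edge whenever the
#' heavy-atom distance criterion holds (distance-only; topologies without
#' hydrogens are the norm for this geometric wire definition).
#'
#' @param frame an [md_frame()].
#' @param topology the matching [md_topology()].
#' @param config a [wire_config()].
#' @return list: \code{nodes} (atom indices: waters, then source, then sink
#'   atoms), \code{node_type} (\code{"water"}/\code{"source"}/\code{"sink"}),
#'   \code{adjacency} (logical matrix).
#' @export
hbond_graph <- function(frame, topology, config) {
  stopifnot(inherits(frame, "md_frame"), inherits(config, "wire_config"))
  xyz <- frame$coords
  n <- nrow(topology$atoms)
  src <- .as_indices(config$source_sel, n)
  snk <- .as_indices(config$sink_sel, n)
  waters <- .wire_waters(topology, config)
  waters <- .cylinder_filter(xyz, waters, src, snk, config$cylinder_radius)
  nodes <- c(waters, src, snk)
  node_type <- c(rep("water", length(waters)),
                 rep("source", length(src)), rep("sink", length(snk)))
  coords <- xyz[nodes, , drop = FALSE]
  d <- .pair_dists(coords, coords, frame$box)
  adj <- d <= config$d_max
  diag(adj) <- FALSE
  # endpoints of the same site are not bridges for one another
  same_src <- node_type == "source"
  same_snk <- node_type == "sink"
  adj[same_src, same_src] <- FALSE
  adj[same_snk, same_snk] <- FALSE
  list(nodes = nodes, node_type = node_type, adjacency = adj)
}

#' Is a water wire present in one frame?
#'
#' Breadth-first search from the source atoms to the sink atoms through at
#' most \code{max_bridging_waters} hydrogen-bonded water nodes, with
#' deterministic node ordering by atom index. Only path existence matters
#' for the per-frame wire/no-wire call; the returned path is the first
#' shortest one found.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [md_topology()].
#' @param config a [wire_config()].
#' @return \code{NULL} when absent; otherwise a list with
#'   \code{water_atoms} (atom indices of the bridging waters, in path order),
#'   \code{water_residues} (their residue ids) and \code{n_waters}.
#' @export
wire_present <- function(frame, topology, config) {
  g <- hbond_graph(frame, topology, config)
  is_water <- g$node_type == "water"
  is_src <- g$node_type == "source"
  is_snk <- g$node_type == "sink"
  # direct source-sink hydrogen bond: connected with zero waters
  if (any(g$adjacency[is_src, is_snk])) {
    return(list(water_atoms = integer(0), water_residues = integer(0), n_waters = 0L))
  }
  nw <- sum(is_water)
  if (nw == 0) return(NULL)
  widx <- which(is_water)
  widx <- widx[order(g$nodes[widx])]  # deterministic expansion order
  depth <- rep(NA_integer_, length(g$nodes))
  parent <- rep(NA_integer_, length(g$nodes))
  frontier <- integer(0)
  for (w in widx) {
    if (any(g$adjacency[w, is_src])) {
      depth[w] <- 1L
      frontier <- c(frontier, w)
    }
  }
  d <- 1L
  while (length(frontier) > 0) {
    hit <- frontier[vapply(frontier, function(w) any(g$adjacency[w, is_snk]), logical(1))]
    if (length(hit) > 0) {
      node <- hit[1]
      path <- node
      while (!is.na(parent[node])) { node <- parent[node]; path <- c(node, path) }
      atoms <- g$nodes[path]
      return(list(water_atoms = atoms,
                  water_residues = topology$atoms$residue_id[atoms],
                  n_waters = length(atoms)))
    }
    if (d >= config$max_bridging_waters) break
    nxt <- integer(0)
    for (w in frontier) {
      nb <- widx[g$adjacency[w, widx] & is.na(depth[widx])]
      for (v in nb) {
        depth[v] <- d + 1L
        parent[v] <- w
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt[order(g$nodes[nxt])]
    d <- d + 1L
  }
  NULL
}

#' Detect water-wire events over a trajectory
#'
#' Evaluates the per-frame wire/no-wire call, forms maximal runs of
#' wire-present frames, merges runs separated by at most
#' \code{gap_merge_frames} absent frames, and reports each event with its
#' inclusive frame span and lifetime.
#'
#' @param traj an [md_trajectory()] (its \code{frame_interval}, ps, sets the
#'   lifetime scale; defaults to the spacing of \code{times}).
#' @param config a [wire_config()].
#' @return object of class \code{wire_events}: data.frame \code{events}
#'   (\code{start_frame}, \code{end_frame}, \code{n_frames},
#'   \code{lifetime_ps}, \code{example_path}), plus \code{per_frame}
#'   (logical) and \code{frame_interval}.
#' @export
detect_events <- function(traj, config) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(config, "wire_config"))
  nf <- n_frames(traj)
  present <- logical(nf)
  paths <- vector("list", nf)
  for (f in seq_len(nf)) {
    res <- wire_present(get_frame(traj, f), traj$topology, config)
    present[f] <- !is.null(res)
    paths[[f]] <- res
  }
  fi <- traj$frame_interval
  if (is.null(fi)) {
    fi <- if (nf > 1) mean(diff(traj$times)) * 1000 else 1
  }
  events <- .segment_runs(present, config$gap_merge_frames)
  if (nrow(events) > 0) {
    events$lifetime_ps <- events$n_frames * fi
    events$example_path <- vapply(seq_len(nrow(events)), function(i) {
      f0 <- events$start_frame[i]
      while (is.null(paths[[f0]]) && f0 <= events$end_frame[i]) f0 <- f0 + 1L
      paste(paths[[f0]]$water_residues, collapse = ",")
    }, character(1))
  } else {
    events$lifetime_ps <- numeric(0)
    events$example_path <- character(0)
  }
  structure(list(events = events, per_frame = present, frame_interval = fi),
            class = "wire_events")
}

# Maximal runs of TRUE, merging runs separated by <= gap FALSE frames.
.segment_runs <- function(present, gap) {
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_frame = starts[r$values], end_frame = ends[r$values])
  if (nrow(runs) > 1 && gap > 0) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      sep <- runs$start_frame[i] - merged$end_frame[nrow(merged)] - 1L
      if (sep <= gap) {
        merged$end_frame[nrow(merged)] <- runs$end_frame[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs$n_frames <- runs$end_frame - runs$start_frame + 1L
  runs
}

#' @export
print.wire_events <- function(x, ...) {
  cat(sprintf("wire_events: %d event(s) over %d frames (%g ps/frame)\n",
              nrow(x$events), length(x$per_frame), x$frame_interval))
  if (nrow(x$events) > 0) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Summary statistics of wire-event lifetimes
#'
#' @param events a [detect_events()] result or its \code{events} data.frame.
#' @param frame_interval ps per frame; only needed when \code{events} lacks a
#'   \code{lifetime_ps} column.
#' @return list: \code{count}, \code{mean_ps}, \code{min_ps}, \code{max_ps}
#'   (the latter three \code{NA} when count is 0).
#' @export
lifetime_stats <- function(events, frame_interval = NULL) {
  ev <- if (inherits(events, "wire_events")) events$events else events
  if (!"lifetime_ps" %in% names(ev)) {
    if (is.null(frame_interval) || frame_interval <= 0) {
      stop("frame_interval (> 0, ps) required to compute lifetimes")
    }
    ev$lifetime_ps <- (ev$end_frame - ev$start_frame + 1) * frame_interval
  }
  if (nrow(ev) == 0) {
    return(list(count = 0L, mean_ps = NA_real_, min_ps = NA_real_, max_ps = NA_real_))
  }
  list(count = nrow(ev), mean_ps = mean(ev$lifetime_ps),
       min_ps = min(ev$lifetime_ps), max_ps = max(ev$lifetime_ps))
}
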