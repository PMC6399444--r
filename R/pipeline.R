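# Config-driven orchestration: run the full comparative analysis battery
# (contacts, structure metrics, essential dynamics, water wires) on one or
# two trajectories and emit TSV tables plus a JSON summary.

#' Load and validate an analysis configuration
#'
#' The configuration is a YAML tree with the structure file, one or more
#' trajectories, and one block per analysis; see the package vignette for a
#' worked example. Validation parses every selection expression against the
#' topology and checks thresholds before any computation runs, so a typo'd
#' segment label (say \code{"M11"}) fails fast.
#'
#' @param path YAML configuration file.
#' @return object of class \code{analysis_config} (the parsed tree plus the
#'   resolved topology and reference frame).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  validate_analysis_config(cfg)
}

#' @rdname read_analysis_config
#' @param cfg a raw configuration list (as parsed from YAML).
#' @export
validate_analysis_config <- function(cfg) {
  base <- if (!is.null(cfg$config_path)) dirname(cfg$config_path) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (is.null(cfg$structure)) stop("config error: 'structure' (PDB path) is required")
  segments <- list()
  if (!is.null(cfg$segments)) segments <- read_segment_map(resolve(cfg$segments))
  st <- read_structure(resolve(cfg$structure), segments = segments)
  if (is.null(cfg$trajectories) || length(cfg$trajectories) == 0) {
    stop("config error: at least one trajectory is required")
  }
  check_sel <- function(expr, where) {
    tryCatch(select_atoms(st$topology, expr),
             error = function(e) stop("config error in ", where, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  for (d in cfg$distances) {
    check_sel(d$selA, paste0("distances/", d$label))
    check_sel(d$selB, paste0("distances/", d$label))
    if (!is.null(d$thresholds) && any(unlist(d$thresholds) <= 0)) {
      stop("config error: thresholds must be positive in distances/", d$label)
    }
  }
  for (h in cfg$hbonds) {
    check_sel(h$donor, paste0("hbonds/", h$label))
    check_sel(h$acceptor, paste0("hbonds/", h$label))
  }
  if (!is.null(cfg$rmsd_profile)) {
    check_sel(cfg$rmsd_profile$fit, "rmsd_profile/fit")
    for (s in cfg$rmsd_profile$segments) {
      if (!s %in% names(st$topology$segments)) {
        stop("config error: undefined segment '", s, "' in rmsd_profile")
      }
    }
  }
  if (!is.null(cfg$rmsd_timeseries)) check_sel(cfg$rmsd_timeseries$fit, "rmsd_timeseries/fit")
  if (!is.null(cfg$clustering)) check_sel(cfg$clustering$sel, "clustering/sel")
  if (!is.null(cfg$pca)) {
    check_sel(cfg$pca$sel, "pca/sel")
    if (!is.null(cfg$pca$fit)) check_sel(cfg$pca$fit, "pca/fit")
  }
  for (w in cfg$wires) {
    check_sel(w$source, paste0("wires/", w$label))
    check_sel(w$sink, paste0("wires/", w$label))
  }
  cfg$topology <- st$topology
  cfg$reference <- st$frame
  cfg$resolve <- resolve
  structure(cfg, class = "analysis_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Analyses for one trajectory; returns the summary sub-tree and writes TSVs.
.run_one <- function(cfg, name, traj, out_dir) {
  topo <- cfg$topology
  ref <- cfg$reference
  summary <- list()
  tag <- function(x) file.path(out_dir, paste0(name, "_", x))

  if (!is.null(cfg$distances)) {
    occ_rows <- list()
    for (d in cfg$distances) {
      ds <- distance_series(traj,
                            select_atoms(topo, d$selA), select_atoms(topo, d$selB),
                            mode = if (is.null(d$mode)) "min-heavy-atom" else d$mode,
                            pair_label = d$label,
                            reference_value = d$reference)
      .write_tsv(data.frame(frame = seq_along(ds$values), time_ns = ds$times,
                            R_nm = ds$values),
                 tag(paste0("distance_", d$label, ".tsv")))
      h <- distance_histogram(ds, bin_width = if (is.null(d$bin_width)) 0.025 else d$bin_width)
      .write_tsv(data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
                            bin_hi = h$bin_edges[-1], density = h$densities),
                 tag(paste0("hist_", d$label, ".tsv")))
      for (thr in d$thresholds) {
        oc <- occupancy(ds, c(0, thr))
        occ_rows[[length(occ_rows) + 1]] <- data.frame(
          pair = d$label, threshold_nm = thr, fraction = oc$fraction,
          crystal_reference_nm = ifelse(is.null(d$reference), NA, d$reference))
      }
    }
    if (length(occ_rows) > 0) {
      occ_tab <- do.call(rbind, occ_rows)
      .write_tsv(occ_tab, tag("occupancies.tsv"))
      summary$occupancies <- occ_tab
    }
  }

  if (!is.null(cfg$hbonds)) {
    hb_rows <- lapply(cfg$hbonds, function(h) {
      res <- hbond_occupancy(traj, select_atoms(topo, h$donor),
                             select_atoms(topo, h$acceptor),
                             d_max = if (is.null(h$d_max)) 0.35 else h$d_max,
                             angle_min = if (is.null(h$angle_min)) 150 else h$angle_min)
      data.frame(label = h$label, fraction = res$fraction, criterion = res$criterion)
    })
    hb_tab <- do.call(rbind, hb_rows)
    .write_tsv(hb_tab, tag("hbond_occupancies.tsv"))
    summary$hbond_occupancies <- hb_tab
  }

  if (!is.null(cfg$rmsd_profile)) {
    rp <- cfg$rmsd_profile
    prof <- segment_rmsd_profile(traj, ref, unlist(rp$segments),
                                 select_atoms(topo, rp$fit),
                                 measure_expr = if (is.null(rp$measure_expr))
                                   "segment %s" else rp$measure_expr)
    .write_tsv(prof, tag("segment_rmsd.tsv"))
    summary$segment_rmsd <- prof
  }

  if (!is.null(cfg$rmsd_timeseries)) {
    sel <- select_atoms(topo, cfg$rmsd_timeseries$fit)
    rts <- rmsd_timeseries(traj, ref, sel)
    .write_tsv(data.frame(frame = seq_along(rts), time_ns = traj$times, rmsd_nm = rts),
               tag("rmsd_timeseries.tsv"))
    summary$rmsd_timeseries_mean <- mean(rts)
  }

  if (!is.null(cfg$clustering)) {
    cl <- cluster_conformations(traj, select_atoms(topo, cfg$clustering$sel),
                                cutoff = if (is.null(cfg$clustering$cutoff)) 0.1
                                         else cfg$clustering$cutoff)
    .write_tsv(cl$clusters, tag("clusters.tsv"))
    summary$clusters <- cl$clusters
    for (i in seq_len(nrow(cl$clusters))) {
      write_structure(topo, get_frame(traj, cl$clusters$representative[i]),
                      tag(sprintf("cluster%d_representative.pdb", i)))
    }
  }

  model <- NULL
  if (!is.null(cfg$pca)) {
    p <- cfg$pca
    fit_ref <- if (is.null(p$fit)) NULL else ref
    fit_sel <- if (is.null(p$fit)) NULL else select_atoms(topo, p$fit)
    model <- fit_pca(traj, select_atoms(topo, p$sel), fit_ref, fit_sel)
    nc <- if (is.null(p$n_components)) 10 else p$n_components
    curve <- variance_accounting(model)
    class_tab <- data.frame(component = seq_len(nc),
                            eigenvalue = model$eigenvalues[seq_len(nc)],
                            cumulative_variance = curve[seq_len(nc)],
                            r_squared = NA_real_, classification = NA_character_)
    for (k in seq_len(nc)) {
      gf <- classify_gaussianity(project_component(traj, model, k))
      class_tab$r_squared[k] <- gf$r_squared
      class_tab$classification[k] <- gf$classification
    }
    .write_tsv(class_tab, tag("pca_components.tsv"))
    summary$pca <- list(
      components = class_tab,
      components_needed = lapply(
        stats::setNames(p$variance_fractions,
                        paste0("fraction_", p$variance_fractions)),
        function(fr) components_needed(model, fr))
    )
  }

  if (!is.null(cfg$wires)) {
    wire_rows <- list()
    for (w in cfg$wires) {
      wc <- wire_config(select_atoms(topo, w$source), select_atoms(topo, w$sink),
                        max_bridging_waters = if (is.null(w$max_bridging_waters)) 4
                                              else w$max_bridging_waters,
                        d_max = if (is.null(w$d_max)) 0.35 else w$d_max,
                        gap_merge_frames = if (is.null(w$gap_merge_frames)) 0
                                           else w$gap_merge_frames)
      ev <- detect_events(traj, wc)
      .write_tsv(ev$events, tag(paste0("wires_", w$label, ".tsv")))
      st <- lifetime_stats(ev)
      wire_rows[[w$label]] <- st
    }
    summary$wires <- wire_rows
  }

  list(summary = summary, model = model)
}

#' Run the full comparative analysis battery
#'
#' Executes every configured analysis on each trajectory, writes per-analysis
#' TSV tables, representative-structure PDBs, a machine-readable
#' \code{summary.json} and a run log (package version, seed, config hash, the
#' H-bond criterion actually applied). When two trajectories and a PCA block
#' are configured, the inner-product matrix between their component sets is
#' included -- the core comparative device for deciding whether two
#' simulations share an essential subspace.
#'
#' @param config an [read_analysis_config()] result or a YAML path.
#' @return the summary list, invisibly; side effect: files under the
#'   configured \code{output_dir}.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- if (is.null(config$output_dir)) "analysis_out" else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  trajs <- list()
  for (name in names(config$trajectories)) {
    t_cfg <- config$trajectories[[name]]
    trajs[[name]] <- read_trajectory(config$resolve(t_cfg$path), config$topology,
                                     frame_interval = t_cfg$frame_interval)
  }
  summary <- list(trajectories = list())
  models <- list()
  for (name in names(trajs)) {
    res <- tryCatch(.run_one(config, name, trajs[[name]], out_dir),
                    error = function(e) {
                      stop("stage failure for trajectory '", name, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
    summary$trajectories[[name]] <- res$summary
    models[[name]] <- res$model
  }
  if (length(models) >= 2 && !is.null(models[[1]]) && !is.null(models[[2]])) {
    k <- if (is.null(config$pca$inner_product_k)) 10 else config$pca$inner_product_k
    M <- inner_products(models[[1]], models[[2]], k)
    .write_tsv(as.data.frame(M), file.path(out_dir, "inner_products.tsv"))
    summary$inner_products <- unname(as.matrix(M))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  log_lines <- c(
    sprintf("sercatraj version: %s", as.character(utils::packageVersion("sercatraj"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("config: %s (md5 %s)", config$config_path,
            if (!is.null(config$config_path)) unname(tools::md5sum(config$config_path)) else "n/a"),
    sprintf("hbond criteria: %s",
            paste(vapply(config$hbonds, function(h)
              sprintf("%s d_max=%g angle_min=%g", h$label,
                      if (is.null(h$d_max)) 0.35 else h$d_max,
                      if (is.null(h$angle_min)) 150 else h$angle_min), character(1)),
              collapse = "; "))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
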