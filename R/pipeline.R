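# End-to-end orchestration: recording -> filtering -> lift segments ->
# MI network -> threshold -> topology -> importance -> key nodes ->
# directed network -> sensor selection -> feature table -> clustering.

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Movement feature table from key-node networks
#'
#' One row per movement condition with the three network features used to
#' compare movements: clustering coefficient `C`, average degree `<k>`,
#' and average path length `L`. For a disconnected key-node network the
#' path length is computed on the largest component and the row is marked
#' (`connected = FALSE`).
#'
#' @param nets named list of `binary_net` objects, one per condition.
#' @return A data frame with columns `condition`, `C`, `k_avg`, `l_path`,
#'   `connected`.
#' @export
movement_feature_table <- function(nets) {
  if (is.null(names(nets))) names(nets) <- paste0("condition", seq_along(nets))
  out <- do.call(rbind, lapply(names(nets), function(cond) {
    net <- nets[[cond]]
    stopifnot(inherits(net, "binary_net"))
    cl <- clustering_coefficient(net)
    connected <- is_connected_adj(net$adj)
    l_path <- if (connected) {
      if (net$n > 1) avg_path_length(net) else 0
    } else {
      comp <- graph_components(net$adj)
      giant <- which.max(tabulate(comp))
      sub <- net$adj[comp == giant, comp == giant, drop = FALSE]
      if (ncol(sub) > 1) {
        avg_path_length(binary_net(sub))
      } else {
        NA_real_
      }
    }
    data.frame(condition = cond, C = cl$c_net, k_avg = mean(rowSums(net$adj)),
               l_path = l_path, connected = connected,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster movement conditions by network features
#'
#' Standardizes each feature column to zero mean and unit variance,
#' computes pairwise Euclidean distances and agglomerates with average
#' linkage. The partition at `k_clusters` groups is returned together with
#' the full dendrogram.
#'
#' @param ft a feature table from [movement_feature_table()], or any data
#'   frame with a `condition` column and numeric feature columns.
#' @param k_clusters number of clusters for the returned partition
#'   (default 2).
#' @param features feature columns to use (default `C`, `k_avg`,
#'   `l_path`).
#' @return A `movement_clustering`: `hclust` (the tree), `partition`
#'   (named integer vector), `k_clusters`, `features`.
#' @examples
#' ft <- data.frame(condition = c("a", "b", "c"),
#'                  C = c(0.69, 0.87, 0.80),
#'                  k_avg = c(28.8, 25.2, 26.2),
#'                  l_path = c(1.32, 1.22, 1.24))
#' cluster_movements(ft, 2)$partition
#' @export
cluster_movements <- function(ft, k_clusters = 2,
                              features = c("C", "k_avg", "l_path")) {
  if (nrow(ft) < 2) stop("need at least two conditions", call. = FALSE)
  if (k_clusters < 1 || k_clusters > nrow(ft)) {
    stop("k_clusters must lie in [1, number of conditions]", call. = FALSE)
  }
  X <- as.matrix(ft[, features, drop = FALSE])
  rownames(X) <- ft$condition
  X <- apply(X, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  hc <- hclust(dist(X, method = "euclidean"), method = "average")
  part <- cutree(hc, k = k_clusters)
  structure(list(hclust = hc, partition = part, k_clusters = k_clusters,
                 features = features),
            class = "movement_clustering")
}

#' @export
print.movement_clustering <- function(x, ...) {
  groups <- split(names(x$partition), x$partition)
  cat(sprintf("<movement_clustering> %d clusters: %s\n", x$k_clusters,
              paste(vapply(groups, function(g) {
                paste0("{", paste(g, collapse = ", "), "}")
              }, character(1)), collapse = " ")))
  invisible(x)
}

resolve_condition_input <- function(x, name) {
  if (inherits(x, "sim_config")) {
    gen <- generate_recording(x)
    list(recording = gen$recording, truth = gen$truth)
  } else if (inherits(x, "emg_recording")) {
    list(recording = x, truth = attr(x, "truth"))
  } else if (is.character(x) && length(x) == 1) {
    rec <- read_recording(x)
    list(recording = rec, truth = attr(rec, "truth"))
  } else {
    stop(sprintf("condition '%s' must be a sim_config, emg_recording or CSV path",
                 name), call. = FALSE)
  }
}

#' Run the full sensor-selection pipeline
#'
#' Orchestrates, per movement condition: preprocessing, lift-phase
#' segmentation, the weighted MI network, threshold selection (the largest
#' threshold feasible for every condition), binarization, topology
#' summary, node-contraction importance. Key nodes are the union across
#' conditions of nodes with importance above `importance_threshold`; their
#' induced subnetworks yield the movement feature table and the
#' hierarchical clustering of conditions. Convergent cross-mapping over
#' the key nodes' activation envelopes builds per-condition information
#' flow networks, synthesized into one directed network from which the
#' final ranked sensor set is selected with surface coverage.
#'
#' All randomness is controlled by the per-condition generator seeds and
#' the `seed` argument; a rerun with the same configuration is identical.
#'
#' @param conditions named list; each element is a [sim_config()], an
#'   `emg_recording`, or the path of a recording CSV written by
#'   [write_recording()].
#' @param low,high,order band-pass settings for [preprocess_recording()].
#' @param phase movement phase analysed (default `"lift"`).
#' @param B histogram bin count for the MI estimator.
#' @param normalization MI normalization (see [build_mi_matrix()]).
#' @param th binarization threshold; `NULL` (default) selects it
#'   automatically via [select_threshold()] per condition and takes the
#'   minimum, so every condition's network is connected with
#'   `<k> > 2 ln n`.
#' @param th_step threshold grid step.
#' @param importance_threshold IMC cut for key-node selection
#'   (default 0.5).
#' @param areas [area_map()] for area profiles and surface coverage;
#'   default the 33-electrode layout when applicable, otherwise a single
#'   nominal surface.
#' @param envelope_cutoff,envelope_decimate envelope extraction settings
#'   for the CCM stage (see [emg_envelope()]).
#' @param envelope_detrend subtract the across-repetition mean activation
#'   profile from each node's envelope before cross-mapping (default
#'   `TRUE`), so causality is probed on trial-to-trial activation dynamics
#'   rather than on the movement-locked profile shared by every channel.
#' @param ccm list of CCM settings: `E`, `tau`, `lib_sizes`, `repeats`,
#'   `n_pred`, `tau_cap`, `thresholds`; unset entries take the
#'   [build_directed_network()] defaults.
#' @param m_sensors number of sensors to select (default 5).
#' @param k_clusters clusters for the movement partition (default 2).
#' @param seed seed for the CCM library draws.
#' @param out_dir optional directory; when given, all stage outputs are
#'   written there (CSV/JSON/GraphML).
#' @return A `musclenet_report` with fields `th`, `networks`, `summaries`,
#'   `area_profiles`, `importance`, `key_nodes`, `key_networks`,
#'   `feature_table`, `clustering`, `directed`, `selection`, `truth`,
#'   `params`.
#' @export
run_pipeline <- function(conditions, low = 20, high = 450, order = 4,
                         phase = "lift", B = 16,
                         normalization = "geometric", th = NULL,
                         th_step = 0.01, importance_threshold = 0.5,
                         areas = NULL, envelope_cutoff = 10,
                         envelope_decimate = 20, envelope_detrend = TRUE,
                         ccm = list(),
                         m_sensors = 5, k_clusters = 2, seed = 1,
                         out_dir = NULL) {
  if (is.null(names(conditions))) {
    stop("conditions must be a named list", call. = FALSE)
  }
  inputs <- lapply(names(conditions), function(cond) {
    pipeline_stage(paste0("load:", cond), {
      resolve_condition_input(conditions[[cond]], cond)
    })
  })
  names(inputs) <- names(conditions)
  truth <- lapply(inputs, `[[`, "truth")

  filtered <- lapply(names(inputs), function(cond) {
    pipeline_stage(paste0("preprocess:", cond), {
      preprocess_recording(inputs[[cond]]$recording, low = low,
                           high = high, order = order)
    })
  })
  names(filtered) <- names(inputs)

  segments <- lapply(names(filtered), function(cond) {
    pipeline_stage(paste0("segment:", cond), {
      segment_phase(filtered[[cond]], phase)
    })
  })
  names(segments) <- names(filtered)

  weighted <- lapply(names(segments), function(cond) {
    pipeline_stage(paste0("mi_network:", cond), {
      build_mi_matrix(segments[[cond]], B = B, normalization = normalization)
    })
  })
  names(weighted) <- names(segments)
  labels <- weighted[[1]]$labels
  n <- length(labels)

  if (is.null(areas)) {
    areas <- if (n == 33 && identical(labels, channel_labels(33))) {
      default_area_map()
    } else {
      area_map(labels, rep(1L, n), rep("all", n))
    }
  }

  th_sel <- NULL
  if (is.null(th)) {
    th_sel <- lapply(names(weighted), function(cond) {
      pipeline_stage(paste0("threshold:", cond), {
        select_threshold(weighted[[cond]], step = th_step)
      })
    })
    names(th_sel) <- names(weighted)
    th <- min(vapply(th_sel, `[[`, numeric(1), "th"))
  }

  networks <- lapply(weighted, binarize, th = th)
  summaries <- lapply(networks, network_summary)
  area_profiles <- lapply(names(networks), function(cond) {
    pipeline_stage(paste0("area_profile:", cond), {
      area_degree_profile(networks[[cond]], areas)
    })
  })
  names(area_profiles) <- names(networks)

  importance <- lapply(names(networks), function(cond) {
    pipeline_stage(paste0("importance:", cond), {
      node_importance(networks[[cond]])
    })
  })
  names(importance) <- names(networks)

  key_nodes <- pipeline_stage("key_nodes", {
    select_key_nodes(importance, threshold = importance_threshold)
  })
  if (length(key_nodes) < 2) {
    stop("pipeline stage 'key_nodes' failed: fewer than two key nodes",
         call. = FALSE)
  }

  key_networks <- lapply(networks, function(net) {
    idx <- match(key_nodes, net$labels)
    binary_net(net$adj[idx, idx, drop = FALSE], labels = key_nodes,
               th = net$th)
  })

  feature_table <- pipeline_stage("feature_table", {
    movement_feature_table(key_networks)
  })

  clustering <- if (length(conditions) >= 2) {
    pipeline_stage("clustering", {
      cluster_movements(feature_table, k_clusters = min(k_clusters,
                                                        nrow(feature_table)))
    })
  } else {
    NULL
  }

  envelopes <- lapply(names(filtered), function(cond) {
    pipeline_stage(paste0("envelope:", cond), {
      phase_envelopes(filtered[[cond]], nodes = key_nodes, phase = phase,
                      cutoff = envelope_cutoff,
                      decimate = envelope_decimate,
                      detrend = envelope_detrend)
    })
  })
  names(envelopes) <- names(filtered)

  ccm_defaults <- list(E = 3, tau = NULL, lib_sizes = NULL, repeats = 5,
                       n_pred = NULL, tau_cap = 10,
                       thresholds = c(strong = 0.3, weak = 0.1, skill = 0.5))
  ccm <- utils::modifyList(ccm_defaults, ccm)

  directed <- pipeline_stage("directed_network", {
    build_directed_network(
      envelopes, nodes = key_nodes, E = ccm$E, tau = ccm$tau,
      lib_sizes = ccm$lib_sizes, repeats = ccm$repeats,
      n_pred = ccm$n_pred, tau_cap = ccm$tau_cap,
      thresholds = ccm$thresholds, seed = seed
    )
  })

  selection <- pipeline_stage("sensor_selection", {
    rank_and_select_sensors(directed, areas = areas, m = m_sensors)
  })

  report <- structure(list(
    conditions = names(conditions), th = th, th_selection = th_sel,
    weighted = weighted, networks = networks, summaries = summaries,
    area_profiles = area_profiles, importance = importance,
    key_nodes = key_nodes, key_networks = key_networks,
    feature_table = feature_table, clustering = clustering,
    directed = directed, selection = selection, truth = truth,
    params = list(low = low, high = high, order = order, phase = phase,
                  B = B, normalization = normalization, th_step = th_step,
                  importance_threshold = importance_threshold,
                  envelope_cutoff = envelope_cutoff,
                  envelope_decimate = envelope_decimate,
                  envelope_detrend = envelope_detrend, ccm = ccm,
                  m_sensors = m_sensors, k_clusters = k_clusters,
                  seed = seed)
  ), class = "musclenet_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

#' @export
print.musclenet_report <- function(x, ...) {
  cat(sprintf("<musclenet_report> conditions: %s\n",
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  threshold TH = %g; key nodes (%d): %s\n", x$th,
              length(x$key_nodes), paste(x$key_nodes, collapse = ", ")))
  cat(sprintf("  selected sensors: %s\n",
              paste(x$selection$selected, collapse = ", ")))
  print(x$feature_table)
  if (!is.null(x$clustering)) print(x$clustering)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits, per condition, the weighted MI matrix and threshold trace (CSV),
#' the binary network (GraphML + edge list), the importance vector (CSV),
#' and globally the feature table (CSV), the directed network (CSV +
#' GraphML), the sensor selection and run parameters (JSON).
#'
#' @param report a `musclenet_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  for (cond in report$conditions) {
    write.csv(report$weighted[[cond]]$w, p("mi_matrix_", cond, ".csv"))
    if (!is.null(report$th_selection)) {
      write.csv(report$th_selection[[cond]]$trace,
                p("threshold_trace_", cond, ".csv"), row.names = FALSE)
    }
    write_network(report$networks[[cond]], p("network_", cond, ".graphml"))
    imc <- report$importance[[cond]]$imc
    write.csv(data.frame(channel = names(imc), imc = imc),
              p("importance_", cond, ".csv"), row.names = FALSE)
  }
  write.csv(report$feature_table, p("feature_table.csv"), row.names = FALSE)
  write.csv(report$directed$edges, p("directed_edges.csv"),
            row.names = FALSE)
  write_network(report$directed, p("directed_overall.graphml"))
  jsonlite::write_json(
    list(key_nodes = report$key_nodes,
         selected = report$selection$selected,
         ranking = report$selection$ranking,
         th = report$th, params = report$params),
    p("selection.json"), auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(dir)
}
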