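# Rule-based causality calls, directed information-flow networks, and
# sensor-set selection.

#' Classify causality from a pair of converged cross-map skills
#'
#' Applies the four-rule decision table to the converged skills. With
#' `D = mx_skill - my_skill` (where `mx_skill` estimates x from the
#' y-manifold, evidence for x -> y):
#' \enumerate{
#'   \item `D > 0.3`: one-way causality x -> y.
#'   \item `D < 0.1`: comparable information in both directions -- no
#'     one-way causality.
#'   \item `0.1 < D < 0.3` and `mx_skill > 0.5`: no one-way causality.
#'   \item `0.1 < D < 0.3` and `mx_skill < 0.5`: one-way causality x -> y.
#' }
#' The mirrored test with the arguments swapped decides y -> x. Boundary
#' conventions: `D = 0.1` falls to rule 2, `D = 0.3` to rules 3/4, and
#' `mx_skill = 0.5` to rule 3.
#'
#' Note the asymmetry of rules 3 and 4: within the intermediate band a
#' *lower* absolute skill favours a causal call. The table is applied
#' exactly as stated.
#'
#' @param mx_skill converged skill of estimating x from the y-manifold.
#' @param my_skill converged skill of estimating y from the x-manifold.
#' @param thresholds named numeric vector `c(strong = 0.3, weak = 0.1,
#'   skill = 0.5)`.
#' @return A `causal_verdict`: `direction` (`"x_to_y"`, `"y_to_x"` or
#'   `"none"`), `rule` (1--4), plus the echoed inputs.
#' @examples
#' classify_causality(0.90, 0.50)$direction # "x_to_y" (rule 1)
#' classify_causality(0.60, 0.55)$direction # "none"   (rule 2)
#' @export
classify_causality <- function(mx_skill, my_skill,
                               thresholds = c(strong = 0.3, weak = 0.1,
                                              skill = 0.5)) {
  if (any(c(mx_skill, my_skill) < -1) || any(c(mx_skill, my_skill) > 1)) {
    stop("skills must lie in [-1, 1]", call. = FALSE)
  }
  eps <- 1e-9 # boundary comparisons are exact up to rounding noise
  forward <- function(d, s) {
    if (d > thresholds[["strong"]] + eps) {
      list(causal = TRUE, rule = 1L)
    } else if (d <= thresholds[["weak"]] + eps) {
      list(causal = FALSE, rule = 2L)
    } else if (s >= thresholds[["skill"]] - eps) {
      list(causal = FALSE, rule = 3L)
    } else {
      list(causal = TRUE, rule = 4L)
    }
  }
  f <- forward(mx_skill - my_skill, mx_skill)
  if (f$causal) {
    direction <- "x_to_y"
    rule <- f$rule
  } else {
    g <- forward(my_skill - mx_skill, my_skill)
    if (g$causal) {
      direction <- "y_to_x"
      rule <- g$rule
    } else {
      direction <- "none"
      rule <- f$rule
    }
  }
  structure(list(direction = direction, rule = rule,
                 mx_skill = mx_skill, my_skill = my_skill,
                 thresholds = thresholds),
            class = "causal_verdict")
}

#' @export
print.causal_verdict <- function(x, ...) {
  cat(sprintf("<causal_verdict> %s (rule %d; Mx = %.3f, My = %.3f)\n",
              x$direction, x$rule, x$mx_skill, x$my_skill))
  invisible(x)
}

# Embed every node of one condition once on a shared time axis; all nodes
# share the segment structure, so the manifolds are aligned and pairwise
# cross-mapping can reuse them.
embed_condition <- function(node_series, E, tau, theiler) {
  first <- node_series[[1]]
  times <- integer(0)
  offset <- 0L
  emb_times <- list()
  for (s in seq_along(first)) {
    m <- delay_embed(first[[s]], E, tau)
    emb_times[[s]] <- m$times
    times <- c(times, m$times + offset)
    offset <- offset + length(first[[s]]) + theiler + 10L
  }
  nodes <- lapply(node_series, function(segs) {
    pts <- list()
    vals <- numeric(0)
    for (s in seq_along(segs)) {
      if (length(segs[[s]]) != length(first[[s]])) {
        stop("all nodes must share the segment structure", call. = FALSE)
      }
      m <- delay_embed(segs[[s]], E, tau)
      pts[[s]] <- m$points
      vals <- c(vals, segs[[s]][emb_times[[s]]])
    }
    list(M = do.call(rbind, pts), vals = vals)
  })
  list(nodes = nodes, times = times)
}

# Convergence analysis for one ordered pair from precomputed embeddings.
conv_from_embeddings <- function(a, b, times, lib_sizes, repeats, pred, k,
                                 theiler, seed) {
  set.seed(seed)
  N <- nrow(a$M)
  # The same library draws serve both directions, so draw-composition noise
  # is common to mx and my and largely cancels in their difference -- the
  # quantity the causality rules act on.
  libs <- lapply(lib_sizes, function(L) {
    lapply(seq_len(repeats), function(i) sample.int(N, L))
  })
  skills <- function(M, vals) {
    vapply(seq_along(lib_sizes), function(j) {
      mean(vapply(libs[[j]], function(lib) {
        skill_once(M, vals, times, lib, pred, k, theiler, FALSE)
      }, numeric(1)))
    }, numeric(1))
  }
  mx <- skills(b$M, a$vals) # estimate a from b's manifold: evidence a -> b
  my <- skills(a$M, b$vals)
  list(mx_skill = mx[length(mx)], my_skill = my[length(my)],
       mx_curve = mx, my_curve = my)
}

# Normalize the per-condition series argument of build_directed_network to
# cond -> node -> list-of-segments.
normalize_series <- function(series) {
  lapply(series, function(cond) {
    if (is.matrix(cond)) {
      cols <- colnames(cond)
      if (is.null(cols)) cols <- channel_labels(ncol(cond))
      stats::setNames(lapply(seq_len(ncol(cond)), function(j) {
        list(cond[, j])
      }), cols)
    } else {
      lapply(cond, function(node) if (is.list(node)) node else list(node))
    }
  })
}

#' Build the directed information-flow network
#'
#' Runs pairwise [convergence_analysis()] plus [classify_causality()] over
#' all node pairs within each movement condition, then synthesizes the
#' overall directed network as the union of per-condition edges. An edge
#' whose reverse is also present (across conditions) is flagged
#' bidirectional.
#'
#' @param series per-condition node series: a named list (one entry per
#'   condition) whose elements are either a time-by-node matrix or a named
#'   list mapping node label to a numeric vector or list of segment
#'   vectors.
#' @param nodes node labels to analyse (default: all nodes of the first
#'   condition).
#' @inheritParams convergence_analysis
#' @param thresholds passed to [classify_causality()].
#' @param seed base seed; each (condition, pair) evaluation derives its own
#'   sub-seed, so results do not depend on evaluation order.
#' @return A `directed_net`: `labels`, `edges` (per-condition calls with
#'   skills and rule), `overall` (unique directed edges with a
#'   `bidirectional` flag and contributing conditions), and `params`.
#' @export
build_directed_network <- function(series, nodes = NULL, E = 3, tau = NULL,
                                   lib_sizes = NULL, repeats = 5,
                                   n_pred = NULL, tau_cap = 10,
                                   thresholds = c(strong = 0.3, weak = 0.1,
                                                  skill = 0.5),
                                   seed = 1) {
  if (length(series) == 0) stop("need at least one condition", call. = FALSE)
  if (is.null(names(series))) {
    names(series) <- paste0("condition", seq_along(series))
  }
  ser <- normalize_series(series)
  all_nodes <- names(ser[[1]])
  if (is.null(nodes)) nodes <- all_nodes
  unknown <- setdiff(nodes, all_nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  edges <- list()
  pair_id <- 0L
  for (cond in names(ser)) {
    cs <- ser[[cond]][nodes]
    if (length(nodes) < 2) next
    tau_c <- tau
    if (is.null(tau_c)) {
      tau_c <- max(vapply(cs, function(segs) select_tau(segs[[1]], tau_cap),
                          numeric(1)))
    }
    theiler <- (E - 1L) * tau_c
    emb <- embed_condition(cs, E, tau_c, theiler)
    N <- nrow(emb$nodes[[1]]$M)
    ls <- if (is.null(lib_sizes)) default_lib_sizes(N, E) else {
      sort(unique(pmin(lib_sizes, N)))
    }
    set.seed(seed)
    pred <- if (is.null(n_pred) || n_pred >= N) {
      seq_len(N)
    } else {
      sort(sample.int(N, n_pred))
    }
    pairs <- combn(nodes, 2)
    for (p in seq_len(ncol(pairs))) {
      pair_id <- pair_id + 1L
      a <- pairs[1, p]
      b <- pairs[2, p]
      conv <- conv_from_embeddings(
        emb$nodes[[a]], emb$nodes[[b]], emb$times, ls, repeats, pred,
        E + 1L, theiler, seed = (seed + pair_id) %% .Machine$integer.max
      )
      verdict <- classify_causality(conv$mx_skill, conv$my_skill,
                                    thresholds)
      if (verdict$direction != "none") {
        from <- if (verdict$direction == "x_to_y") a else b
        to <- if (verdict$direction == "x_to_y") b else a
        edges[[length(edges) + 1L]] <- data.frame(
          condition = cond, from = from, to = to,
          mx_skill = conv$mx_skill, my_skill = conv$my_skill,
          rule = verdict$rule, stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(edges) > 0) {
    do.call(rbind, edges)
  } else {
    data.frame(condition = character(), from = character(),
               to = character(), mx_skill = numeric(),
               my_skill = numeric(), rule = integer(),
               stringsAsFactors = FALSE)
  }
  overall <- synthesize_overall(edges)
  structure(list(
    labels = nodes, edges = edges, overall = overall,
    conditions = names(ser),
    params = list(E = E, tau = tau, repeats = repeats, seed = seed,
                  thresholds = thresholds)
  ), class = "directed_net")
}

# Union of per-condition directed edges; reverse pairs are flagged
# bidirectional.
synthesize_overall <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(from = character(), to = character(),
                      bidirectional = logical(), conditions = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  uniq <- !duplicated(key)
  out <- edges[uniq, c("from", "to"), drop = FALSE]
  out$conditions <- vapply(key[uniq], function(k) {
    paste(sort(unique(edges$condition[key == k])), collapse = ",")
  }, character(1))
  rev_key <- paste(out$to, out$from, sep = "\r")
  out$bidirectional <- rev_key %in% key[uniq]
  rownames(out) <- NULL
  out[c("from", "to", "bidirectional", "conditions")]
}

#' @export
print.directed_net <- function(x, ...) {
  cat(sprintf(
    "<directed_net> %d nodes, %d per-condition calls, %d overall edges (%d bidirectional)\n",
    length(x$labels), nrow(x$edges), nrow(x$overall),
    sum(x$overall$bidirectional)
  ))
  invisible(x)
}

#' @export
as_igraph.directed_net <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(net$labels), name = net$labels)
  if (nrow(net$overall) > 0) {
    g <- igraph::add_edges(g, rbind(net$overall$from, net$overall$to))
  }
  g
}

# Longest directed path (in edges) from any source to each node, computed
# on the condensation of strongly connected components; members of one
# component share the value.
longest_path_depth <- function(net) {
  g <- as_igraph(net)
  scc <- igraph::components(g, mode = "strong")
  memb <- scc$membership
  nc <- scc$no
  cadj <- matrix(FALSE, nc, nc)
  if (nrow(net$overall) > 0) {
    fi <- memb[match(net$overall$from, net$labels)]
    ti <- memb[match(net$overall$to, net$labels)]
    keep <- fi != ti
    cadj[cbind(fi[keep], ti[keep])] <- TRUE
  }
  depth <- rep(NA_real_, nc)
  remaining <- rep(TRUE, nc)
  while (any(remaining)) {
    ready <- which(remaining & vapply(seq_len(nc), function(v) {
      preds <- which(cadj[, v])
      all(!remaining[preds])
    }, logical(1)))
    if (length(ready) == 0) break # cannot happen on a DAG
    for (v in ready) {
      preds <- which(cadj[, v])
      depth[v] <- if (length(preds) == 0) 0 else max(depth[preds]) + 1
      remaining[v] <- FALSE
    }
  }
  stats::setNames(depth[memb], net$labels)
}

#' Rank nodes of the directed network and select a sensor set
#'
#' Nodes at the top of the information flow (sources, where motion
#' information originates) rank first. The declared rank key is:
#' longest directed path from any source ending at the node (ascending --
#' sources first), then out-degree minus in-degree (descending), then
#' label order; nodes with equal key values are reported as equal rank.
#' On a cyclic network the path depth is computed on the condensation of
#' strongly connected components, whose members share rank.
#'
#' The selection takes the top `m` ranked nodes and then minimally adjusts
#' it so that every limb surface with at least one candidate node is
#' represented: the best-ranked node of a missing surface replaces the
#' worst-ranked selected node of an over-represented surface.
#'
#' @param dnet a `directed_net`.
#' @param areas an [area_map()] giving each node's surface; default the
#'   33-electrode layout.
#' @param m number of sensors to select (default 5).
#' @return A `sensor_selection`: `ranking` (data frame with `label`,
#'   `depth`, `out_minus_in`, `rank`, `surface`), `selected` (labels),
#'   `coverage` (per-surface candidate/selected counts), `m`.
#' @export
rank_and_select_sensors <- function(dnet, areas = default_area_map(), m = 5) {
  stopifnot(inherits(dnet, "directed_net"))
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  labels <- dnet$labels
  missing <- setdiff(labels, areas$channel)
  if (length(missing) > 0) {
    stop(sprintf("area map does not cover node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  depth <- longest_path_depth(dnet)
  outd <- ind <- stats::setNames(numeric(length(labels)), labels)
  if (nrow(dnet$overall) > 0) {
    ot <- table(factor(dnet$overall$from, levels = labels))
    it <- table(factor(dnet$overall$to, levels = labels))
    outd[] <- as.numeric(ot)
    ind[] <- as.numeric(it)
  }
  omi <- outd - ind
  surface <- areas$surface[match(labels, areas$channel)]
  ord <- order(depth, -omi, seq_along(labels))
  key <- paste(depth, omi, sep = "|")
  rank <- match(key, unique(key[ord]))
  ranking <- data.frame(
    label = labels[ord], depth = depth[ord], out_minus_in = omi[ord],
    rank = rank[ord], surface = surface[ord], stringsAsFactors = FALSE
  )
  rownames(ranking) <- NULL

  m_eff <- min(m, length(labels))
  selected_idx <- seq_len(m_eff)
  surfaces_present <- unique(ranking$surface)
  repeat {
    sel_surf <- ranking$surface[selected_idx]
    missing_surf <- setdiff(surfaces_present, sel_surf)
    if (length(missing_surf) == 0) break
    # candidates of the first missing surface, best rank first
    cand <- setdiff(which(ranking$surface == missing_surf[1]), selected_idx)
    if (length(cand) == 0) break
    counts <- table(sel_surf)
    over <- names(counts)[counts >= 2]
    drop_pos <- rev(selected_idx)[match(TRUE, ranking$surface[rev(selected_idx)] %in% over)]
    if (is.na(drop_pos)) break # cannot free a slot without losing a surface
    selected_idx <- sort(c(setdiff(selected_idx, drop_pos), cand[1]))
  }
  selected <- ranking$label[selected_idx]
  cov <- do.call(rbind, lapply(surfaces_present, function(s) {
    data.frame(surface = s,
               n_candidates = sum(ranking$surface == s),
               n_selected = sum(ranking$surface[selected_idx] == s),
               stringsAsFactors = FALSE)
  }))
  structure(list(ranking = ranking, selected = selected, coverage = cov,
                 m = m),
            class = "sensor_selection")
}

#' @export
print.sensor_selection <- function(x, ...) {
  cat(sprintf("<sensor_selection> %s\n", paste(x$selected, collapse = ", ")))
  invisible(x)
}
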