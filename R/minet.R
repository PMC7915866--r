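# Weighted and binary muscle functional networks built from pairwise
# normalized mutual information.

#' Build the weighted mutual-information adjacency matrix
#'
#' For each analysis segment the pairwise normalized MI between all channel
#' pairs is estimated and the per-segment matrices are averaged, yielding
#' the weighted adjacency `A(aij)` of the muscle functional network. The
#' diagonal is forced to zero.
#'
#' Two normalizations are available: `"geometric"` (the default) divides MI
#' by `sqrt(H(S) H(Q))`, which is intrinsically bounded in `[0, 1]` and
#' comparable across recordings; `"minmax"` rescales the averaged raw-MI
#' off-diagonal entries linearly onto `[0, 1]`.
#'
#' @param segments a list of `emg_segment` objects (see [segment_phase()])
#'   or of plain samples-by-channels matrices, all with the same channel
#'   set.
#' @param B histogram bin count per channel (default 16).
#' @param normalization `"geometric"` or `"minmax"`.
#' @return A `weighted_net`: fields `w` (symmetric matrix, zero diagonal,
#'   entries in `[0, 1]`), `labels`, `normalization`, `B`, `n_segments`.
#' @export
build_mi_matrix <- function(segments, B = 16,
                            normalization = c("geometric", "minmax")) {
  normalization <- match.arg(normalization)
  if (length(segments) == 0) stop("need at least one segment", call. = FALSE)
  mats <- lapply(segments, function(s) {
    if (inherits(s, "emg_segment")) s$signals else as.matrix(s)
  })
  labels <- colnames(mats[[1]])
  if (is.null(labels)) labels <- channel_labels(ncol(mats[[1]]))
  for (m in mats) {
    lab <- colnames(m)
    if (is.null(lab)) lab <- channel_labels(ncol(m))
    if (!identical(lab, labels)) {
      stop("all segments must share the same channel set", call. = FALSE)
    }
  }
  raw <- normalization == "minmax"
  W <- Reduce(`+`, lapply(mats, mi_matrix_one, B = B, normalize = !raw)) /
    length(mats)
  if (raw) {
    off <- W[upper.tri(W)]
    rng <- range(off)
    W <- if (rng[2] > rng[1]) (W - rng[1]) / (rng[2] - rng[1]) else W * 0
  }
  diag(W) <- 0
  dimnames(W) <- list(labels, labels)
  structure(list(
    w = W, labels = labels, n = length(labels),
    normalization = normalization, B = B, n_segments = length(mats)
  ), class = "weighted_net")
}

#' @export
print.weighted_net <- function(x, ...) {
  cat(sprintf(
    "<weighted_net> %d nodes, %s-normalized MI averaged over %d segment(s) (B = %d)\n",
    x$n, x$normalization, x$n_segments, x$B
  ))
  cat(sprintf("  off-diagonal weights: %.3f .. %.3f\n",
              min(x$w[upper.tri(x$w)]), max(x$w[upper.tri(x$w)])))
  invisible(x)
}

#' Construct a binary functional network
#'
#' Low-level constructor used throughout the package; see [binarize()] for
#' thresholding a weighted MI network.
#'
#' @param adj symmetric 0/1 matrix with zero diagonal.
#' @param labels node labels (default `V1..Vn` or the matrix dimnames).
#' @param th threshold that produced the network, if any.
#' @return A `binary_net` with fields `adj`, `labels`, `n`, `th`.
#' @export
binary_net <- function(adj, labels = NULL, th = NA_real_) {
  adj <- as_adjacency(adj)
  if (is.null(labels)) {
    labels <- if (!is.null(colnames(adj))) colnames(adj)
              else channel_labels(ncol(adj))
  }
  dimnames(adj) <- list(labels, labels)
  structure(list(adj = adj, labels = labels, n = ncol(adj), th = th),
            class = "binary_net")
}

#' @export
print.binary_net <- function(x, ...) {
  cat(sprintf("<binary_net> %d nodes, %d edges%s\n", x$n,
              sum(x$adj) / 2,
              if (is.na(x$th)) "" else sprintf(" (TH = %g)", x$th)))
  invisible(x)
}

#' Threshold a weighted network into a binary one
#'
#' An edge is drawn between nodes `i` and `j` exactly when the normalized
#' mutual information exceeds the threshold: `aij = 1` iff `wij > TH`
#' (strict inequality).
#'
#' @param W a `weighted_net` (or a plain symmetric weight matrix).
#' @param th threshold in `[0, 1]`, or a [select_threshold()] result.
#' @return A `binary_net`.
#' @export
binarize <- function(W, th) {
  if (inherits(th, "th_selection")) th <- th$th
  if (!is.numeric(th) || th < 0 || th > 1) {
    stop("th must lie in [0, 1]", call. = FALSE)
  }
  w <- if (inherits(W, "weighted_net")) W$w else as.matrix(W)
  adj <- (w > th) * 1
  diag(adj) <- 0
  binary_net(adj, labels = colnames(w), th = th)
}

#' Select the binarization threshold
#'
#' Scans a threshold grid over `[0, 1]` and keeps the values whose binary
#' network (i) is connected -- a single component, hence no isolated nodes
#' -- and (ii) has average degree `<k>` greater than `2 ln n`. Among the
#' feasible values the largest (the sparsest valid network) is returned,
#' together with the full diagnostic trace.
#'
#' @param W a `weighted_net` (or plain symmetric weight matrix).
#' @param step grid step (default 0.01, grid `seq(0, 1, step)`).
#' @return A `th_selection`: `th` (chosen threshold), `degree_bound`
#'   (`2 ln n`), and `trace`, a data frame with per-threshold average
#'   degree, isolated-node count, component count and feasibility.
#'   If no grid value is feasible an error is signalled; the trace is
#'   attached to the condition as field `trace`.
#' @examples
#' w <- matrix(0.7, 5, 5); diag(w) <- 0
#' select_threshold(w)$th
#' @export
select_threshold <- function(W, step = 0.01) {
  w <- if (inherits(W, "weighted_net")) W$w else as.matrix(W)
  n <- ncol(w)
  bound <- 2 * log(n)
  grid <- seq(0, 1, by = step)
  trace <- data.frame(
    th = grid, avg_degree = NA_real_, n_isolated = NA_integer_,
    n_components = NA_integer_, feasible = NA
  )
  for (i in seq_along(grid)) {
    adj <- (w > grid[i]) * 1
    diag(adj) <- 0
    deg <- rowSums(adj)
    comp <- graph_components(adj)
    trace$avg_degree[i] <- mean(deg)
    trace$n_isolated[i] <- sum(deg == 0)
    trace$n_components[i] <- max(comp)
    trace$feasible[i] <- max(comp) == 1L && mean(deg) > bound
  }
  if (!any(trace$feasible)) {
    cond <- structure(
      class = c("musclenet_threshold_error", "error", "condition"),
      list(message = paste0(
        "no threshold yields a connected network with <k> > 2 ln n = ",
        sprintf("%.3f", bound), "; inspect the attached trace"
      ), call = NULL, trace = trace)
    )
    stop(cond)
  }
  th <- max(grid[trace$feasible])
  structure(list(th = th, degree_bound = bound, trace = trace),
            class = "th_selection")
}

#' @export
print.th_selection <- function(x, ...) {
  cat(sprintf("<th_selection> TH = %g (degree bound 2 ln n = %.3f)\n",
              x$th, x$degree_bound))
  invisible(x)
}

#' Export a network for external tools
#'
#' Writes a `binary_net` or `directed_net` as GraphML or as an edge-list
#' CSV.
#'
#' @param net a `binary_net` or `directed_net`.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.csv(el, path, row.names = FALSE)
  }
  invisible(path)
}

#' Convert a musclenet network to an igraph object
#'
#' @param net a `binary_net` or `directed_net`.
#' @return An `igraph` graph (undirected for `binary_net`, directed for
#'   `directed_net`).
#' @export
as_igraph <- function(net) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.binary_net <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
}
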