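# Node-contraction importance: how much more cohesive the network becomes
# when a node and its neighborhood are merged into a single supernode.

# Cohesion of a plain adjacency matrix: (n - 1) / sum_{i != j} d_ij,
# i.e. 1 / (n * L). A single-node network has cohesion 1 by convention
# (maximal: it cannot be contracted further).
cohesion_adj <- function(adj) {
  n <- ncol(adj)
  if (n == 1L) {
    return(1)
  }
  D <- graph_distances(adj)
  total <- sum(D[row(D) != col(D)])
  if (!is.finite(total)) stop_disconnected(adj, "cohesion")
  (n - 1) / total
}

#' Network cohesion
#'
#' Cohesion of a connected network `M` is defined as
#' \deqn{\partial(M) = \frac{1}{n L} = \frac{n - 1}{\sum_{i \ne j} d_{ij}}}
#' the inverse of node count times average shortest-path length. Smaller,
#' sparser, more stretched-out networks are less cohesive. A single-node
#' network has cohesion 1 by convention.
#'
#' @param net a connected `binary_net`.
#' @return Cohesion, a unitless positive value.
#' @examples
#' cohesion(binary_net(1 - diag(3))) # K_3: 1/3
#' @export
cohesion <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  cohesion_adj(net$adj)
}

# Contract node i together with its neighborhood into one supernode on a
# plain adjacency matrix. Returns the reduced matrix (n - k_i nodes) and
# the member labels of the supernode.
contract_adj <- function(adj, i) {
  n <- ncol(adj)
  members <- which(adj[i, ] > 0)
  s <- sort(unique(c(i, members)))
  rest <- setdiff(seq_len(n), s)
  m <- length(rest) + 1L
  out <- matrix(0, m, m)
  if (length(rest) > 0) {
    out[seq_along(rest), seq_along(rest)] <- adj[rest, rest]
    link <- as.numeric(colSums(adj[s, rest, drop = FALSE]) > 0)
    out[m, seq_along(rest)] <- link
    out[seq_along(rest), m] <- link
  }
  labels <- colnames(adj)
  if (!is.null(labels)) {
    dimnames(out) <- list(
      c(labels[rest], paste(labels[s], collapse = "+")),
      c(labels[rest], paste(labels[s], collapse = "+"))
    )
  }
  out
}

#' Contract a node with its neighborhood
#'
#' Merges node `i` and the set of nodes directly connected to it into one
#' supernode; every edge touching the merged set is reattached to the
#' supernode, parallel edges collapse and self-loops are dropped. For a
#' node of degree `ki` the contracted network has `n - ki` nodes.
#' Contracting a connected network yields a connected network.
#'
#' @param net a connected `binary_net`.
#' @param i node index or label to contract.
#' @return The contracted `binary_net`; the supernode label joins the
#'   merged labels with `"+"`.
#' @export
contract_node <- function(net, i) {
  stopifnot(inherits(net, "binary_net"))
  if (is.character(i)) i <- match(i, net$labels)
  if (is.na(i) || i < 1 || i > net$n) {
    stop("unknown node", call. = FALSE)
  }
  if (!is_connected_adj(net$adj)) stop_disconnected(net$adj, "contract_node")
  out <- contract_adj(net$adj, i)
  binary_net(out, labels = colnames(out), th = net$th)
}

# IMC scores on a plain adjacency matrix (assumed connected).
imc_adj <- function(adj) {
  base <- cohesion_adj(adj)
  vapply(seq_len(ncol(adj)), function(i) {
    1 - base / cohesion_adj(contract_adj(adj, i))
  }, numeric(1))
}

#' Node-contraction importance (IMC)
#'
#' The importance of node `i` is the relative cohesion gain obtained by
#' contracting `i` with its neighborhood:
#' \deqn{IMC(i) = 1 - \frac{\partial(M)}{\partial(M \times i)}}
#' where \eqn{M \times i} is the contracted network. A node whose
#' contraction collapses the whole network to a single supernode receives
#' the maximal score \eqn{1 - \partial(M)} (single-node cohesion is 1).
#' Scores are always `< 1`; structurally critical hubs score highest.
#'
#' @param net a connected `binary_net`.
#' @return An `importance_vector`: `imc` (named per-node scores),
#'   `cohesion` (of the input network), `labels`.
#' @examples
#' p3 <- binary_net(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' node_importance(p3)$imc # center 0.75, leaves 0.5
#' @export
node_importance <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  if (!is_connected_adj(net$adj)) stop_disconnected(net$adj, "node_importance")
  imc <- imc_adj(net$adj)
  names(imc) <- net$labels
  structure(list(imc = imc, cohesion = cohesion_adj(net$adj),
                 labels = net$labels),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat(sprintf("<importance_vector> %d nodes, input cohesion %.4f\n",
              length(x$imc), x$cohesion))
  ord <- order(x$imc, decreasing = TRUE)
  top <- head(ord, 5)
  cat("  top IMC:", paste(sprintf("%s = %.3f", names(x$imc)[top],
                                  x$imc[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Select key nodes by importance threshold
#'
#' Returns the labels whose IMC exceeds the threshold. When several
#' conditions are supplied (a list of importance vectors), the selection is
#' the union of the per-condition selections.
#'
#' @param iv an `importance_vector`, or a (possibly named) list of them,
#'   one per movement condition.
#' @param threshold selection cut in `[0, 1)` (default 0.5).
#' @return Character vector of selected labels, in label order. An empty
#'   selection triggers a warning and returns `character(0)`.
#' @export
select_key_nodes <- function(iv, threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  ivs <- if (inherits(iv, "importance_vector")) list(iv) else iv
  labels <- ivs[[1]]$labels
  sel <- unique(unlist(lapply(ivs, function(v) {
    names(v$imc)[v$imc > threshold]
  })))
  sel <- labels[labels %in% sel]
  if (length(sel) == 0) {
    warning("no node exceeds the importance threshold", call. = FALSE)
  }
  sel
}
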