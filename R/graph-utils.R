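# Small dense-graph primitives shared by the network modules. Networks here
# are tiny (n <= 33 channels), so breadth-first search on the adjacency
# matrix is both simpler and faster than converting to a graph object for
# every call.

# Validate and coerce a 0/1 adjacency matrix.
as_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (any(is.na(adj)) || !all(adj %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  if (!isTRUE(all.equal(adj, t(adj), check.attributes = FALSE))) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(adj) != 0)) {
    stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  }
  storage.mode(adj) <- "double"
  adj
}

# All-pairs shortest path lengths (edge counts) by simultaneous BFS from all
# sources; Inf marks unreachable pairs.
graph_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n == 1L) {
    return(D)
  }
  reach <- diag(TRUE, n)
  frontier <- diag(1, n)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- (frontier %*% adj > 0) & !reach
    if (!any(nxt)) break
    D[nxt] <- d
    reach <- reach | nxt
    frontier <- nxt * 1
  }
  dimnames(D) <- dimnames(adj)
  D
}

# Connected-component membership (undirected), via reachability from each
# unvisited node.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    k <- k + 1L
    members <- logical(n)
    members[v] <- TRUE
    frontier <- members
    while (any(frontier)) {
      nbrs <- (colSums(adj[frontier, , drop = FALSE]) > 0) & !members
      members <- members | nbrs
      frontier <- nbrs
    }
    comp[members] <- k
  }
  comp
}

is_connected_adj <- function(adj) {
  nrow(adj) <= 1L || max(graph_components(adj)) == 1L
}

stop_disconnected <- function(adj, what) {
  comp <- graph_components(adj)
  sizes <- as.integer(table(comp))
  stop(sprintf(
    "%s requires a connected network; found %d components with sizes %s",
    what, length(sizes), paste(sizes, collapse = ", ")
  ), call. = FALSE)
}
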