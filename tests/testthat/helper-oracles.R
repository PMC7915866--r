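# Independent brute-force oracles used to cross-check the package's graph
# and information-theoretic computations. These deliberately use different
# algorithms from the implementation (Floyd-Warshall instead of BFS,
# explicit neighbour-pair and joint-bin enumeration).

# All-pairs shortest paths by Floyd-Warshall.
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

fw_connected <- function(adj) all(is.finite(fw_distances(adj)))

bf_avg_path_length <- function(adj) {
  D <- fw_distances(adj)
  mean(D[row(D) != col(D)])
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        e <- e + adj[nb[a], nb[b]]
      }
    }
    ci[i] <- 2 * e / (k * (k - 1))
  }
  list(ci = ci, c_net = mean(ci))
}

bf_cohesion <- function(adj) {
  n <- nrow(adj)
  if (n == 1) {
    return(1)
  }
  D <- fw_distances(adj)
  (n - 1) / sum(D[row(D) != col(D)])
}

# Quotient graph after merging node i with its neighbourhood (set-merge
# enumeration).
bf_contract <- function(adj, i) {
  s <- sort(unique(c(i, which(adj[i, ] > 0))))
  rest <- setdiff(seq_len(nrow(adj)), s)
  m <- length(rest) + 1L
  out <- matrix(0, m, m)
  for (a in seq_along(rest)) {
    for (b in seq_along(rest)) {
      out[a, b] <- adj[rest[a], rest[b]]
    }
  }
  for (a in seq_along(rest)) {
    out[m, a] <- out[a, m] <- as.numeric(any(adj[s, rest[a]] > 0))
  }
  out
}

bf_imc <- function(adj) {
  base <- bf_cohesion(adj)
  vapply(seq_len(ncol(adj)), function(i) {
    1 - base / bf_cohesion(bf_contract(adj, i))
  }, numeric(1))
}

# All connected labelled graphs on n nodes, as adjacency matrices.
all_connected_adjacencies <- function(n) {
  pairs <- utils::combn(n, 2)
  ne <- ncol(pairs)
  out <- vector("list", 2^ne)
  cnt <- 0L
  for (mask in 0:(2^ne - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(ne)]
    adj <- matrix(0, n, n)
    on <- which(bits == 1L)
    if (length(on) > 0) {
      adj[cbind(pairs[1, on], pairs[2, on])] <- 1
      adj[cbind(pairs[2, on], pairs[1, on])] <- 1
    }
    if (fw_connected(adj)) {
      cnt <- cnt + 1L
      out[[cnt]] <- adj
    }
  }
  out[seq_len(cnt)]
}

# Histogram MI oracle: explicit enumeration of the B x B joint bin counts.
bf_mutual_information <- function(s, q, B) {
  edges_of <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) {
      return(NULL)
    }
    seq(r[1], r[2], length.out = B + 1)
  }
  bin_of <- function(x, edges) {
    if (is.null(edges)) {
      return(rep(1L, length(x)))
    }
    i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    i
  }
  bs <- bin_of(s, edges_of(s))
  bq <- bin_of(q, edges_of(q))
  n <- length(s)
  joint <- matrix(0, B, B)
  for (i in seq_len(B)) {
    for (j in seq_len(B)) {
      joint[i, j] <- sum(bs == i & bq == j)
    }
  }
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  H(rowSums(joint) / n) + H(colSums(joint) / n) - H(joint / n)
}

# Convenience constructors for small graphs.
path_graph <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  adj
}

star_graph <- function(k) { # center = node 1, k leaves
  adj <- matrix(0, k + 1, k + 1)
  adj[1, 2:(k + 1)] <- adj[2:(k + 1), 1] <- 1
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1, n, n)
  diag(adj) <- 0
  adj
}

# Seeded random connected graph on n nodes (rejection sampling).
random_connected_adj <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0, n, n)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, p)
    adj <- adj + t(adj)
    if (fw_connected(adj)) {
      return(adj)
    }
  }
}

# Hand-constructed directed_net for selection tests.
make_directed_net <- function(labels, edges_df) {
  rev_key <- paste(edges_df$to, edges_df$from)
  key <- paste(edges_df$from, edges_df$to)
  edges_df$bidirectional <- rev_key %in% key
  if (is.null(edges_df$conditions)) {
    edges_df$conditions <- rep("a", nrow(edges_df))
  }
  n <- nrow(edges_df)
  structure(list(
    labels = labels,
    edges = data.frame(condition = rep("a", n), from = edges_df$from,
                       to = edges_df$to, mx_skill = rep(NA_real_, n),
                       my_skill = rep(NA_real_, n),
                       rule = rep(NA_integer_, n),
                       stringsAsFactors = FALSE),
    overall = edges_df[c("from", "to", "bidirectional", "conditions")],
    conditions = "a",
    params = list()
  ), class = "directed_net")
}
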