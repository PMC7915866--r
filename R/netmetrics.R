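# Topology metrics of the binary muscle functional network.

#' Degree statistics of a binary network
#'
#' @param net a `binary_net`.
#' @return A list with `k` (named per-node degrees), `k_avg` (average
#'   degree), and `pk` (data frame of degree values and their proportions
#'   `P(k) = n_k / n`).
#' @examples
#' net <- binary_net(1 - diag(5)) # K_5
#' degree_stats(net)$k_avg
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  k <- rowSums(net$adj)
  names(k) <- net$labels
  tab <- table(k)
  pk <- data.frame(k = as.integer(names(tab)),
                   p = as.numeric(tab) / net$n)
  list(k = k, k_avg = mean(k), pk = pk)
}

#' Clustering coefficients
#'
#' Per-node clustering `Ci = 2 Ei / (ki (ki - 1))`, where `Ei` counts the
#' edges among the neighbors of node `i`; `Ci = 0` by convention when
#' `ki < 2`. The network coefficient `C` is the mean of the `Ci`.
#'
#' @param net a `binary_net`.
#' @return A list with `ci` (named per-node coefficients in `[0, 1]`) and
#'   `c_net` (their mean).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  adj <- net$adj
  n <- net$n
  ci <- numeric(n)
  k <- rowSums(adj)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nbrs <- which(adj[i, ] > 0)
    ei <- sum(adj[nbrs, nbrs]) / 2
    ci[i] <- 2 * ei / (k[i] * (k[i] - 1))
  }
  names(ci) <- net$labels
  list(ci = ci, c_net = mean(ci))
}

#' Average shortest-path length
#'
#' `L = sum_{i != j} d_ij / (n (n - 1))`, with `d_ij` the shortest-path
#' edge count between nodes `i` and `j`. Defined for connected networks
#' only; a disconnected input raises an error reporting component sizes.
#'
#' @param net a `binary_net`.
#' @return The average path length (a single number, `>= 1` for connected
#'   networks with `n >= 2`).
#' @export
avg_path_length <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  if (net$n == 1L) {
    return(0)
  }
  if (!is_connected_adj(net$adj)) {
    stop_disconnected(net$adj, "avg_path_length")
  }
  D <- graph_distances(net$adj)
  sum(D[row(D) != col(D)]) / (net$n * (net$n - 1))
}

#' Full topology summary of a binary network
#'
#' Convenience wrapper assembling degrees, degree distribution, clustering
#' and (for connected networks) average path length.
#'
#' @param net a `binary_net`.
#' @return A `net_summary` list: `k`, `k_avg`, `pk`, `ci`, `c_net`,
#'   `l_path` (`NA` when disconnected), `connected`, `n`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "binary_net"))
  deg <- degree_stats(net)
  cl <- clustering_coefficient(net)
  connected <- is_connected_adj(net$adj)
  l_path <- if (connected && net$n > 1) avg_path_length(net) else NA_real_
  structure(list(
    n = net$n, k = deg$k, k_avg = deg$k_avg, pk = deg$pk,
    ci = cl$ci, c_net = cl$c_net, l_path = l_path, connected = connected
  ), class = "net_summary")
}

#' @export
print.net_summary <- function(x, ...) {
  cat(sprintf(
    "<net_summary> n = %d, <k> = %.3f, C = %.3f, L = %s, %s\n",
    x$n, x$k_avg, x$c_net,
    if (is.na(x$l_path)) "NA" else sprintf("%.3f", x$l_path),
    if (x$connected) "connected" else "disconnected"
  ))
  invisible(x)
}

#' Electrode area map
#'
#' Assigns each channel to one of the limb areas and to a surface
#' (front / back / side). [default_area_map()] provides the 33-electrode
#' layout used throughout: the front carries `V1`--`V12` (areas 1 and 2),
#' the back `V13`--`V23` (areas 3 and 4), the outer side `V24`--`V33`
#' (areas 5 and 6); each surface is split into two areas by distance along
#' the limb, without an anatomical claim as to which is nearer the wound.
#'
#' @param channel character vector of channel labels.
#' @param area integer area index per channel.
#' @param surface surface label per channel (`"front"`, `"back"`,
#'   `"side"`).
#' @return An `area_map` data frame with columns `channel`, `area`,
#'   `surface`.
#' @export
area_map <- function(channel, area, surface) {
  if (length(channel) != length(area) || length(channel) != length(surface)) {
    stop("channel, area and surface must have equal length", call. = FALSE)
  }
  if (any(table(area) == 0)) stop("each area must be nonempty", call. = FALSE)
  structure(
    data.frame(channel = as.character(channel), area = as.integer(area),
               surface = as.character(surface), stringsAsFactors = FALSE),
    class = c("area_map", "data.frame")
  )
}

#' @rdname area_map
#' @export
default_area_map <- function() {
  area_map(
    channel = channel_labels(33),
    area = rep(1:6, c(6, 6, 5, 6, 5, 5)),
    surface = rep(c("front", "back", "side"), c(12, 11, 10))
  )
}

#' Per-area mean degree profile
#'
#' Mean node degree within each electrode area, plus the overall mean --
#' the per-area degree profile used to compare movement conditions across
#' limb surfaces.
#'
#' @param net a `binary_net`.
#' @param areas an [area_map()] covering every node of `net`.
#' @return A data frame with one row per area (`area`, `surface`,
#'   `n_nodes`, `mean_degree`) and an attribute `overall_mean`.
#' @export
area_degree_profile <- function(net, areas = default_area_map()) {
  stopifnot(inherits(net, "binary_net"))
  missing <- setdiff(net$labels, areas$channel)
  if (length(missing) > 0) {
    stop(sprintf("area map does not cover node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  k <- rowSums(net$adj)
  names(k) <- net$labels
  areas <- areas[areas$channel %in% net$labels, , drop = FALSE]
  out <- do.call(rbind, lapply(split(areas, areas$area), function(a) {
    data.frame(area = a$area[1], surface = a$surface[1],
               n_nodes = nrow(a), mean_degree = mean(k[a$channel]))
  }))
  rownames(out) <- NULL
  attr(out, "overall_mean") <- mean(k)
  out
}
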