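# Histogram (plug-in) information estimators. Each channel is discretized
# into B equal-width bins spanning its observed range; probabilities are
# relative bin counts. Entropies are in bits.

# Map a numeric series onto 1..B equal-width bins; a constant series falls
# entirely into bin 1.
bin_series <- function(x, B) {
  if (length(x) == 0) stop("empty series", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) {
    return(rep(1L, length(x)))
  }
  breaks <- seq(r[1], r[2], length.out = B + 1)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Histogram entropy of one channel
#'
#' Shannon entropy \eqn{H = -\sum_i p_i \log_2 p_i} (bits) of the series
#' discretized into `B` equal-width bins over its observed range. The
#' convention \eqn{0 \log 0 = 0} applies, so `H` lies in `[0, log2(B)]` and
#' a constant series has zero entropy.
#'
#' @param x numeric series, finite, with `length(x) >= B`.
#' @param B number of bins (default 16).
#' @return Entropy in bits.
#' @examples
#' channel_entropy(rep(c(0, 1), 50), B = 2) # 1 bit
#' @export
channel_entropy <- function(x, B = 16) {
  if (length(x) < B) {
    stop(sprintf("series length (%d) must be >= B (%d)", length(x), B),
         call. = FALSE)
  }
  entropy_from_counts(tabulate(bin_series(x, B), nbins = B))
}

#' Joint histogram entropy of two channels
#'
#' \eqn{H(S,Q) = -\sum_{i,j} P_{sq}(s_i, q_j) \log_2 P_{sq}(s_i, q_j)} over
#' the `B x B` grid of per-channel equal-width bins. Satisfies
#' `max(H(S), H(Q)) <= H(S,Q) <= H(S) + H(Q)`.
#'
#' @param s,q numeric series of equal length.
#' @inheritParams channel_entropy
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(s, q, B = 16) {
  if (length(s) != length(q)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(s) < B) {
    stop(sprintf("series length (%d) must be >= B (%d)", length(s), B),
         call. = FALSE)
  }
  bs <- bin_series(s, B)
  bq <- bin_series(q, B)
  entropy_from_counts(tabulate((bs - 1L) * B + bq, nbins = B * B))
}

#' Histogram mutual information between two channels
#'
#' `MI(S, Q) = H(S) + H(Q) - H(S, Q)`, estimated on a shared `B`-bin
#' equal-width discretization. Non-negative, symmetric in its arguments,
#' and equal to `H(S)` when `q = s`. `MI = 0` indicates independent
#' channels under the histogram model.
#'
#' @inheritParams joint_entropy
#' @param normalize if `TRUE`, return `MI / sqrt(H(S) * H(Q))`, which is
#'   bounded in `[0, 1]` (1 for identical channels); defined as 0 when
#'   either marginal entropy is 0.
#' @return Mutual information in bits (or a unitless value in `[0, 1]` when
#'   normalized).
#' @examples
#' x <- sin(seq(0, 20, length.out = 500))
#' mutual_information(x, x) == channel_entropy(x)
#' @export
mutual_information <- function(s, q, B = 16, normalize = FALSE) {
  if (length(s) != length(q)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(s) < B) {
    stop(sprintf("series length (%d) must be >= B (%d)", length(s), B),
         call. = FALSE)
  }
  bs <- bin_series(s, B)
  bq <- bin_series(q, B)
  hs <- entropy_from_counts(tabulate(bs, nbins = B))
  hq <- entropy_from_counts(tabulate(bq, nbins = B))
  hsq <- entropy_from_counts(tabulate((bs - 1L) * B + bq, nbins = B * B))
  mi <- max(hs + hq - hsq, 0)
  if (!normalize) {
    return(mi)
  }
  if (hs <= 0 || hq <= 0) 0 else mi / sqrt(hs * hq)
}

# Pairwise normalized-MI matrix of a samples x channels matrix; the
# workhorse behind build_mi_matrix. Returns raw MI when normalize = FALSE.
mi_matrix_one <- function(mat, B, normalize = TRUE) {
  nc <- ncol(mat)
  bins <- lapply(seq_len(nc), function(j) bin_series(mat[, j], B))
  H <- vapply(bins, function(b) entropy_from_counts(tabulate(b, nbins = B)),
              numeric(1))
  W <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) {
    bi <- (bins[[i]] - 1L) * B
    for (j in (i + 1L):nc) {
      hsq <- entropy_from_counts(tabulate(bi + bins[[j]], nbins = B * B))
      mi <- max(H[i] + H[j] - hsq, 0)
      W[i, j] <- W[j, i] <- if (normalize) {
        if (H[i] <= 0 || H[j] <= 0) 0 else mi / sqrt(H[i] * H[j])
      } else {
        mi
      }
    }
  }
  W
}
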