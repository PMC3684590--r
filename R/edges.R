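#' Edge (functional connection) indexing
#'
#' A connectome on `n_rois` regions has `n_rois * (n_rois - 1) / 2` undirected
#' edges. Feature vectors linearize the strict upper triangle of the symmetric
#' connectivity matrix in row-major order: (1,2), (1,3), ..., (1,R), (2,3), ...
#' These helpers form the bijection between the linear edge index `k` and the
#' ROI pair `(i, j)` with `i < j`. With 1024 regions the feature dimension is
#' 523776.
#'
#' @param n_rois number of regions (>= 2).
#' @return `n_edges()`: the edge count. `edge_index()`: linear indices.
#'   `edge_pair()`: an `length(k) x 2` matrix of ROI pairs. `edge_pairs()`: the
#'   full `E x 2` pair matrix in linear-index order.
#' @examples
#' n_edges(1024)            # 523776
#' edge_index(1, 2, 90)     # 1
#' edge_pair(n_edges(90), 90)  # c(89, 90)
#' @export
n_edges <- function(n_rois) {
  stopifnot_scalar_count(n_rois, "n_rois", min = 2)
  n_rois * (n_rois - 1) / 2
}

#' @rdname n_edges
#' @param i,j ROI indices (1-based), `i < j` elementwise.
#' @export
edge_index <- function(i, j, n_rois) {
  if (any(i >= j) || any(i < 1) || any(j > n_rois)) {
    stop("need 1 <= i < j <= n_rois", call. = FALSE)
  }
  (i - 1) * (2 * n_rois - i) / 2 + (j - i)
}

#' @rdname n_edges
#' @param k linear edge indices in `1:n_edges(n_rois)`.
#' @export
edge_pair <- function(k, n_rois) {
  E <- n_edges(n_rois)
  if (any(k < 1) || any(k > E)) stop("edge index out of range", call. = FALSE)
  # cumulative edge counts after each row i of the upper triangle
  ends <- cumsum(seq(n_rois - 1, 1))
  i <- findInterval(k - 1, c(0, ends), rightmost.closed = FALSE)
  j <- k - c(0, ends)[i] + i
  cbind(i = i, j = j)
}

#' @rdname n_edges
#' @export
edge_pairs <- function(n_rois) {
  stopifnot_scalar_count(n_rois, "n_rois", min = 2)
  reps <- seq(n_rois - 1, 1)
  i <- rep.int(seq_len(n_rois - 1), reps)
  j <- sequence(reps) + i
  cbind(i = i, j = j)
}
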