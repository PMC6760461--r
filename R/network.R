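#' Median + MAD threshold of a value set
#'
#' Threshold used to binarize LPS matrices: the median of the values plus
#' the median of the absolute deviations from that median.  The MAD is
#' unscaled (no normal-consistency factor).
#'
#' @param values Numeric vector (non-empty).
#' @return The threshold value.
#' @examples
#' mad_threshold(c(1, 2, 3, 4, 5))  # median 3 + MAD 1 = 4
#' @export
mad_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot threshold an empty value set")
  m <- median(values)
  m + median(abs(values - m))
}

.is_hyper <- function(adj) !is.null(attr(adj, "blocks"))

.new_adjacency <- function(m, threshold, blocks = NULL, labels = NULL) {
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  diag(m) <- 1  # self-connections: stored, excluded from all counts/metrics
  structure(m, class = c("adjacency_matrix", "matrix"),
            threshold = threshold, blocks = blocks)
}

# edge count over the off-diagonal upper triangle
.n_edges <- function(m) {
  m <- unclass(m)
  sum(m[upper.tri(m)])
}

#' Binarize an LPS matrix into an adjacency matrix
#'
#' An edge is set wherever the band-averaged LPS value is greater than or
#' equal to the median + MAD threshold computed over that trial's full
#' value set (325 values for a single-brain matrix; all 1326 intra- and
#' inter-brain values jointly for a hyperbrain matrix).  With
#' `mode = "pooled"`, a caller-supplied threshold (e.g. computed over a
#' pooled set of trials) is applied instead.
#'
#' @param lps An `lps_matrix` (values in `[0, 1]`).
#' @param mode `"per-trial"` (default) or `"pooled"`.
#' @param threshold Threshold override, required for `mode = "pooled"`.
#' @return An `adjacency_matrix`: binary symmetric matrix with attributes
#'   `threshold` and (for hyperbrain input) `blocks = c(n1, n2)`.  The
#'   diagonal stores self-connections, which are excluded from every count
#'   and measure.
#' @export
binarize <- function(lps, mode = c("per-trial", "pooled"), threshold = NULL) {
  mode <- match.arg(mode)
  vals <- unclass(lps)[upper.tri(lps)]
  if (any(vals < -1e-9 | vals > 1 + 1e-9, na.rm = TRUE))
    stop("LPS values outside [0, 1]")
  thr <- if (mode == "pooled") {
    if (is.null(threshold)) stop("pooled mode requires a threshold")
    threshold
  } else mad_threshold(vals)
  m <- ifelse(unclass(lps) >= thr, 1, 0)
  m[is.na(m)] <- 0
  .new_adjacency(m, thr, blocks = attr(lps, "blocks"),
                 labels = rownames(lps))
}

#' Assemble a hyperbrain adjacency matrix from blocks
#'
#' Builds the 52 x 52 (in general `(n1 + n2)` square) matrix whose upper
#' left and lower right blocks are the two intra-brain maps and whose off
#' diagonal blocks are the inter-brain map (lower left equal to the
#' transpose of upper right).  By convention the first block is J1, the
#' less experienced member of the dyad.
#'
#' @param intra_j1,intra_j2 Binary symmetric intra-brain matrices.
#' @param inter Binary `n1 x n2` inter-brain matrix (J1 rows, J2 columns).
#' @param threshold Optional threshold annotation.
#' @return A hyperbrain `adjacency_matrix`.
#' @export
assemble_hyperbrain <- function(intra_j1, intra_j2, inter, threshold = NA) {
  n1 <- nrow(intra_j1); n2 <- nrow(intra_j2)
  if (nrow(inter) != n1 || ncol(inter) != n2)
    stop("block dimensions do not match")
  m <- matrix(0, n1 + n2, n1 + n2)
  m[seq_len(n1), seq_len(n1)] <- unclass(intra_j1)
  m[n1 + seq_len(n2), n1 + seq_len(n2)] <- unclass(intra_j2)
  m[seq_len(n1), n1 + seq_len(n2)] <- unclass(inter)
  m[n1 + seq_len(n2), seq_len(n1)] <- t(unclass(inter))
  labels <- c(rownames(intra_j1), rownames(intra_j2))
  if (is.null(labels) || length(labels) != n1 + n2) labels <- NULL
  .new_adjacency(m, threshold, blocks = c(n1, n2), labels = labels)
}

#' Extract intra- and inter-brain blocks of a hyperbrain matrix
#'
#' @param adj A hyperbrain `adjacency_matrix` (with a block map).
#' @return List with `intra_J1`, `intra_J2` (single-brain adjacency
#'   matrices) and `inter` (the `n1 x n2` block, returned once).
#' @export
extract_blocks <- function(adj) {
  if (!.is_hyper(adj)) stop("not a hyperbrain matrix (no block map)")
  b <- attr(adj, "blocks"); n1 <- b[1]; n2 <- b[2]
  m <- unclass(adj)
  list(intra_J1 = .new_adjacency(m[seq_len(n1), seq_len(n1)],
                                 attr(adj, "threshold"),
                                 labels = rownames(m)[seq_len(n1)]),
       intra_J2 = .new_adjacency(m[n1 + seq_len(n2), n1 + seq_len(n2)],
                                 attr(adj, "threshold"),
                                 labels = rownames(m)[n1 + seq_len(n2)]),
       inter = m[seq_len(n1), n1 + seq_len(n2), drop = FALSE])
}

#' Number of edges of an adjacency matrix
#'
#' Counts edges over the off-diagonal upper triangle (self-connections on
#' the diagonal never count).
#' @param adj An `adjacency_matrix` or plain 0/1 matrix.
#' @export
n_edges <- function(adj) .n_edges(adj)

# igraph view with self-connections stripped
.as_graph <- function(adj) {
  m <- unclass(adj)
  diag(m) <- 0
  igraph::graph_from_adjacency_matrix(m, mode = "undirected")
}
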