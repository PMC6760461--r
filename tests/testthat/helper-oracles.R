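# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately avoid the package's own code paths.

# Floyd-Warshall all-pairs shortest paths; mean over reachable pairs
oracle_path_length <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  d[m == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

# mean local clustering by explicit neighbor-pair counting
oracle_clustering <- function(m) {
  n <- nrow(m)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(m[v, ] == 1)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    cc[v] <- mean(m[cbind(pairs[1, ], pairs[2, ])])
  }
  mean(cc)
}

# random simple graph as a plain 0/1 matrix with empty diagonal
rand_adj <- function(n, p = 0.4) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  m[up] <- as.numeric(stats::runif(sum(up)) < p)
  m + t(m)
}

# adjacency matrix from an explicit edge list over n nodes
adj_from_edges <- function(n, edges) {
  m <- matrix(0, n, n)
  for (e in edges) {
    m[e[1], e[2]] <- 1
    m[e[2], e[1]] <- 1
  }
  m
}

# minimal source_trial without going through the simulator
toy_trial <- function(nroi = 26, fs = 64, dur = 10, condition = "SOLO",
                      value = NULL) {
  n <- round(fs * dur)
  data <- if (is.null(value))
    array(stats::rnorm(nroi * 3 * n), dim = c(nroi, 3, n))
  else array(value, dim = c(nroi, 3, n))
  structure(list(data = data, sampling_rate = fs,
                 roi_labels = paste0("R", seq_len(nroi)),
                 session_id = "S1", juggler_id = "J1",
                 condition = condition, trial_index = 1L),
            class = "source_trial")
}

# degree sequence helpers for surrogate checks
intra_degrees <- function(m, idx) sort(rowSums(m[idx, idx]))
inter_degrees <- function(m, idx1, idx2)
  list(sort(rowSums(m[idx1, idx2])), sort(colSums(m[idx1, idx2])))

# precision / recall of a binarized matrix against a set of true pairs
recovery_scores <- function(adj, true_pairs, n) {
  truth <- matrix(FALSE, n, n)
  truth[cbind(true_pairs$i, true_pairs$j)] <- TRUE
  truth <- truth | t(truth)
  pred <- unclass(adj) == 1
  diag(pred) <- FALSE
  ut <- upper.tri(pred)
  tp <- sum(pred[ut] & truth[ut])
  fp <- sum(pred[ut] & !truth[ut])
  fn <- sum(!pred[ut] & truth[ut])
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}
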