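#' Characteristic path length
#'
#' Mean shortest-path length over all reachable node pairs.  Unreachable
#' pairs are excluded from the average: binary thresholded brain networks
#' can fragment, and excluding infinite paths keeps the normalized global
#' efficiency finite.
#'
#' @param adj An `adjacency_matrix` or 0/1 matrix (at least 2 nodes).
#' @return Mean shortest-path length (steps).
#' @export
characteristic_path_length <- function(adj) {
  if (nrow(adj) < 2) stop("at least two nodes required")
  if (.n_edges(adj) == 0) stop("path length undefined for an empty graph")
  d <- igraph::distances(.as_graph(adj))
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' Mean clustering coefficient (unnormalized)
#'
#' Average over nodes of the fraction of a node's neighbor pairs that are
#' themselves connected; nodes of degree < 2 contribute 0.
#'
#' @param adj An `adjacency_matrix` or 0/1 matrix (at least 3 nodes).
#' @return Mean local clustering coefficient.
#' @export
mean_clustering_coefficient <- function(adj) {
  if (nrow(adj) < 3) stop("at least three nodes required")
  igraph::transitivity(.as_graph(adj), type = "localaverage",
                       isolates = "zero")
}

#' Degree-preserving surrogate ensemble
#'
#' Generates `n` surrogate networks by double-edge swaps that preserve the
#' degree sequence exactly; on hyperbrain input, intra-J1, intra-J2 and
#' inter-brain edges each rewire only within their own class, so the intra-
#' and inter-brain degree sequences are preserved separately.  With
#' `kind = "random"` every admissible swap is accepted (Maslov-Sneppen
#' randomization); with `kind = "lattice"` a swap is accepted only when it
#' does not increase the distance of the edges from a banded ring-lattice
#' ordering of the nodes (latticization).  Ensemble summaries report the
#' mean characteristic path length and mean clustering coefficient.
#'
#' @param adj An `adjacency_matrix`.
#' @param kind `"random"` or `"lattice"`.
#' @param n Number of surrogates (study default 100).
#' @param attempts_per_edge Attempted swaps per edge per surrogate.
#' @param seed Optional seed for reproducibility.
#' @return A `surrogate_ensemble`: list with `kind`, `L_mean`, `C_mean`,
#'   per-surrogate `L` and `C`, and the surrogate adjacency matrices.
#' @export
generate_surrogates <- function(adj, kind = c("random", "lattice"), n = 100,
                                attempts_per_edge = 10, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  blocks <- attr(adj, "blocks")
  nn <- nrow(adj)
  brain <- if (is.null(blocks)) rep(1L, nn)
  else rep(c(1L, 2L), times = blocks)
  m <- unclass(adj)
  storage.mode(m) <- "integer"
  surr <- vector("list", n)
  L <- numeric(n); C <- numeric(n)
  for (k in seq_len(n)) {
    s <- rewire_blocks_cpp(m, brain, kind == "lattice", attempts_per_edge)
    surr[[k]] <- s
    L[k] <- characteristic_path_length(s)
    C[k] <- mean_clustering_coefficient(s)
  }
  structure(list(kind = kind, n = n, L = L, C = C,
                 L_mean = mean(L), C_mean = mean(C),
                 attempts_per_edge = attempts_per_edge,
                 surrogates = surr),
            class = "surrogate_ensemble")
}

.clip01 <- function(x) min(max(x, 0), 1)

#' Normalized global efficiency
#'
#' Compares the observed characteristic path length with the mean path
#' length of degree-preserving random (and, for the interpolation
#' convention, lattice) surrogates.  Under the default ratio convention
#' `G = L_random / L_observed`: 1 when the network is as efficiently wired
#' as its randomized counterparts, smaller for lattice-like long paths.
#' Values are clipped to `[0, 1]`, as occasional excursions occur in very
#' sparse or dense networks.
#'
#' @param adj An `adjacency_matrix` (or give `L_obs` directly).
#' @param rand,latt `surrogate_ensemble`s of the same network.
#' @param convention `"ratio"` (default) or `"interpolation"`
#'   (`(L_latt - L) / (L_latt - L_rand)`).
#' @param L_obs Optional pre-computed observed path length.
#' @return Normalized global efficiency in `[0, 1]`.
#' @export
normalized_global_efficiency <- function(adj = NULL, rand, latt = NULL,
                                         convention = c("ratio",
                                                        "interpolation"),
                                         L_obs = NULL) {
  convention <- match.arg(convention)
  if (is.null(L_obs)) L_obs <- characteristic_path_length(adj)
  if (convention == "ratio") return(.clip01(rand$L_mean / L_obs))
  if (is.null(latt)) stop("interpolation convention needs a lattice ensemble")
  den <- latt$L_mean - rand$L_mean
  if (abs(den) < 1e-12) stop("degenerate ensembles: L_latt equals L_rand")
  .clip01((latt$L_mean - L_obs) / den)
}

#' Normalized clustering coefficient
#'
#' Under the default ratio convention `C = C_observed / C_lattice`: 1 when
#' clustering reaches the lattice surrogates' level, near 0 for random-like
#' networks.  Clipped to `[0, 1]`.
#'
#' @inheritParams normalized_global_efficiency
#' @param C_obs Optional pre-computed observed clustering.
#' @return Normalized clustering in `[0, 1]`.
#' @export
normalized_clustering <- function(adj = NULL, rand = NULL, latt,
                                  convention = c("ratio", "interpolation"),
                                  C_obs = NULL) {
  convention <- match.arg(convention)
  if (is.null(C_obs)) C_obs <- mean_clustering_coefficient(adj)
  if (convention == "ratio") {
    if (latt$C_mean <= 0) stop("lattice ensemble has zero mean clustering")
    return(.clip01(C_obs / latt$C_mean))
  }
  if (is.null(rand)) stop("interpolation convention needs a random ensemble")
  den <- latt$C_mean - rand$C_mean
  if (abs(den) < 1e-12) stop("degenerate ensembles: C_latt equals C_rand")
  .clip01((C_obs - rand$C_mean) / den)
}

#' Small-world index
#'
#' Product of the normalized global efficiency and the normalized
#' clustering coefficient; 1 only when the network jointly shows
#' random-like path lengths and lattice-like clustering.
#'
#' @param G,C Normalized efficiency and clustering in `[0, 1]`.
#' @export
small_world_index <- function(G, C) {
  stopifnot(G >= 0, G <= 1, C >= 0, C <= 1)
  G * C
}

#' Connection density
#'
#' Edges as a proportion of all possible edges, `n(n-1)/2` (325 for a
#' 26-node intra-brain network, 1326 for a 52-node hyperbrain network).
#'
#' @param adj An `adjacency_matrix`.
#' @export
connection_density <- function(adj) {
  n <- nrow(adj)
  .n_edges(adj) / (n * (n - 1) / 2)
}

#' Intra-brain / inter-brain connection ratio
#'
#' Total number of intra-brain edges of both members divided by the number
#' of inter-brain edges.  With zero inter-brain edges the ratio is
#' undefined and returned as `NA` (flagged, with a warning) rather than
#' infinity, so that aggregation can skip it.
#'
#' @param adj A hyperbrain `adjacency_matrix`.
#' @export
intra_inter_ratio <- function(adj) {
  bl <- extract_blocks(adj)
  inter <- sum(bl$inter)
  intra <- .n_edges(bl$intra_J1) + .n_edges(bl$intra_J2)
  if (inter == 0) {
    warning("no inter-brain edges: IIR undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  intra / inter
}

#' All global network measures for one network
#'
#' Convenience wrapper computing L, raw C, surrogate-normalized G and C,
#' SWI, density and (for hyperbrain input) IIR with a fresh pair of
#' surrogate ensembles.
#'
#' @param adj An `adjacency_matrix`.
#' @param n_surrogates Surrogates per ensemble.
#' @param convention Normalization convention, see
#'   [normalized_global_efficiency()].
#' @param seed Optional seed.
#' @return One-row tibble with the measures.
#' @export
network_metrics <- function(adj, n_surrogates = 100,
                            convention = "ratio", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rand <- generate_surrogates(adj, "random", n = n_surrogates)
  latt <- generate_surrogates(adj, "lattice", n = n_surrogates)
  L <- characteristic_path_length(adj)
  C_raw <- mean_clustering_coefficient(adj)
  G <- normalized_global_efficiency(rand = rand, latt = latt,
                                    convention = convention, L_obs = L)
  C <- normalized_clustering(rand = rand, latt = latt,
                             convention = convention, C_obs = C_raw)
  out <- tibble(L = L, C_raw = C_raw, G = G, C = C,
                SWI = small_world_index(G, C), D = connection_density(adj))
  if (.is_hyper(adj)) out$IIR <- as.numeric(suppressWarnings(
    intra_inter_ratio(adj)))
  out
}
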