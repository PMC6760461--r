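# Edge-count asymmetry indices.  All four indices are of the form
# (A - B) / (A + B) over edge counts in two exclusive classes, bounded in
# [-1, +1]; edges straddling the two classes are excluded from both counts.
# A zero denominator returns 0 with attribute `no_classified_edges`, so
# session aggregation stays total.

.ratio_index <- function(a, b) {
  if (a + b == 0) return(structure(0, no_classified_edges = TRUE))
  (a - b) / (a + b)
}

.edge_list <- function(adj) {
  m <- unclass(adj)
  diag(m) <- 0
  which(upper.tri(m) & m == 1, arr.ind = TRUE)
}

#' Hemispheric lateralization of intra-brain connections
#'
#' `(R - L) / (R + L)` where `R` counts edges with both endpoints in the
#' right hemisphere and `L` edges with both endpoints in the left; +1 means
#' all classified intra-brain connections are right-hemispheric.
#'
#' @param adj A single-brain `adjacency_matrix` (26 nodes).
#' @param atlas Atlas for that brain with a `hemisphere` column.
#' @return Value in `[-1, 1]`.
#' @export
lateralization_intra <- function(adj, atlas = roi_atlas("J1")) {
  stopifnot(nrow(adj) == nrow(atlas))
  e <- .edge_list(adj)
  h <- atlas$hemisphere
  r <- sum(h[e[, 1]] == "right" & h[e[, 2]] == "right")
  l <- sum(h[e[, 1]] == "left" & h[e[, 2]] == "left")
  .ratio_index(r, l)
}

#' Regional asymmetry of intra-brain connections
#'
#' `(F - P) / (F + P)` where `F` counts edges with both endpoints in
#' fronto-limbic regions and `P` edges with both endpoints in
#' occipito-parietal regions; +1 means only fronto-limbic connections.
#'
#' @inheritParams lateralization_intra
#' @export
regional_asymmetry_intra <- function(adj, atlas = roi_atlas("J1")) {
  stopifnot(nrow(adj) == nrow(atlas))
  if (anyNA(atlas$region_class)) stop("atlas ROI lacking a region class")
  e <- .edge_list(adj)
  cl <- atlas$region_class
  f <- sum(cl[e[, 1]] == "fronto-limbic" & cl[e[, 2]] == "fronto-limbic")
  p <- sum(cl[e[, 1]] == "occipito-parietal" &
             cl[e[, 2]] == "occipito-parietal")
  .ratio_index(f, p)
}

# inter-brain attachment counts for one member of the dyad
.inter_attach <- function(adj, atlas, juggler, col) {
  if (!.is_hyper(adj)) stop("hyperbrain matrix required")
  if (!juggler %in% atlas$brain) stop("juggler not present in the matrix")
  bl <- extract_blocks(adj)
  inter <- bl$inter  # J1 rows x J2 columns
  side <- atlas[atlas$brain == juggler, ][[col]]
  counts <- if (juggler == unique(atlas$brain)[1]) rowSums(inter)
  else colSums(inter)
  tapply(counts, side, sum)
}

#' Hemispheric lateralization of one member's inter-brain connections
#'
#' Over inter-brain edges only: `(R - L) / (R + L)` where `R` (`L`) counts
#' edges attached to a right (left) hemisphere ROI of the chosen member.
#'
#' @param adj A hyperbrain `adjacency_matrix`.
#' @param atlas Dyad atlas (52 rows).
#' @param juggler `"J1"` or `"J2"`.
#' @export
lateralization_inter <- function(adj, atlas = roi_atlas(), juggler = "J1") {
  a <- .inter_attach(adj, atlas, juggler, "hemisphere")
  .ratio_index(.zero_na(a["right"]), .zero_na(a["left"]))
}

#' Regional asymmetry of one member's inter-brain connections
#'
#' As [lateralization_inter()] with fronto-limbic vs occipito-parietal
#' region classes in place of hemispheres.
#'
#' @inheritParams lateralization_inter
#' @export
regional_asymmetry_inter <- function(adj, atlas = roi_atlas(),
                                     juggler = "J1") {
  a <- .inter_attach(adj, atlas, juggler, "region_class")
  .ratio_index(.zero_na(a["fronto-limbic"]), .zero_na(a["occipito-parietal"]))
}

.zero_na <- function(x) if (is.na(x) || !length(x)) 0 else as.numeric(x)
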