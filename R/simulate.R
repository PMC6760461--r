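#' Simulation configuration for dyadic source signals
#'
#' Parameters of the synthetic dyadic hyperscanning generator.  Latent ROI
#' oscillators are narrowband-filtered Gaussian noise in `band` (so phase is
#' non-degenerate), lagged coupling between ROIs is planted through a ground
#' truth graph, each ROI's three-dimensional dipole moment is a fixed random
#' unit orientation times its latent signal plus isotropic broadband noise,
#' and optional zero-lag within-brain mixing emulates volume conduction.
#'
#' @param n_rois_per_brain ROIs per brain (atlas default 26).
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration Trial length in seconds (trials are later trimmed
#'   to their central 10 s).
#' @param n_trials Number of trials per condition.
#' @param center_freq Oscillator center frequency in Hz, inside `band`.
#' @param band Passband of the latent oscillators in Hz.
#' @param coupling_strength Default planted-edge strength in `[0, 1]`.
#' @param coupling_lag Default planted-edge lag in seconds; 0.025 s is about
#'   a quarter cycle at 10 Hz.
#' @param mixing_strength Zero-lag within-brain leakage in `[0, 1)`.
#' @param noise_sd Standard deviation of the additive broadband noise on
#'   each spatial component, relative to the unit-variance latent signal.
#' @param seed Integer seed; one global seed governs a per-trial stream so
#'   trials are reproducible independently.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_rois_per_brain = 26, sampling_rate = 1024,
                              trial_duration = 20, n_trials = 12,
                              center_freq = 10, band = c(8.5, 12),
                              coupling_strength = 0.9, coupling_lag = 0.025,
                              mixing_strength = 0, noise_sd = 0.1,
                              seed = 1L) {
  stopifnot(n_rois_per_brain >= 1, sampling_rate > 0, n_trials >= 1)
  if (sampling_rate <= 2 * band[2])
    stop("sampling_rate must exceed twice the highest simulated frequency")
  if (band[1] >= band[2]) stop("band must be an increasing interval")
  if (center_freq < band[1] || center_freq > band[2])
    stop("center_freq must lie inside band")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must be in [0, 1]")
  if (mixing_strength < 0 || mixing_strength >= 1)
    stop("mixing_strength must be in [0, 1)")
  if (trial_duration < 10) stop("trial_duration must be at least 10 s")
  structure(list(n_rois_per_brain = n_rois_per_brain,
                 sampling_rate = sampling_rate,
                 trial_duration = trial_duration, n_trials = n_trials,
                 center_freq = center_freq, band = band,
                 coupling_strength = coupling_strength,
                 coupling_lag = coupling_lag,
                 mixing_strength = mixing_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Ground-truth coupling graph
#'
#' A set of directed planted edges between ROI indices of the dyad (nodes
#' `1..n` are the first brain, `n+1..2n` the second).  Each target node may
#' have at most one generative parent: the target's latent oscillator is a
#' strength-weighted copy of the parent's, delayed by the edge lag, plus an
#' independent innovation scaled to preserve unit variance.
#'
#' @param from,to Integer node indices (no self-pairs; `to` unique).
#' @param lag Per-edge lag in seconds (recycled).
#' @param strength Per-edge strength in `[0, 1]` (recycled).
#' @return A `ground_truth` tibble with columns `from`, `to`, `lag`,
#'   `strength`.
#' @export
ground_truth <- function(from = integer(), to = integer(), lag = 0.025,
                         strength = 0.9) {
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(length(from) == length(to))
  g <- tibble(from = from, to = to,
              lag = rep_len(as.numeric(lag), length(from)),
              strength = rep_len(as.numeric(strength), length(from)))
  if (any(g$from == g$to)) stop("self-pairs are not allowed")
  if (anyDuplicated(g$to))
    stop("each node may have at most one generative parent")
  if (any(g$strength < 0 | g$strength > 1))
    stop("strength must be in [0, 1]")
  # forest check: following parents must terminate
  parent <- setNames(g$from, g$to)
  for (v in g$to) {
    seen <- integer(); u <- v
    while (!is.na(parent[as.character(u)])) {
      if (u %in% seen) stop("ground truth contains a cycle")
      seen <- c(seen, u)
      u <- parent[[as.character(u)]]
    }
  }
  class(g) <- c("ground_truth", class(g))
  g
}

#' Empty ground truth (fully independent sources)
#' @export
truth_none <- function() ground_truth()

#' Two-phase traveling-rhythm ground truth
#'
#' A shared rhythm propagating across the dyad: one reference node carries
#' the driving oscillator; every other node copies it with strength
#' `strength`, either in phase (lag 0) or shifted by `lag` (a quarter cycle
#' at the default 10 Hz).  All pairs straddling the two phase groups then
#' carry genuine lagged coupling, while pairs within a group are coupled at
#' zero lag only — exactly the component a lagged measure must ignore.  The
#' default split (38 of 52 nodes in phase) puts the lagged pairs at about
#' 40% of all pairs: the median of the mixed LPS values then sits inside
#' the zero-lag population, the MAD matches that population's deviation
#' scale, and the median + MAD threshold lands in the separation gap
#' between the zero-lag and lagged populations.
#'
#' @param n_nodes Total nodes across the dyad.
#' @param n_in_phase Number of nodes (including the reference) in the
#'   zero-lag group.
#' @param strength,lag Per-edge coupling parameters.
#' @param root Index of the reference node.
#' @return A `ground_truth` object.
#' @export
truth_two_phase <- function(n_nodes = 52, n_in_phase = 38, strength = 0.9,
                            lag = 0.025, root = 1L) {
  stopifnot(n_in_phase >= 1, n_in_phase <= n_nodes)
  others <- setdiff(seq_len(n_nodes), root)
  in_phase <- others[seq_len(n_in_phase - 1)]
  shifted <- setdiff(others, in_phase)
  ground_truth(from = rep(root, length(others)),
               to = c(in_phase, shifted),
               lag = c(rep(0, length(in_phase)), rep(lag, length(shifted))),
               strength = strength)
}

#' Phase-staggered multi-group ground truth
#'
#' Generalization of [truth_two_phase()]: nodes are assigned round-robin to
#' `n_groups` phase groups; every node copies the reference oscillator with
#' lag `(group - 1) * lag_step`.  All pairs from different groups carry
#' genuine lagged coupling (for small `lag_step` all pairwise phase offsets
#' stay away from half a cycle), so the resulting networks contain
#' triangles and non-trivial clustering, unlike the bipartite two-phase
#' layout.  The default step of 1/64 s is exactly 16 samples at 1024 Hz.
#'
#' @param n_nodes Total nodes across the dyad.
#' @param n_groups Number of phase groups.
#' @param lag_step Lag increment per group in seconds.
#' @param strength Per-edge coupling strength.
#' @param root Reference node index.
#' @return A `ground_truth` object.
#' @export
truth_phase_groups <- function(n_nodes = 52, n_groups = 3,
                               lag_step = 1 / 64, strength = 0.9,
                               root = 1L) {
  others <- setdiff(seq_len(n_nodes), root)
  grp <- (seq_len(n_nodes) - 1L) %% n_groups  # root is group 0
  ground_truth(from = rep(root, length(others)), to = others,
               lag = grp[others] * lag_step, strength = strength)
}

# cumulative (strength, lag) from each node up to its root
.path_to_root <- function(truth, v) {
  s <- 1; l <- 0
  repeat {
    e <- which(truth$to == v)
    if (!length(e)) break
    s <- s * truth$strength[e]
    l <- l + truth$lag[e]
    v <- truth$from[e]
  }
  list(root = v, strength = s, lag = l)
}

#' Pairs with genuine lagged coupling implied by a ground truth
#'
#' Resolves the pairwise dependence implied by the generative forest: two
#' nodes sharing a common root are coupled with strength equal to the
#' product of the edge strengths along both paths and lag equal to the lag
#' difference.  A pair is reported as detectable by a lagged measure when
#' that strength is at least `min_strength` and the coupling has
#' non-negligible quadrature at the oscillator frequency (|sin(2 pi f lag)|
#' at least `min_quadrature`); zero-lag and half-cycle couplings are
#' excluded because their coherency is purely real.
#'
#' @param truth A [ground_truth()] object.
#' @param config A [simulation_config()] (for the center frequency).
#' @param min_strength,min_quadrature Detection floor parameters.
#' @return Tibble of unordered pairs `i < j` with implied `strength`, `lag`.
#' @export
detectable_pairs <- function(truth, config, min_strength = 0.25,
                             min_quadrature = 0.25) {
  nodes <- sort(unique(c(truth$from, truth$to)))
  if (!length(nodes)) return(tibble(i = integer(), j = integer(),
                                    strength = numeric(), lag = numeric()))
  info <- lapply(nodes, function(v) .path_to_root(truth, v))
  names(info) <- nodes
  out <- list()
  for (a in seq_along(nodes)) for (b in seq_len(a - 1L)) {
    pa <- info[[a]]; pb <- info[[b]]
    if (pa$root != pb$root) next
    s <- pa$strength * pb$strength
    # shared path segments cancel; for a forest with one root per tree the
    # product over both full paths is exact only when paths diverge at the
    # root, which holds for star-shaped truths; deeper trees share edges.
    l <- pa$lag - pb$lag
    q <- abs(sin(2 * pi * config$center_freq * l))
    if (s >= min_strength && q >= min_quadrature)
      out[[length(out) + 1L]] <- c(min(nodes[a], nodes[b]),
                                   max(nodes[a], nodes[b]), s, l)
  }
  if (!length(out)) return(tibble(i = integer(), j = integer(),
                                  strength = numeric(), lag = numeric()))
  m <- do.call(rbind, out)
  tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
         strength = m[, 3], lag = m[, 4])
}

# narrowband Gaussian noise, unit variance, via FFT brick-wall filtering;
# circularly stationary so integer-sample delays are exact circular shifts
.band_noise <- function(n, fs, band) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

.circshift <- function(x, k) {
  n <- length(x); k <- k %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[seq_len(n - k)])
}

.unit_sphere <- function(m) {
  v <- matrix(rnorm(3 * m), nrow = 3)
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

.trial_seed <- function(seed, trial_index)
  as.integer((as.numeric(seed) + 1000003 * trial_index) %% 2147483629)

.new_source_trial <- function(data, sampling_rate, roi_labels, session_id,
                              juggler_id, condition, trial_index) {
  structure(list(data = data, sampling_rate = sampling_rate,
                 roi_labels = roi_labels, session_id = session_id,
                 juggler_id = juggler_id, condition = condition,
                 trial_index = trial_index),
            class = "source_trial")
}

#' @export
print.source_trial <- function(x, ...) {
  cat(sprintf("<source_trial> %s %s %s trial %d: %d ROIs x 3 x %d samples @ %g Hz\n",
              x$session_id, x$juggler_id, x$condition, x$trial_index,
              dim(x$data)[1], dim(x$data)[3], x$sampling_rate))
  invisible(x)
}

#' Generate one dyadic trial of 3D source current densities
#'
#' Produces two [print.source_trial()]-class trials, one per brain, each an
#' `n_rois x 3 x samples` array.  Latent oscillators are built root-first
#' along the ground-truth forest: each coupled node is a strength-weighted,
#' integer-sample-delayed copy of its parent plus an independent innovation
#' scaled by `sqrt(1 - strength^2)`.  Requested lags are rounded to the
#' nearest sample (with a warning when rounding is material).  Orientation
#' vectors are drawn once per ROI from the session seed, so they are stable
#' across trials; everything else is drawn from a per-trial stream, so the
#' same `(seed, trial_index)` always regenerates identical data.
#'
#' @param config A [simulation_config()].
#' @param truth A [ground_truth()] object (node indices `1..2n`).
#' @param trial_index 1-based trial number.
#' @param session_id,condition Metadata carried on the trials.
#' @return List with elements `J1` and `J2`.
#' @export
generate_dyad_trial <- function(config, truth = truth_none(),
                                trial_index = 1L, session_id = "S1",
                                condition = "PAIRED") {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_rois_per_brain
  ntot <- 2L * n
  if (nrow(truth) && max(c(truth$from, truth$to)) > ntot)
    stop("ground truth references ROI beyond the dyad")
  fs <- config$sampling_rate
  nsamp <- round(config$trial_duration * fs)

  # session-level stream: fixed dipole orientations
  set.seed(config$seed)
  U <- .unit_sphere(ntot)

  set.seed(.trial_seed(config$seed, trial_index))
  lat <- matrix(NA_real_, nrow = ntot, ncol = nsamp)
  roots <- setdiff(seq_len(ntot), truth$to)
  for (v in roots) lat[v, ] <- .band_noise(nsamp, fs, config$band)
  pending <- truth
  rounded <- abs(truth$lag * fs - round(truth$lag * fs)) > 1e-9
  if (any(rounded))
    warning(sprintf("%d planted lag(s) not representable at %g Hz; rounded to the nearest sample",
                    sum(rounded), fs))
  while (nrow(pending)) {
    ready <- !is.na(lat[pending$from, 1])
    if (!any(ready)) stop("ground truth contains a cycle")
    for (e in which(ready)) {
      k <- pending$lag[e] * fs
      s <- pending$strength[e]
      innov <- .band_noise(nsamp, fs, config$band)
      lat[pending$to[e], ] <- s * .circshift(lat[pending$from[e], ],
                                             as.integer(round(k))) +
        sqrt(1 - s^2) * innov
    }
    pending <- pending[!ready, , drop = FALSE]
  }

  data <- array(0, dim = c(ntot, 3, nsamp))
  for (r in seq_len(ntot))
    data[r, , ] <- outer(U[, r], lat[r, ]) +
      config$noise_sd * matrix(rnorm(3 * nsamp), nrow = 3)

  atlas <- roi_atlas(c("J1", "J2"))
  labels <- atlas$node
  if (n != 26) labels <- c(paste0("J1_R", seq_len(n)), paste0("J2_R", seq_len(n)))
  t1 <- .new_source_trial(data[seq_len(n), , , drop = FALSE], fs,
                          labels[seq_len(n)], session_id, "J1", condition,
                          as.integer(trial_index))
  t2 <- .new_source_trial(data[n + seq_len(n), , , drop = FALSE], fs,
                          labels[n + seq_len(n)], session_id, "J2", condition,
                          as.integer(trial_index))
  if (config$mixing_strength > 0) {
    t1 <- apply_instantaneous_mixing(t1, config$mixing_strength)
    t2 <- apply_instantaneous_mixing(t2, config$mixing_strength)
  }
  list(J1 = t1, J2 = t2)
}

#' Zero-lag within-brain mixing (volume conduction surrogate)
#'
#' Replaces each ROI's 3D signal by a convex combination of itself and the
#' instantaneous average of all other ROIs of the same brain (rescaled to
#' the ROI's own RMS, so `mixing_strength` is the share of leaked signal).
#' Mixing is strictly within one brain and strictly zero-lag: it inflates
#' instantaneous dependence between ROIs while adding no lagged dependence,
#' which is the confound a lagged synchronization measure must reject.
#'
#' @param trial A `source_trial`.
#' @param mixing_strength Leakage share in `[0, 1)`; 0 returns the trial
#'   unchanged.
#' @return The mixed `source_trial`.
#' @export
apply_instantaneous_mixing <- function(trial, mixing_strength) {
  stopifnot(inherits(trial, "source_trial"))
  if (mixing_strength < 0 || mixing_strength >= 1)
    stop("mixing_strength must be in [0, 1)")
  if (mixing_strength == 0) return(trial)
  d <- trial$data
  nroi <- dim(d)[1]
  if (nroi < 2) return(trial)
  total <- apply(d, c(2, 3), sum)
  out <- d
  for (r in seq_len(nroi)) {
    own <- d[r, , ]
    m <- (total - own) / (nroi - 1)
    scale <- sqrt(mean(own^2)) / max(sqrt(mean(m^2)), 1e-300)
    out[r, , ] <- (1 - mixing_strength) * own + mixing_strength * scale * m
  }
  trial$data <- out
  trial
}

#' Export a ground truth as a labeled edge table
#'
#' @param truth A [ground_truth()].
#' @param atlas Atlas resolving node indices to labels (rows in node-index
#'   order, as from [roi_atlas()]).
#' @return Tibble with `from`, `to` (node labels), `lag`, `strength`.
#' @export
export_truth <- function(truth, atlas = roi_atlas()) {
  if (nrow(truth) && max(c(truth$from, truth$to)) > nrow(atlas))
    stop("ground truth references an ROI not present in the atlas")
  tibble(from = atlas$node[truth$from], to = atlas$node[truth$to],
         lag = truth$lag, strength = truth$strength)
}
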