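#' Phase-normalized Fourier 3-vectors of one window
#'
#' Transforms each spatial dimension of each ROI with a discrete Fourier
#' transform and normalizes, per ROI and frequency bin, the complex
#' 3-vector to unit Euclidean norm — factoring out amplitude so that only
#' phase information remains.  Frequency resolution is `1 / window` seconds
#' (0.5 Hz for the default 2 s windows).  Bins where the vector has
#' (numerically) zero amplitude cannot be normalized and are returned as
#' `NA` and flagged.
#'
#' @param x One window: a `3 x w` matrix (single ROI) or `nroi x 3 x w`
#'   array.
#' @param sampling_rate Sampling rate in Hz.
#' @return Complex array `3 x nfreq` (or `3 x nfreq x nroi`), frequencies
#'   `0 .. Nyquist` in attribute `"freq"`; attribute `"flagged"` marks
#'   zero-amplitude bins.
#' @export
normalized_spectra <- function(x, sampling_rate) {
  single <- length(dim(x)) == 2
  if (single) x <- array(x, dim = c(1, dim(x)))
  nroi <- dim(x)[1]; w <- dim(x)[3]
  nfreq <- floor(w / 2) + 1L
  freq <- (seq_len(nfreq) - 1) * sampling_rate / w
  out <- array(NA_complex_, dim = c(3, nfreq, nroi))
  flagged <- matrix(FALSE, nfreq, nroi)
  for (r in seq_len(nroi)) {
    X <- t(mvfft(t(x[r, , , drop = TRUE])))[, seq_len(nfreq), drop = FALSE]
    nrm <- sqrt(colSums(Mod(X)^2))
    zero <- nrm < 1e-290
    flagged[zero, r] <- TRUE
    nrm[zero] <- NA_real_
    out[, , r] <- sweep(X, 2, nrm, "/")
  }
  if (single) out <- out[, , 1]
  attr(out, "freq") <- freq
  attr(out, "flagged") <- flagged
  out
}

.band_bins <- function(freq, band, tol = 1e-9) {
  which(freq >= band[1] - tol & freq <= band[2] + tol)
}

#' Segment-averaged spectral covariances
#'
#' For every ROI and retained frequency bin, averages the outer product of
#' the phase-normalized 3-vector with its own conjugate transpose across
#' segments (auto-spectral covariance, Hermitian with unit trace), and for
#' every ROI pair the outer product of one ROI's vector with the conjugate
#' of the other's (cross-spectral covariance).  Segments flagged as
#' zero-amplitude at a bin are excluded from that bin's average.
#'
#' @param segments A `segment_set` from [segment_trial()].
#' @param band Frequency band in Hz whose bins are retained (`NULL` keeps
#'   all bins; the default keeps the alpha band used downstream).
#' @return A `spectral_covariance_set`: `auto` (`3 x 3 x nbin x nroi`),
#'   `cross` (`3 x 3 x nbin x nroi x nroi`, entry `[ , , b, i, j]` holding
#'   the mean of `v_i v_j^*`), `vectors` (`3 x nseg x nroi x nbin`),
#'   `freq`, `n_segments`.
#' @export
accumulate_covariances <- function(segments, band = c(8.5, 12)) {
  stopifnot(inherits(segments, "segment_set"))
  nseg <- length(segments$windows)
  if (nseg < 1) stop("at least one segment is required")
  sp1 <- normalized_spectra(segments$windows[[1]], segments$sampling_rate)
  freq <- attr(sp1, "freq")
  bins <- if (is.null(band)) seq_along(freq) else .band_bins(freq, band)
  if (!length(bins)) stop("band contains no frequency bins")
  nroi <- dim(segments$windows[[1]])[1]
  V <- array(NA_complex_, dim = c(3, nseg, nroi, length(bins)))
  for (s in seq_len(nseg)) {
    sp <- if (s == 1) sp1 else
      normalized_spectra(segments$windows[[s]], segments$sampling_rate)
    if (nroi == 1) sp <- array(sp, dim = c(3, length(freq), 1))
    V[, s, , ] <- aperm(sp[, bins, , drop = FALSE], c(1, 3, 2))
  }
  auto <- array(NA_complex_, dim = c(3, 3, length(bins), nroi))
  cross <- array(NA_complex_, dim = c(3, 3, length(bins), nroi, nroi))
  for (b in seq_along(bins)) for (i in seq_len(nroi)) {
    vi <- V[, , i, b, drop = FALSE]; dim(vi) <- c(3, nseg)
    ok_i <- !is.na(vi[1, ])
    if (!any(ok_i)) stop("no valid segments at a frequency bin")
    auto[, , b, i] <- vi[, ok_i, drop = FALSE] %*%
      Conj(t(vi[, ok_i, drop = FALSE])) / sum(ok_i)
    for (j in seq_len(nroi)) {
      vj <- V[, , j, b, drop = FALSE]; dim(vj) <- c(3, nseg)
      ok <- ok_i & !is.na(vj[1, ])
      cross[, , b, i, j] <- vi[, ok, drop = FALSE] %*%
        Conj(t(vj[, ok, drop = FALSE])) / sum(ok)
    }
  }
  structure(list(auto = auto, cross = cross, vectors = V,
                 freq = freq[bins], n_segments = nseg,
                 roi_labels = segments$roi_labels),
            class = "spectral_covariance_set")
}

# log-determinant of a Hermitian matrix with a relative ridge, via
# eigenvalues (base det() does not accept complex matrices)
.logdet_h <- function(M, ridge) {
  d <- ridge * mean(Re(diag(M)))
  ev <- eigen(M + d * diag(nrow(M)), symmetric = TRUE,
              only.values = TRUE)$values
  sum(log(pmax(ev, 1e-300)))
}

.f_pair <- function(V1, V2, keep, ridge) {
  ns <- length(keep)
  A <- V1[, keep, drop = FALSE] %*% Conj(t(V1[, keep, drop = FALSE])) / ns
  B <- V2[, keep, drop = FALSE] %*% Conj(t(V2[, keep, drop = FALSE])) / ns
  Cx <- V1[, keep, drop = FALSE] %*% Conj(t(V2[, keep, drop = FALSE])) / ns
  S <- rbind(cbind(A, Cx), cbind(Conj(t(Cx)), B))
  c(total = .logdet_h(A, ridge) + .logdet_h(B, ridge) - .logdet_h(S, ridge),
    inst = .logdet_h(Re(A), ridge) + .logdet_h(Re(B), ridge) -
      .logdet_h(Re(S), ridge))
}

#' Lagged phase synchronization between two ROIs at one frequency bin
#'
#' Determinant-based decomposition of the linear dependence between the two
#' phase-normalized 3-dimensional series: total dependence from the 6x6
#' Hermitian covariance, instantaneous (zero-lag) dependence from its real
#' part, lagged dependence as their difference.  Each F-measure maps to
#' `[0, 1]` as `1 - exp(-F)`.  Because both F estimates carry small-sample
#' bias, a leave-one-segment-out jackknife correction is applied by
#' default; near-singular covariances are stabilized by a ridge
#' proportional to the mean diagonal.
#'
#' @param covset A `spectral_covariance_set`.
#' @param i,j ROI indices.
#' @param bin Frequency bin index into `covset$freq`.
#' @param ridge Relative ridge (fraction of the mean diagonal).
#' @param jackknife Apply leave-one-segment-out debiasing.
#' @return List with `lagged` (clipped to `[0, 1]`), `lagged_raw`
#'   (unclipped, used for band averaging), `total`, `instantaneous`,
#'   `f_total`, `f_inst`.
#' @export
lps_pair <- function(covset, i, j, bin = 1L, ridge = 0.005,
                     jackknife = TRUE) {
  stopifnot(inherits(covset, "spectral_covariance_set"))
  V1 <- covset$vectors[, , i, bin, drop = FALSE]
  V2 <- covset$vectors[, , j, bin, drop = FALSE]
  ns <- dim(covset$vectors)[2]
  dim(V1) <- c(3, ns); dim(V2) <- c(3, ns)
  keep <- which(!is.na(V1[1, ]) & !is.na(V2[1, ]))
  if (length(keep) < 2) stop("fewer than two valid segments")
  f <- .f_pair(V1, V2, keep, ridge)
  if (jackknife && length(keep) > 2) {
    loo <- vapply(seq_along(keep), function(s)
      .f_pair(V1, V2, keep[-s], ridge), numeric(2))
    n <- length(keep)
    f <- n * f - (n - 1) * rowMeans(loo)
  }
  raw <- 1 - exp(-(f[["total"]] - f[["inst"]]))
  list(lagged = min(max(raw, 0), 1), lagged_raw = raw,
       total = 1 - exp(-f[["total"]]), instantaneous = 1 - exp(-f[["inst"]]),
       f_total = f[["total"]], f_inst = f[["inst"]])
}

#' Band-averaged lagged phase synchronization for all ROI pairs
#'
#' Arithmetic mean of the per-bin lagged values over all bins of the band
#' (inclusive endpoints).  The unclipped per-bin values are averaged and
#' the mean is then clipped to `[0, 1]`; clipping before averaging would
#' bias the null upward.
#'
#' @param covset A `spectral_covariance_set` restricted to (at least) the
#'   band of interest.
#' @param band Frequency band in Hz.
#' @param ridge,jackknife See [lps_pair()].
#' @return Symmetric matrix of band-averaged LPS values (diagonal `NA`).
#' @export
band_average_lps <- function(covset, band = c(8.5, 12), ridge = 0.005,
                             jackknife = TRUE) {
  bins <- .band_bins(covset$freq, band)
  if (!length(bins)) stop("band contains no frequency bins")
  nroi <- dim(covset$vectors)[3]
  out <- matrix(NA_real_, nroi, nroi)
  for (i in seq_len(nroi - 1)) for (j in (i + 1):nroi) {
    raw <- vapply(bins, function(b)
      lps_pair(covset, i, j, b, ridge, jackknife)$lagged_raw, numeric(1))
    out[i, j] <- out[j, i] <- min(max(mean(raw), 0), 1)
  }
  dimnames(out) <- list(covset$roi_labels, covset$roi_labels)
  out
}

#' Band-averaged LPS matrix for one trial (or a synchronized pair)
#'
#' Runs the full connectivity stage for a trial: segmentation, Fourier
#' transform, phase normalization, covariance averaging across segments,
#' per-bin lagged phase synchronization for every ROI pair, band
#' averaging.  For a SOLO trial (one brain) this yields a 26-node matrix
#' with 325 informative values; for a PAIRED trial (list of two
#' synchronized trials) a 52-node hyperbrain matrix with 1326 values, the
#' estimator being identical for intra- and inter-brain pairs.
#'
#' @param trials A single `source_trial` or a list of two synchronized
#'   trials (same sampling rate and sample count).
#' @param band Frequency band in Hz (default alpha, 8.5-12).
#' @param window,step Segmentation parameters in seconds.
#' @param ridge,jackknife Estimator parameters, see [lps_pair()].
#' @param use_compiled Use the compiled pair loop (identical results to the
#'   R reference path).
#' @return An `lps_matrix`: symmetric numeric matrix with node labels,
#'   attributes `band`, `n_segments`, `total` and `instantaneous`
#'   (band-averaged companion matrices), and `blocks` (`c(n1, n2)`) for the
#'   hyperbrain case.
#' @export
lps_matrix_for_trial <- function(trials, band = c(8.5, 12), window = 2,
                                 step = 1, ridge = 0.005, jackknife = TRUE,
                                 use_compiled = TRUE) {
  paired <- !inherits(trials, "source_trial")
  if (paired) {
    stopifnot(length(trials) == 2)
    t1 <- trials[[1]]; t2 <- trials[[2]]
    if (t1$sampling_rate != t2$sampling_rate)
      stop("paired trials have mismatched sampling rates")
    if (dim(t1$data)[3] != dim(t2$data)[3])
      stop("paired trials have mismatched sample counts")
    trial <- t1
    n1 <- dim(t1$data)[1]; n2 <- dim(t2$data)[1]
    comb <- array(NA_real_, dim = c(n1 + n2, 3, dim(t1$data)[3]))
    comb[seq_len(n1), , ] <- t1$data
    comb[n1 + seq_len(n2), , ] <- t2$data
    trial$data <- comb
    trial$roi_labels <- c(t1$roi_labels, t2$roi_labels)
  } else trial <- trials

  segs <- segment_trial(trial, window = window, step = step)
  cov <- accumulate_covariances(segs, band = band)
  bins <- .band_bins(cov$freq, band)
  nroi <- dim(cov$vectors)[3]
  nseg <- dim(cov$vectors)[2]

  if (use_compiled && !anyNA(cov$vectors)) {
    V <- array(cov$vectors[, , , bins, drop = FALSE],
               dim = c(3, nseg, nroi * length(bins)))
    # reorder slices to r + nroi * b layout (already the case: roi fastest)
    res <- lps_pairs_cpp(V, nroi, ridge, jackknife)
    raw <- 1 - exp(-(res$f_total - res$f_inst))
    tot <- 1 - exp(-res$f_total)
    ins <- 1 - exp(-res$f_inst)
    lps <- pmin(pmax(apply(raw, c(1, 2), mean), 0), 1)
    total <- pmin(pmax(apply(tot, c(1, 2), mean), 0), 1)
    inst <- pmin(pmax(apply(ins, c(1, 2), mean), 0), 1)
    diag(lps) <- NA_real_; diag(total) <- NA_real_; diag(inst) <- NA_real_
    dimnames(lps) <- list(trial$roi_labels, trial$roi_labels)
  } else {
    lps <- band_average_lps(cov, band, ridge, jackknife)
    total <- matrix(NA_real_, nroi, nroi); inst <- total
    for (i in seq_len(nroi - 1)) for (j in (i + 1):nroi) {
      vals <- vapply(bins, function(b) {
        p <- lps_pair(cov, i, j, b, ridge, jackknife)
        c(p$total, p$instantaneous)
      }, numeric(2))
      total[i, j] <- total[j, i] <- min(max(mean(vals[1, ]), 0), 1)
      inst[i, j] <- inst[j, i] <- min(max(mean(vals[2, ]), 0), 1)
    }
  }
  structure(lps, class = c("lps_matrix", "matrix"), band = band,
            n_segments = nseg, total = total, instantaneous = inst,
            blocks = if (paired) c(dim(trials[[1]]$data)[1],
                                   dim(trials[[2]]$data)[1]) else NULL)
}
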