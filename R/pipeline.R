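#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults set to
#' the study parameters: alpha band 8.5-12 Hz, 2 s windows stepped by 1 s
#' over the central 10 s of each trial, per-trial median + MAD
#' thresholding, ratio normalization against 100 random and 100 lattice
#' degree-preserving surrogates.
#'
#' @param band Analysis band in Hz.
#' @param window,step Segmentation parameters in seconds.
#' @param trim_duration Central interval retained per trial, seconds.
#' @param threshold_mode `"per-trial"` or `"pooled"`.
#' @param convention Surrogate normalization convention.
#' @param n_surrogates Surrogates per ensemble.
#' @param ridge,jackknife LPS estimator parameters, see [lps_pair()].
#' @param seed Master seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(8.5, 12), window = 2, step = 1,
                            trim_duration = 10,
                            threshold_mode = "per-trial",
                            convention = "ratio", n_surrogates = 100,
                            ridge = 0.005, jackknife = TRUE, seed = 1L) {
  if (band[1] >= band[2]) stop("band must be an increasing interval")
  structure(list(band = band, window = window, step = step,
                 trim_duration = trim_duration,
                 threshold_mode = threshold_mode, convention = convention,
                 n_surrogates = n_surrogates, ridge = ridge,
                 jackknife = jackknife, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate a complete multi-session study
#'
#' Generates SOLO and PAIRED trials for every session of a design.  PAIRED
#' trials carry a cross-brain two-phase coupling truth
#' ([truth_two_phase()]); SOLO trials couple ROIs within each brain only
#' (the same truth restricted to one brain).  Per-session seeds are
#' derived from the master seed.
#'
#' @param design Session design (see [default_session_design()]).
#' @param n_trials Trials per condition per session (kept small by
#'   default; the bundled design's retained trial counts can be used via
#'   `n_trials = NULL`).
#' @param config Base [simulation_config()]; its seed is overridden per
#'   session.
#' @return List of `source_trial`s for SOLO and of two-trial dyad lists
#'   for PAIRED, with a `design` attribute.
#' @export
simulate_study <- function(design = default_session_design(), n_trials = 2,
                           config = simulation_config()) {
  validate_design(design)
  sessions <- unique(design$session)
  out <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    row <- design[design$session == s, ]
    cfg <- config
    cfg$seed <- .trial_seed(config$seed, 7919L * si)
    n <- cfg$n_rois_per_brain
    n_solo <- if (is.null(n_trials)) min(row$solo_trials) else n_trials
    n_pair <- if (is.null(n_trials)) min(row$paired_trials) else n_trials
    # within-brain phase-staggered coupling for the SOLO condition
    intra1 <- truth_phase_groups(n_nodes = n,
                                 strength = cfg$coupling_strength)
    intra2 <- intra1
    intra2$from <- intra2$from + n
    intra2$to <- intra2$to + n
    solo_truth <- ground_truth(c(intra1$from, intra2$from),
                               c(intra1$to, intra2$to),
                               c(intra1$lag, intra2$lag),
                               c(intra1$strength, intra2$strength))
    # phase groups interleaved across both brains for the PAIRED condition
    pair_truth <- truth_phase_groups(n_nodes = 2 * n,
                                     strength = cfg$coupling_strength)
    for (k in seq_len(n_solo)) {
      dy <- generate_dyad_trial(cfg, solo_truth, trial_index = k,
                                session_id = s, condition = "SOLO")
      out[[length(out) + 1L]] <- dy$J1
      out[[length(out) + 1L]] <- dy$J2
    }
    for (k in seq_len(n_pair)) {
      dy <- generate_dyad_trial(cfg, pair_truth,
                                trial_index = 1000L + k,
                                session_id = s, condition = "PAIRED")
      out[[length(out) + 1L]] <- structure(dy, class = "dyad_trial")
    }
  }
  attr(out, "design") <- design
  out
}

# graph measures with per-matrix failure tolerance: a degenerate network
# (e.g. an edgeless block) yields NA measures and a message, and the
# pipeline continues with the remaining trials
.safe_network_metrics <- function(adj, n_surrogates, convention, where) {
  tryCatch(network_metrics(adj, n_surrogates = n_surrogates,
                           convention = convention),
           error = function(e) {
             message(sprintf("graph measures skipped for %s: %s", where,
                             conditionMessage(e)))
             tibble(L = NA_real_, C_raw = NA_real_, G = NA_real_,
                    C = NA_real_, SWI = NA_real_, D = connection_density(adj),
                    IIR = NA_real_)
           })
}

# per-trial measures for one single-brain adjacency matrix
.intra_measure_rows <- function(adj, atlas1, session, condition, unit,
                                trial, n_surrogates, convention) {
  gm <- .safe_network_metrics(adj, n_surrogates, convention,
                              sprintf("%s %s %s t%s", session, condition,
                                      unit, trial))
  tibble(session = session, condition = condition, unit = unit,
         trial = trial,
         measure = c("G", "C", "SWI", "D", "Lat_intra", "RA_intra",
                     "L", "C_raw"),
         value = c(gm$G, gm$C, gm$SWI, gm$D,
                   as.numeric(lateralization_intra(adj, atlas1)),
                   as.numeric(regional_asymmetry_intra(adj, atlas1)),
                   gm$L, gm$C_raw))
}

#' Run the full analysis pipeline
#'
#' Takes a set of trials (e.g. from [simulate_study()]), and for every
#' trial: validates, trims to the central interval, computes the
#' band-averaged LPS matrix, binarizes with the median + MAD threshold,
#' and derives graph and asymmetry measures (intra-brain measures from
#' SOLO matrices and from the intra blocks of PAIRED hyperbrain matrices;
#' hyperbrain and inter-brain measures from the full 52-node matrix).
#' Per-trial metrics are aggregated to session means and fed into the
#' session-level statistics: three-factor mixed ANOVAs per intra-brain
#' measure, two-factor ANOVAs within each dyad group, two-factor ANOVAs on
#' the inter-brain asymmetries, and independent t tests on the hyperbrain
#' measures between dyad groups.
#'
#' @param trials Trial list from [simulate_study()] (or assembled
#'   manually: `source_trial`s for SOLO, `dyad_trial` pairs for PAIRED).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: per-trial LPS and adjacency CSVs,
#'   the metrics tables and statistics are written there.
#' @param design Session design; defaults to the `design` attribute of
#'   `trials`.
#' @return List with `trial_metrics`, `session_metrics`, `anova`
#'   (per-measure three-factor tables), `anova_by_group`, `anova_inter`,
#'   `hyperbrain_tests`, and the `config`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(),
                         out_dir = NULL, design = attr(trials, "design")) {
  set.seed(config$seed)
  atlas1 <- roi_atlas("J1")
  atlas2 <- roi_atlas(c("J1", "J2"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (tr in trials) {
    if (inherits(tr, "dyad_trial")) {
      t1 <- trim_trial(validate_trial(tr[[1]], atlas1), config$trim_duration)
      t2 <- trim_trial(validate_trial(tr[[2]], atlas1), config$trim_duration)
      lps <- lps_matrix_for_trial(list(t1, t2), band = config$band,
                                  window = config$window, step = config$step,
                                  ridge = config$ridge,
                                  jackknife = config$jackknife)
      adj <- binarize(lps, mode = config$threshold_mode)
      ses <- t1$session_id; k <- t1$trial_index
      gm <- .safe_network_metrics(adj, config$n_surrogates,
                                  config$convention,
                                  sprintf("%s PAIRED hyper t%s", ses, k))
      rows[[length(rows) + 1L]] <- tibble(
        session = ses, condition = "PAIRED", unit = "HYPER", trial = k,
        measure = c("G", "C", "SWI", "D", "IIR", "L", "C_raw"),
        value = c(gm$G, gm$C, gm$SWI, gm$D, gm$IIR, gm$L, gm$C_raw))
      bl <- extract_blocks(adj)
      rows[[length(rows) + 1L]] <- .intra_measure_rows(
        bl$intra_J1, atlas1, ses, "PAIRED", "J1", k,
        config$n_surrogates, config$convention)
      rows[[length(rows) + 1L]] <- .intra_measure_rows(
        bl$intra_J2, atlas1, ses, "PAIRED", "J2", k,
        config$n_surrogates, config$convention)
      for (jg in c("J1", "J2"))
        rows[[length(rows) + 1L]] <- tibble(
          session = ses, condition = "PAIRED", unit = jg, trial = k,
          measure = c("Lat_inter", "RA_inter"),
          value = c(as.numeric(lateralization_inter(adj, atlas2, jg)),
                    as.numeric(regional_asymmetry_inter(adj, atlas2, jg))))
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_PAIRED_t%d", ses, k))
        write_matrix_csv(round(unclass(lps), 6), paste0(stem, "_lps.csv"))
        write_matrix_csv(unclass(adj), paste0(stem, "_adj.csv"))
      }
    } else {
      t1 <- trim_trial(validate_trial(tr, atlas1), config$trim_duration)
      lps <- lps_matrix_for_trial(t1, band = config$band,
                                  window = config$window, step = config$step,
                                  ridge = config$ridge,
                                  jackknife = config$jackknife)
      adj <- binarize(lps, mode = config$threshold_mode)
      rows[[length(rows) + 1L]] <- .intra_measure_rows(
        adj, atlas1, t1$session_id, t1$condition, t1$juggler_id,
        t1$trial_index, config$n_surrogates, config$convention)
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_%s_%s_t%d", t1$session_id,
                                           t1$juggler_id, t1$condition,
                                           t1$trial_index))
        write_matrix_csv(round(unclass(lps), 6), paste0(stem, "_lps.csv"))
        write_matrix_csv(unclass(adj), paste0(stem, "_adj.csv"))
      }
    }
  }
  trial_metrics <- do.call(rbind, rows)
  session_metrics <- aggregate_session_means(trial_metrics, design)

  intra_measures <- c("G", "C", "SWI", "D", "Lat_intra", "RA_intra")
  anova <- list(); anova_by_group <- list(); anova_inter <- list()
  if (!is.null(design)) {
    for (m in intra_measures) {
      sub <- session_metrics[session_metrics$measure == m &
                               session_metrics$unit %in% c("J1", "J2"), ]
      anova[[m]] <- tryCatch(mixed_anova(sub), error = function(e) NULL)
      for (g in unique(sub$matched)) {
        key <- paste0(m, if (g) "_matched" else "_unmatched")
        anova_by_group[[key]] <- tryCatch(
          mixed_anova(sub[sub$matched == g, ], between = NULL),
          error = function(e) NULL)
      }
    }
    for (m in c("Lat_inter", "RA_inter")) {
      sub <- session_metrics[session_metrics$measure == m, ]
      anova_inter[[m]] <- tryCatch(
        mixed_anova(sub, within = "skill"), error = function(e) NULL)
    }
  }
  hyper <- session_metrics[session_metrics$unit == "HYPER", ]
  hyper_tests <- if (!is.null(design) && nrow(hyper))
    tryCatch(hyperbrain_group_ttests(hyper), error = function(e) NULL)
  else NULL

  out <- list(trial_metrics = trial_metrics,
              session_metrics = session_metrics, anova = anova,
              anova_by_group = anova_by_group, anova_inter = anova_inter,
              hyperbrain_tests = hyper_tests, config = config)
  if (!is.null(out_dir)) {
    write.csv(trial_metrics, file.path(out_dir, "trial_metrics.csv"),
              row.names = FALSE)
    write.csv(session_metrics, file.path(out_dir, "session_metrics.csv"),
              row.names = FALSE)
    an <- do.call(rbind, lapply(names(anova), function(m)
      if (!is.null(anova[[m]])) cbind(measure = m, anova[[m]])))
    if (!is.null(an))
      write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
    jsonlite::write_json(list(config = unclass(config)),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
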