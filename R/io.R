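#' Bundled dyad session design
#'
#' The seven-session dyadic design used throughout the package examples:
#' two members per session (J1 always the less experienced), years of
#' individual experience, the matched-dyad flag (experience difference
#' of at most 3 years), and retained SOLO / PAIRED trial counts.
#'
#' @return Tibble with one row per session member.
#' @export
default_session_design <- function() {
  tibble(
    session = rep(sprintf("S%d", 1:7), each = 2),
    juggler = rep(c("J1", "J2"), times = 7),
    subject = c("Subj4", "Subj3", "Subj6", "Subj5", "Subj7", "Subj8",
                "Subj10", "Subj9", "Subj11", "Subj12", "Subj2", "Subj13",
                "Subj10", "Subj1"),
    handedness = c("right", "right", "right", "right", "right", "right",
                   "left", "right", "right", "right", "right", "right",
                   "left", "mixed"),
    years_experience = c(16, 19, 3, 7, 3, 7, 8, 10, 5, 8, 6, 15, 8, 14),
    matched = rep(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
                  each = 2),
    solo_trials = c(8, 9, 9, 12, 9, 10, 8, 12, 10, 10, 7, 10, 9, 8),
    paired_trials = c(4, 4, 3, 3, 6, 6, 6, 6, 4, 4, 3, 3, 8, 8)
  )
}

#' Validate a session design table
#'
#' Checks the two-members-per-session structure, that J1 is the less
#' experienced member, and that the matched flag is consistent with the
#' 3-year experience-difference rule.
#'
#' @param design Tibble as from [default_session_design()].
#' @return The design, invisibly, or an error.
#' @export
validate_design <- function(design) {
  for (s in unique(design$session)) {
    d <- design[design$session == s, ]
    if (nrow(d) != 2 || !setequal(d$juggler, c("J1", "J2")))
      stop("each session needs exactly jugglers J1 and J2")
    e1 <- d$years_experience[d$juggler == "J1"]
    e2 <- d$years_experience[d$juggler == "J2"]
    if (e1 >= e2) stop("J1 must be the less experienced member")
    if (any(d$matched != (abs(e2 - e1) <= 3)))
      stop("matched flag inconsistent with the 3-year rule")
  }
  invisible(design)
}

#' Write source trials to a plain-text directory layout
#'
#' Each trial becomes one CSV (`samples x (3 * nroi)` with `label.x/.y/.z`
#' headers) named `<session>_<juggler>_<condition>_t<k>.csv`, plus a
#' `meta.json` sidecar holding the sampling rate and ROI labels.
#'
#' @param trials List of `source_trial`s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file names.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  files <- vapply(trials, function(tr) {
    stem <- sprintf("%s_%s_%s_t%d", tr$session_id, tr$juggler_id,
                    tr$condition, tr$trial_index)
    nroi <- dim(tr$data)[1]
    flat <- matrix(aperm(tr$data, c(3, 2, 1)), ncol = 3 * nroi)
    colnames(flat) <- paste0(rep(tr$roi_labels, each = 3), ".",
                             c("x", "y", "z"))
    f <- file.path(dir, paste0(stem, ".csv"))
    write.csv(flat, f, row.names = FALSE)
    meta[[stem]] <<- list(sampling_rate = tr$sampling_rate,
                          roi_labels = tr$roi_labels,
                          session_id = tr$session_id,
                          juggler_id = tr$juggler_id,
                          condition = tr$condition,
                          trial_index = tr$trial_index)
    f
  }, character(1))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(files)
}

#' Read source trials from a directory written by [write_trials()]
#'
#' @param dir Directory containing trial CSVs and `meta.json`.
#' @return List of `source_trial`s.
#' @export
read_trials <- function(dir) {
  mf <- file.path(dir, "meta.json")
  if (!file.exists(mf)) stop("missing meta.json in ", dir)
  meta <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  lapply(names(meta), function(stem) {
    m <- meta[[stem]]
    f <- file.path(dir, paste0(stem, ".csv"))
    if (!file.exists(f)) stop("missing trial file ", f)
    flat <- as.matrix(read.csv(f, check.names = FALSE))
    nroi <- length(m$roi_labels)
    if (ncol(flat) != 3 * nroi) stop("wrong dimensionality in ", f)
    data <- aperm(array(flat, dim = c(nrow(flat), 3, nroi)), c(3, 2, 1))
    .new_source_trial(data, m$sampling_rate, m$roi_labels, m$session_id,
                      m$juggler_id, m$condition, as.integer(m$trial_index))
  })
}

#' Write a labeled matrix (LPS or adjacency) as CSV
#' @param m Matrix with dimnames.
#' @param path Output file.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(unclass(m), path, row.names = TRUE)
  invisible(path)
}

#' Export a binary network as GraphML for external inspection
#' @param adj An `adjacency_matrix`.
#' @param path Output file.
#' @export
export_graphml <- function(adj, path) {
  igraph::write_graph(.as_graph(adj), path, format = "graphml")
  invisible(path)
}
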