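#' @importFrom tibble tibble as_tibble
NULL

# 13 cortical ROIs per hemisphere with MNI centroid coordinates.  The same
# set is mirrored across hemispheres and, for dyadic analyses, across the
# two brains of a pair.
.roi_table <- function() {
  labs <- c("SMA", "SPL", "SPFC", "OFC", "APFC", "LPFC", "ACC", "PCC",
            "PHG", "IPC", "FUS", "PVC", "INS")
  long <- c("SensoriMotor Area", "Superior Parietal Lobule",
            "Superior PreFrontal Cortex", "OrbitoFrontal Cortex",
            "Anterior PreFrontal Cortex", "Lateral PreFrontal Cortex",
            "Anterior Cingulate Cortex", "Posterior Cingulate Cortex",
            "ParaHippocampal Gyrus", "Inferior Parietal Cortex",
            "Fusiform cortex", "Primary Visual Cortex", "INSULA")
  x <- c(40, 15, 25, 25, 25, 50, 5, 5, 20, 45, 40, 15, 40)
  y <- c(-25, -60, 0, 35, 45, 20, 20, -50, -20, -45, -65, -85, -10)
  z <- c(50, 50, 50, -15, 25, 15, 25, 20, -20, 35, 0, 0, 10)
  tibble(
    label = rep(labs, each = 2),
    extended_label = rep(long, each = 2),
    hemisphere = rep(c("left", "right"), times = length(labs)),
    x = rep(x, each = 2) * rep(c(-1, 1), times = length(labs)),
    y = rep(y, each = 2),
    z = rep(z, each = 2)
  )
}

#' Default fronto-limbic / occipito-parietal region classification
#'
#' Reads the region-class map shipped with the package (a small JSON config
#' mapping each ROI label to either `"fronto-limbic"` or
#' `"occipito-parietal"`).  The map is a configuration file rather than a
#' hard-coded constant so that alternative classifications can be supplied
#' to [roi_atlas()].
#'
#' @param path Path to a JSON file with `fronto_limbic` and
#'   `occipito_parietal` character arrays of ROI labels.
#' @return Named character vector: ROI label -> region class.
#' @export
default_region_classes <- function(path = system.file("extdata",
                                                      "region_classes.json",
                                                      package = "hyperlps")) {
  cfg <- jsonlite::fromJSON(path)
  c(setNames(rep("fronto-limbic", length(cfg$fronto_limbic)),
             cfg$fronto_limbic),
    setNames(rep("occipito-parietal", length(cfg$occipito_parietal)),
             cfg$occipito_parietal))
}

#' ROI atlas for one brain or a dyad
#'
#' Builds the atlas of 26 cortical regions of interest per brain (13 labels
#' x 2 hemispheres) with MNI centroid coordinates, hemisphere, brain
#' membership, and a fronto-limbic vs occipito-parietal region class.  For a
#' dyad the atlas spans 52 ROIs with node names prefixed by the brain id
#' (e.g. `"J1_SMA_L"`); by convention `J1` is the less experienced member of
#' the pair.
#'
#' @param brain_ids Character vector of brain identifiers; `c("J1", "J2")`
#'   for a hyperbrain atlas or a single id for one brain.
#' @param region_classes Named character vector mapping ROI labels to region
#'   classes (see [default_region_classes()]).
#' @return A tibble with one row per ROI: `node`, `label`, `hemisphere`,
#'   `brain`, `region_class`, `x`, `y`, `z`.
#' @examples
#' atlas <- roi_atlas("J1")
#' nrow(atlas)  # 26
#' @export
roi_atlas <- function(brain_ids = c("J1", "J2"),
                      region_classes = default_region_classes()) {
  stopifnot(length(brain_ids) >= 1, !anyDuplicated(brain_ids))
  base <- .roi_table()
  missing <- setdiff(base$label, names(region_classes))
  if (length(missing))
    stop("no region class for ROI label(s): ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(brain_ids, function(b) {
    a <- base
    a$brain <- b
    a
  }))
  hemi <- ifelse(out$hemisphere == "left", "L", "R")
  out$node <- if (length(brain_ids) > 1)
    paste0(out$brain, "_", out$label, "_", hemi)
  else paste0(out$label, "_", hemi)
  out$region_class <- unname(region_classes[out$label])
  as_tibble(out[, c("node", "label", "hemisphere", "brain", "region_class",
                    "x", "y", "z")])
}
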