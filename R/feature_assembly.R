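#' Canonical feature names and feature-type map
#'
#' The 452 canonical feature names, in the fixed assembly order: the OCT LBP
#' block, the OCTA LBP block, capillary vessel features, large-vessel
#' features, and the FAZ parameters. `feature_types()` returns the
#' feature-type tag of every name
#' (`LBP_OCT`, `LBP_OCTA`, `capillary`, `large_vessel`, `FAZ`), used for the
#' per-type contribution percentages.
#'
#' @return `feature_names()`: character vector of length 452;
#'   `feature_types()`: named character vector (names are the features).
#' @export
feature_names <- function() {
  lbp <- function(mod)
    as.vector(vapply(LAYERS,
                     function(l) paste0(mod, "_", l, "_LBP", 1:59),
                     character(59)))
  vessel <- function(structure)
    c(as.vector(vapply(VESSEL_INDICES,
                       function(i) paste(structure, i, SUMMARY_STATS,
                                         sep = "_"),
                       character(6))),
      paste0(structure, "_FD"))
  faz <- paste0("FAZ_", c("area", "perimeter", "CI", "diameter",
                          "centroid_x", "centroid_y", "eccentricity",
                          "compactness", "flatness", "anisotropy",
                          "convexity", "angle"))
  c(lbp("OCT"), lbp("OCTA"), vessel("capillary"), vessel("large_vessel"),
    faz)
}

#' @rdname feature_names
#' @export
feature_types <- function() {
  nm <- feature_names()
  types <- c(rep("LBP_OCT", 177), rep("LBP_OCTA", 177),
             rep("capillary", 43), rep("large_vessel", 43),
             rep("FAZ", 12))
  names(types) <- nm
  types
}

#' Assemble the 452-dimensional feature vector of one eye
#'
#' Concatenates, in canonical order, the OCT LBP block (177), the OCTA LBP
#' block (177), the capillary vessel features (43), the large-vessel
#' features computed on the artery-vein union (43) and the FAZ parameters
#' (12). Any non-finite intermediate value is replaced by 0 with a warning
#' naming the feature, so the vector is always finite.
#'
#' @param record An [eye_record()].
#' @param window_size Vessel index window edge in pixels (default 20).
#' @return Named numeric vector of length 452.
#' @export
assemble <- function(record, window_size = 20) {
  validate_eye_record(record)
  out <- tryCatch(
    c(lbp_feature_block(record, "OCT"),
      lbp_feature_block(record, "OCTA"),
      vessel_feature_set(record$masks$capillary, "capillary", window_size),
      vessel_feature_set(merge_large_vessel(record$masks$artery,
                                            record$masks$vein),
                         "large_vessel", window_size),
      faz_feature_set(record$masks$FAZ)),
    error = function(e) stop("eye '", record$eye_id, "': ",
                             conditionMessage(e), call. = FALSE))
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("eye '", record$eye_id, "': non-finite value(s) in ",
            paste(names(out)[bad], collapse = ", "), " replaced by 0",
            call. = FALSE)
    out[bad] <- 0
  }
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Build the cohort feature table
#'
#' One row per eye: `eye_id`, the 452 canonical feature columns, `label`.
#' The column set and order are fixed across cohorts and runs.
#'
#' @param records List of [eye_record()] objects (distinct `eye_id`s).
#' @param window_size Vessel index window edge in pixels (default 20).
#' @return Data frame with `length(records)` rows and 454 columns.
#' @export
build_feature_table <- function(records, window_size = 20) {
  if (length(records) < 1)
    stop("need at least one record", call. = FALSE)
  ids <- vapply(records, function(r) r$eye_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate eye_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  feats <- t(vapply(records, assemble, numeric(452),
                    window_size = window_size))
  tab <- data.frame(eye_id = ids, feats,
                    label = vapply(records, function(r)
                      as.character(r$label), character(1)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  validate_feature_table(tab)
  tab
}

# Split a feature table into the numeric matrix and its labels.
table_matrix <- function(table) {
  validate_feature_table(table)
  x <- as.matrix(table[, feature_names(), drop = FALSE])
  rownames(x) <- table$eye_id
  list(x = x, label = table$label)
}
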