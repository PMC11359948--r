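#' Construct an eye record
#'
#' Bundles the six grayscale projection images (OCT and OCTA, each with the
#' FULL, ILM-OPL and OPL-BM slabs), the four binary structure masks
#' (capillary, artery, vein, FAZ) and the disease label of one eye.
#'
#' @param eye_id Character scalar identifying the eye.
#' @param projections Named list of integer matrices (intensities 0-255); names
#'   must be `"<modality>_<layer>"` for all six modality/layer combinations.
#' @param masks Named list of logical matrices; names `"capillary"`,
#'   `"artery"`, `"vein"`, `"FAZ"`.
#' @param label One of `"control"`, `"AMD"`, `"DR"`, `"other"`, or `NA`.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(eye_id, projections, masks, label = NA_character_) {
  rec <- structure(
    list(eye_id = as.character(eye_id), projections = projections,
         masks = masks, label = label),
    class = "eye_record"
  )
  validate_eye_record(rec)
  # canonical component order, so equal records are `identical()`
  rec$projections <- rec$projections[projection_keys()]
  rec$masks <- rec$masks[STRUCTURES]
  rec
}

projection_keys <- function() {
  as.vector(t(outer(MODALITIES, LAYERS, paste, sep = "_")))
}

#' @export
print.eye_record <- function(x, ...) {
  d <- dim(x$projections[[1]])
  cat(sprintf("<eye_record> %s  %dx%d  label: %s\n",
              x$eye_id, d[1], d[2], as.character(x$label)))
  invisible(x)
}

validate_eye_record <- function(rec) {
  keys <- projection_keys()
  missing_p <- setdiff(keys, names(rec$projections))
  if (length(missing_p) > 0)
    stop("incomplete record '", rec$eye_id, "': missing projection ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  missing_m <- setdiff(STRUCTURES, names(rec$masks))
  if (length(missing_m) > 0)
    stop("incomplete record '", rec$eye_id, "': missing mask ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  ref <- dim(rec$projections[[keys[1]]])
  for (k in keys)
    if (!identical(dim(rec$projections[[k]]), ref))
      stop("geometry mismatch in record '", rec$eye_id, "': projection ", k,
           call. = FALSE)
  for (s in STRUCTURES) {
    if (!is.logical(rec$masks[[s]]))
      stop("mask '", s, "' of record '", rec$eye_id, "' is not logical",
           call. = FALSE)
    if (!identical(dim(rec$masks[[s]]), ref))
      stop("geometry mismatch in record '", rec$eye_id, "': mask ", s,
           call. = FALSE)
  }
  if (!is.na(rec$label) && !(rec$label %in% GROUP_LABELS))
    stop("unknown label '", rec$label, "' for record '", rec$eye_id, "'",
         call. = FALSE)
  invisible(rec)
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Read one eye from an on-disk cohort
#'
#' Expects the canonical layout written by [write_cohort()]: one directory per
#' eye containing `"<modality>_<layer>.png"` projection images and
#' `"<structure>_mask.png"` binary masks (any nonzero pixel is foreground),
#' plus a two-column `labels.csv` (`eye_id,label`) at the cohort root.
#'
#' @param root_path Cohort root directory.
#' @param eye_id Eye identifier (sub-directory name).
#' @return An [eye_record()].
#' @export
read_eye_record <- function(root_path, eye_id) {
  dir <- file.path(root_path, eye_id)
  if (!dir.exists(dir))
    stop("incomplete record '", eye_id, "': missing directory ", dir,
         call. = FALSE)
  projections <- list()
  for (k in projection_keys()) {
    f <- file.path(dir, paste0(k, ".png"))
    if (!file.exists(f))
      stop("incomplete record '", eye_id, "': missing projection file ",
           basename(f), call. = FALSE)
    projections[[k]] <- read_gray_png(f)
  }
  masks <- list()
  for (s in STRUCTURES) {
    f <- file.path(dir, paste0(s, "_mask.png"))
    if (!file.exists(f))
      stop("incomplete record '", eye_id, "': missing mask file ",
           basename(f), call. = FALSE)
    masks[[s]] <- read_gray_png(f) > 0
  }
  label <- NA_character_
  lf <- file.path(root_path, "labels.csv")
  if (file.exists(lf)) {
    lab <- read.csv(lf, stringsAsFactors = FALSE)
    hit <- match(eye_id, lab$eye_id)
    if (!is.na(hit)) label <- lab$label[hit]
  }
  eye_record(eye_id, projections, masks, label)
}

#' Write a cohort of eye records to disk in the canonical layout
#'
#' @param records List of [eye_record()] objects.
#' @param root_path Destination directory (created if needed).
#' @return `root_path`, invisibly.
#' @export
write_cohort <- function(records, root_path) {
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  labs <- data.frame(eye_id = character(0), label = character(0))
  for (rec in records) {
    validate_eye_record(rec)
    dir <- file.path(root_path, rec$eye_id)
    dir.create(dir, showWarnings = FALSE)
    for (k in projection_keys())
      png::writePNG(rec$projections[[k]] / 255,
                    file.path(dir, paste0(k, ".png")))
    for (s in STRUCTURES)
      png::writePNG(rec$masks[[s]] * 1,
                    file.path(dir, paste0(s, "_mask.png")))
    labs <- rbind(labs, data.frame(eye_id = rec$eye_id, label = rec$label))
  }
  write.csv(labs, file.path(root_path, "labels.csv"), row.names = FALSE)
  invisible(root_path)
}

feature_table_columns <- function() {
  c("eye_id", feature_names(), "label")
}

#' Write / read a cohort feature table
#'
#' The on-disk format is a UTF-8 CSV with one row per eye and the columns
#' `eye_id`, the 452 canonical feature names (see [feature_names()]), and
#' `label`. Values round-trip at full double precision (15 significant
#' digits).
#'
#' @param table Data frame as produced by [build_feature_table()].
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the validated data frame.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- feature_table_columns()
  if (!identical(names(tab), expected)) {
    extra <- setdiff(names(tab), expected)
    missing <- setdiff(expected, names(tab))
    stop("schema mismatch in feature table '", path, "'",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 3), collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(head(extra, 3), collapse = ", ")),
         call. = FALSE)
  }
  validate_feature_table(tab)
  tab
}

validate_feature_table <- function(tab) {
  expected <- feature_table_columns()
  if (!identical(names(tab), expected))
    stop("schema mismatch: feature table must have columns eye_id, the 452 ",
         "canonical features, and label", call. = FALSE)
  if (anyDuplicated(tab$eye_id))
    stop("duplicate eye_id in feature table", call. = FALSE)
  invisible(tab)
}
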