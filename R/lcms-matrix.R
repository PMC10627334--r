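#' Peptide-cluster x sample intensity matrix
#'
#' The central container of the workflow: a numeric features x samples grid of
#' intensities (missing values allowed) together with per-feature metadata
#' (retention time, m/z, neutral mass, charge, internal-standard and trait-row
#' flags), per-sample metadata (injection order, flour weight, QC flag,
#' technical-factor levels, trait value), and a stage tag recording the last
#' transformation applied. Stages are ordered
#' \code{raw -> weight -> is -> drift -> corrected -> z}; processing functions
#' refuse to run out of order.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Dimnames are taken from the metadata if absent.
#' @param features data.frame of feature metadata with at least
#'   \code{cluster_id}; columns \code{rt_min}, \code{mz}, \code{mass_da},
#'   \code{charge}, \code{is_internal_standard}, \code{is_trait_row} are
#'   filled with defaults if absent.
#' @param samples data.frame of sample metadata with at least
#'   \code{sample_id}; columns \code{injection_order}, \code{flour_weight_mg},
#'   \code{is_qc}, \code{lc_column}, \code{mass_cal}, \code{capillary},
#'   \code{trait_u_per_g}, \code{trait_imputed} are filled with defaults if
#'   absent.
#' @param stage stage tag, one of \code{"raw"}, \code{"weight"}, \code{"is"},
#'   \code{"drift"}, \code{"corrected"}, \code{"z"}.
#' @return an object of class \code{lcms_matrix}.
#' @export
lcms_matrix <- function(values, features, samples, stage = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  features <- .complete_feature_meta(as.data.frame(features,
                                                  stringsAsFactors = FALSE))
  samples <- .complete_sample_meta(as.data.frame(samples,
                                                 stringsAsFactors = FALSE))
  if (nrow(values) != nrow(features))
    stop("values has ", nrow(values), " rows but features describes ",
         nrow(features))
  if (ncol(values) != nrow(samples))
    stop("values has ", ncol(values), " columns but samples describes ",
         nrow(samples))
  rownames(values) <- features$cluster_id
  colnames(values) <- samples$sample_id
  obj <- structure(list(values = values, features = features,
                        samples = samples, stage = stage),
                   class = "lcms_matrix")
  validate_lcms_matrix(obj)
  obj
}

.lcms_stages <- c("raw", "weight", "is", "drift", "corrected", "z")

.complete_feature_meta <- function(df) {
  if (is.null(df$cluster_id)) stop("feature metadata needs a cluster_id column")
  df$cluster_id <- as.character(df$cluster_id)
  defaults <- list(rt_min = NA_real_, mz = NA_real_, mass_da = NA_real_,
                   charge = NA_integer_, is_internal_standard = FALSE,
                   is_trait_row = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$is_internal_standard <- as.logical(df$is_internal_standard)
  df$is_trait_row <- as.logical(df$is_trait_row)
  rownames(df) <- NULL
  df
}

.complete_sample_meta <- function(df) {
  if (is.null(df$sample_id)) stop("sample metadata needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  defaults <- list(injection_order = NA_integer_, flour_weight_mg = NA_real_,
                   is_qc = FALSE, lc_column = NA_integer_,
                   mass_cal = NA_integer_, capillary = NA_integer_,
                   trait_u_per_g = NA_real_, trait_imputed = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$is_qc <- as.logical(df$is_qc)
  df$trait_imputed <- as.logical(df$trait_imputed)
  rownames(df) <- NULL
  df
}

#' Validate an lcms_matrix
#'
#' Checks the structural invariants: metadata lengths match the grid, ids are
#' unique, the stage tag is known, at most one internal-standard and one trait
#' row exist, QC samples carry no trait value, and raw-stage intensities are
#' non-negative.
#'
#' @param x an \code{lcms_matrix}.
#' @return \code{x}, invisibly; errors describe the violated invariant.
#' @export
validate_lcms_matrix <- function(x) {
  stopifnot(inherits(x, "lcms_matrix"))
  if (!x$stage %in% .lcms_stages)
    stop("unknown stage tag: ", x$stage)
  if (anyDuplicated(x$features$cluster_id))
    stop("duplicated cluster_id in feature metadata")
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicated sample_id in sample metadata")
  if (sum(x$features$is_internal_standard, na.rm = TRUE) > 1)
    stop("more than one internal-standard feature")
  if (sum(x$features$is_trait_row, na.rm = TRUE) > 1)
    stop("more than one trait row")
  if (any(x$samples$is_qc & !is.na(x$samples$trait_u_per_g)))
    stop("QC samples must not carry a trait value")
  ord <- x$samples$injection_order
  if (!all(is.na(ord)) && anyDuplicated(ord[!is.na(ord)]))
    stop("injection_order values must be unique")
  if (x$stage == "raw" && any(x$values < 0, na.rm = TRUE))
    stop("raw-stage intensities must be non-negative")
  invisible(x)
}

#' @export
dim.lcms_matrix <- function(x) dim(x$values)

#' @export
print.lcms_matrix <- function(x, ...) {
  cat("lcms_matrix: ", nrow(x$values), " features x ", ncol(x$values),
      " samples (stage: ", x$stage, ")\n", sep = "")
  cat("  QC samples: ", sum(x$samples$is_qc), "; missing cells: ",
      sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

.stage_index <- function(stage) match(stage, .lcms_stages)

# Guard used by every pipeline step: refuse to run out of order.
require_stage <- function(x, expected, step) {
  if (!identical(x$stage, expected))
    stop(step, " expects a matrix at stage '", expected,
         "' but got stage '", x$stage, "'")
  invisible(x)
}

set_stage <- function(x, stage) {
  x$stage <- stage
  x
}

#' Subset an lcms_matrix
#'
#' @param x an \code{lcms_matrix}.
#' @param features logical/integer/character index of features to keep.
#' @param samples logical/integer/character index of samples to keep.
#' @return the subsetted \code{lcms_matrix} (stage tag preserved).
#' @export
subset_lcms <- function(x, features = NULL, samples = NULL) {
  if (!is.null(features)) {
    idx <- if (is.character(features))
      match(features, x$features$cluster_id) else features
    if (is.numeric(idx) && anyNA(idx)) stop("unknown feature ids in subset")
    x$values <- x$values[idx, , drop = FALSE]
    x$features <- x$features[idx, , drop = FALSE]
    rownames(x$features) <- NULL
  }
  if (!is.null(samples)) {
    idx <- if (is.character(samples))
      match(samples, x$samples$sample_id) else samples
    if (is.numeric(idx) && anyNA(idx)) stop("unknown sample ids in subset")
    x$values <- x$values[, idx, drop = FALSE]
    x$samples <- x$samples[idx, , drop = FALSE]
    rownames(x$samples) <- NULL
  }
  x
}

#' Drop QC samples from a matrix
#'
#' QC injections anchor the drift correction but are excluded from all trait
#' statistics; the pipeline drops them once normalization is complete.
#'
#' @param x an \code{lcms_matrix}.
#' @return the matrix restricted to non-QC samples.
#' @export
drop_qc_samples <- function(x) subset_lcms(x, samples = !x$samples$is_qc)

#' Write / read the matrix CSV dialect
#'
#' The on-disk form is one row per feature: \code{cluster_id}, the feature
#' metadata columns (\code{rt_min}, \code{mz}, \code{mass_da}, \code{charge},
#' \code{is_internal_standard}, \code{is_trait_row}), then one intensity column
#' per sample id. Missing intensities are empty cells. Sample metadata travels
#' in its own CSV (one row per sample).
#'
#' @param x an \code{lcms_matrix}.
#' @param matrix_file path of the matrix CSV.
#' @param samples_file path of the sample-metadata CSV.
#' @return \code{write_lcms_csv} returns the paths invisibly;
#'   \code{read_lcms_csv} returns an \code{lcms_matrix}.
#' @export
write_lcms_csv <- function(x, matrix_file, samples_file) {
  meta_cols <- c("cluster_id", "rt_min", "mz", "mass_da", "charge",
                 "is_internal_standard", "is_trait_row")
  out <- cbind(x$features[meta_cols],
               as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(out, matrix_file, row.names = FALSE, na = "")
  smp <- x$samples
  smp$stage_tag <- x$stage
  utils::write.csv(smp, samples_file, row.names = FALSE, na = "")
  invisible(c(matrix_file, samples_file))
}

#' @rdname write_lcms_csv
#' @export
read_lcms_csv <- function(matrix_file, samples_file) {
  tab <- utils::read.csv(matrix_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- c("cluster_id", "rt_min", "mz", "mass_da", "charge",
                 "is_internal_standard", "is_trait_row")
  feat <- tab[intersect(meta_cols, names(tab))]
  vals <- as.matrix(tab[setdiff(names(tab), meta_cols)])
  smp <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
  stage <- if (!is.null(smp$stage_tag)) smp$stage_tag[1] else "raw"
  smp$stage_tag <- NULL
  vals <- vals[, smp$sample_id, drop = FALSE]
  lcms_matrix(vals, feat, smp, stage = stage)
}
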