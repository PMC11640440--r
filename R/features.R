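# Per-structure radiomic feature extraction: volume in millilitres plus
# first-order Hounsfield-unit statistics.
#
# Metric roster (8 per structure): volume_ml, hu_sum, hu_q1, hu_q3, hu_mean,
# hu_median, hu_min, hu_max. The median doubles as Q2, so quartiles
# contribute two metrics, not three; together with volume this yields the
# 8-metric schema (320 structures x 8 = 2560 features on the full anatomical
# + tissue roster). Quantiles use linear interpolation of order statistics at
# position (n-1)*q — R's quantile type 7.

.METRIC_NAMES <- c("volume_ml", "hu_sum", "hu_q1", "hu_q3", "hu_mean",
                   "hu_median", "hu_min", "hu_max")

#' Metric names of the feature schema
#'
#' @return Character vector of the 8 metric names, in canonical order.
#' @export
metric_names <- function() .METRIC_NAMES

#' First-order HU statistics over a masked region
#'
#' Computes the seven intensity metrics (sum, Q1, Q3, mean, median, min, max)
#' over exactly the HU values at mask-1 voxels. Quartiles use linear
#' interpolation at position `(n-1)*q` (quantile type 7).
#'
#' @param ct A [ct_volume].
#' @param mask A [structure_mask] on the CT grid.
#' @return Named numeric vector of the 7 HU metrics, or `NULL` when the mask
#'   is empty (the structure is treated as absent and yields no features).
#' @export
hu_statistics <- function(ct, mask) {
  stopifnot(inherits(ct, "ct_volume"), inherits(mask, "structure_mask"))
  if (!identical(dim(mask$voxels), dim(ct$voxels))) {
    stop("mask grid does not match CT grid", call. = FALSE)
  }
  vals <- ct$voxels[mask$voxels == 1L]
  if (length(vals) == 0L) {
    return(NULL)
  }
  q <- stats::quantile(vals, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  c(hu_sum = sum(vals), hu_q1 = q[1], hu_q3 = q[3], hu_mean = mean(vals),
    hu_median = q[2], hu_min = min(vals), hu_max = max(vals))
}

#' Structure volume in millilitres
#'
#' Voxel count times the voxel volume from the affine. Empty masks are
#' allowed and yield 0 mL.
#'
#' @param mask A [structure_mask].
#' @param affine 4x4 voxel-to-world transform.
#' @return Volume in mL.
#' @export
structure_volume_ml <- function(mask, affine) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels == 1L) * voxel_volume_ml(affine)
}

#' Extract the radiomic feature table for one volume
#'
#' For every non-empty mask, emits 8 records (volume plus the 7 HU metrics)
#' in deterministic order (structure, then metric). Empty masks emit no
#' records — the structure counts as absent, which is what triggers the
#' pairwise-existence exclusion downstream.
#'
#' @param ct A [ct_volume].
#' @param masks A [mask_set] aligned to `ct`, or a list of such mask sets
#'   (e.g. anatomical + tissue).
#' @return A tidy data.frame with columns `patient_id`, `condition`,
#'   `structure`, `metric`, `value`.
#' @export
extract_features <- function(ct, masks) {
  stopifnot(inherits(ct, "ct_volume"))
  if (inherits(masks, "mask_set")) masks <- list(masks)
  all_masks <- unlist(lapply(masks, function(ms) {
    stopifnot(inherits(ms, "mask_set"))
    ms$masks
  }), recursive = FALSE)
  if (anyDuplicated(names(all_masks))) {
    stop("duplicate structure names across mask sets", call. = FALSE)
  }
  ord <- order(names(all_masks))
  all_masks <- all_masks[ord]

  vox_ml <- voxel_volume_ml(ct$affine)
  rows <- lapply(all_masks, function(m) {
    stats <- hu_statistics(ct, m)
    if (is.null(stats)) return(NULL)
    vol <- sum(m$voxels == 1L) * vox_ml
    vals <- c(volume_ml = vol, stats)[.METRIC_NAMES]
    data.frame(patient_id = ct$patient_id, condition = ct$condition,
               structure = m$structure_name, metric = .METRIC_NAMES,
               value = unname(vals), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(patient_id = character(), condition = character(),
                      structure = character(), metric = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature identifier schema
#'
#' Cross product of structure names and the 8 metric names, deterministically
#' ordered (structure-major in the given order, then metric).
#'
#' @param structure_names Character vector of unique structure names.
#' @return A data.frame with columns `structure`, `metric`, `feature_id`.
#' @export
#' @examples
#' nrow(feature_schema(c("liver", "spleen")))  # 16
feature_schema <- function(structure_names) {
  if (anyDuplicated(structure_names)) {
    stop("duplicate structure names: ",
         paste(unique(structure_names[duplicated(structure_names)]),
               collapse = ", "), call. = FALSE)
  }
  if (length(structure_names) == 0L) {
    return(data.frame(structure = character(), metric = character(),
                      feature_id = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    structure = rep(structure_names, each = length(.METRIC_NAMES)),
    metric = rep(.METRIC_NAMES, times = length(structure_names)),
    stringsAsFactors = FALSE
  )
  out$feature_id <- paste(out$structure, out$metric, sep = ":")
  out
}

#' Write a feature table as CSV
#'
#' Values are rounded to 6 significant decimals for stable diffs across
#' platforms; in-memory tables keep full double precision.
#'
#' @param features Feature data.frame from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  out <- features
  out$value <- signif(out$value, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
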