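# Body-composition tissue masks: intersection of body-region masks with
# Hounsfield-unit intervals.
#
# The schema is 7 tissue classes x 29 body regions = 203 tissue masks. The
# five adipose compartments (SAT, VAT, IMAT, PAT, EAT) share the adipose HU
# interval [-190, +30]; the compartment distinction comes entirely from which
# region mask is supplied. Muscle is [-29, +150]. Both intervals are closed,
# so adipose and muscle overlap on [-29, +30] by construction. The bone
# interval is not part of the published threshold set; the default
# [+151, +3000] is contiguous with muscle's upper bound and can be overridden.

.ADIPOSE_HU <- c(-190, 30)
.MUSCLE_HU <- c(-29, 150)
.BONE_HU_DEFAULT <- c(151, 3000)

.VERTEBRAL_LEVELS <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
.WHOLE_BODY_REGIONS <- c("abdominal_cavity", "thoracic_cavity",
                         "ventral_cavity", "mediastinum", "pericardium")

#' Tissue classes and their HU intervals
#'
#' The seven tissue classes of the body-composition schema with their closed
#' Hounsfield-unit intervals: the five adipose compartments (SAT, VAT, IMAT,
#' PAT, EAT) at \[-190, +30\] HU, muscle at \[-29, +150\] HU, and bone.
#'
#' @param bone_interval Closed HU interval for bone; the default
#'   `c(151, 3000)` is a package convention (contiguous with the muscle upper
#'   bound), not a published constant.
#' @return A data.frame with columns `class`, `hu_lo`, `hu_hi`.
#' @export
tissue_classes <- function(bone_interval = .BONE_HU_DEFAULT) {
  stopifnot(length(bone_interval) == 2L, bone_interval[1] <= bone_interval[2])
  data.frame(
    class = c("SAT", "VAT", "IMAT", "PAT", "EAT", "bone", "muscle"),
    hu_lo = c(rep(.ADIPOSE_HU[1], 5), bone_interval[1], .MUSCLE_HU[1]),
    hu_hi = c(rep(.ADIPOSE_HU[2], 5), bone_interval[2], .MUSCLE_HU[2]),
    stringsAsFactors = FALSE
  )
}

#' The 29 body regions
#'
#' Vertebral levels C1-C7, T1-T12, L1-L5 plus the five whole-body regions
#' (abdominal cavity, thoracic cavity, ventral cavity, mediastinum,
#' pericardium), in anatomical order.
#'
#' @return Character vector of length 29.
#' @export
body_regions <- function() {
  c(.VERTEBRAL_LEVELS, .WHOLE_BODY_REGIONS)
}

#' Full tissue-mask schema
#'
#' Cross product of the 7 tissue classes and 29 body regions: 203 mask
#' identifiers, deterministically ordered class-major with regions in
#' anatomical order (C1..C7, T1..T12, L1..L5, then whole-body regions).
#'
#' @param bone_interval Passed to [tissue_classes()].
#' @return A data.frame with columns `class`, `region`, `name`, `hu_lo`,
#'   `hu_hi`; one row per (class, region) pair.
#' @export
#' @examples
#' nrow(tissue_schema())  # 203
tissue_schema <- function(bone_interval = .BONE_HU_DEFAULT) {
  cls <- tissue_classes(bone_interval)
  regions <- body_regions()
  out <- data.frame(
    class = rep(cls$class, each = length(regions)),
    region = rep(regions, times = nrow(cls)),
    hu_lo = rep(cls$hu_lo, each = length(regions)),
    hu_hi = rep(cls$hu_hi, each = length(regions)),
    stringsAsFactors = FALSE
  )
  out$name <- paste(out$class, out$region, sep = "_")
  out[, c("class", "region", "name", "hu_lo", "hu_hi")]
}

#' Intersect a region mask with a tissue HU interval
#'
#' A voxel belongs to the tissue mask iff it belongs to the region mask and
#' its HU value lies in the closed interval `[hu_lo, hu_hi]` (both endpoints
#' inclusive).
#'
#' @param ct A [ct_volume].
#' @param region_mask A [structure_mask] on the CT grid.
#' @param tissue Tissue class name (row of [tissue_classes()]) or a list/row
#'   with elements `class`/`name`, `hu_lo`, `hu_hi`.
#' @param bone_interval Passed to [tissue_classes()] when `tissue` is a name.
#' @return A [structure_mask] named `<class>_<region>`.
#' @export
classify_tissue <- function(ct, region_mask, tissue,
                            bone_interval = .BONE_HU_DEFAULT) {
  stopifnot(inherits(ct, "ct_volume"), inherits(region_mask, "structure_mask"))
  if (!identical(dim(region_mask$voxels), dim(ct$voxels))) {
    stop("region mask grid does not match CT grid", call. = FALSE)
  }
  if (is.character(tissue)) {
    cls <- tissue_classes(bone_interval)
    row <- cls[cls$class == tissue, ]
    if (nrow(row) != 1L) {
      stop("unknown tissue class: ", tissue, call. = FALSE)
    }
    tissue <- list(class = row$class, hu_lo = row$hu_lo, hu_hi = row$hu_hi)
  }
  cls_name <- if (!is.null(tissue$class)) tissue$class else tissue$name
  sel <- region_mask$voxels == 1L &
    ct$voxels >= tissue$hu_lo & ct$voxels <= tissue$hu_hi
  structure_mask(array(sel, dim = dim(ct$voxels)),
                 paste(cls_name, region_mask$structure_name, sep = "_"))
}

#' Derive body-composition tissue masks from region masks
#'
#' For every supplied body-region mask, emits one tissue mask per tissue
#' class (7 per region). Regions absent from the input are omitted, not
#' emitted as empty masks; region names outside the 29-region vocabulary are
#' skipped with a warning. With all 29 regions present this yields the full
#' 203-mask schema.
#'
#' @param ct A [ct_volume].
#' @param region_masks A [mask_set] whose names are body regions (see
#'   [body_regions()]).
#' @param bone_interval Passed to [tissue_classes()].
#' @return A [mask_set] with `source = "tissue"`.
#' @export
derive_tissue_masks <- function(ct, region_masks,
                                bone_interval = .BONE_HU_DEFAULT) {
  stopifnot(inherits(ct, "ct_volume"), inherits(region_masks, "mask_set"))
  known <- body_regions()
  present <- names(region_masks$masks)
  unknown <- setdiff(present, known)
  if (length(unknown) > 0L) {
    warning("skipping unknown region name(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  schema <- tissue_schema(bone_interval)
  schema <- schema[schema$region %in% intersect(present, known), ,
                   drop = FALSE]
  masks <- lapply(seq_len(nrow(schema)), function(i) {
    classify_tissue(ct, region_masks$masks[[schema$region[i]]],
                    list(class = schema$class[i],
                         hu_lo = schema$hu_lo[i], hu_hi = schema$hu_hi[i]))
  })
  names(masks) <- schema$name
  mask_set(masks, source = "tissue")
}

#' Write the tissue schema as a plain-text manifest
#'
#' @param path Output file; two tab-separated columns (mask name, HU
#'   interval).
#' @param bone_interval Passed to [tissue_schema()].
#' @return `path`, invisibly.
#' @export
write_tissue_manifest <- function(path, bone_interval = .BONE_HU_DEFAULT) {
  schema <- tissue_schema(bone_interval)
  lines <- paste0(schema$name, "\t[", schema$hu_lo, ",", schema$hu_hi, "]")
  writeLines(lines, path)
  invisible(path)
}
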