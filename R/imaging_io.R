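# CT volume / mask containers and NIfTI-facing I/O.
#
# Grids are never resampled: any shape mismatch between a CT volume and its
# masks is an error. Silent resampling would corrupt HU statistics.

#' CT volume container
#'
#' Bundles a 3-D Hounsfield-unit voxel grid with its voxel-to-world affine and
#' patient/condition labels. Stored values are assumed to be HU, i.e. any
#' intensity scaling declared in a source file header has already been applied.
#'
#' @param voxels 3-D numeric array of HU intensities.
#' @param affine 4x4 voxel-index-to-world-mm transform; the upper-left 3x3
#'   block must be invertible.
#' @param patient_id Patient identifier.
#' @param condition `"pre"` or `"post"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, affine = diag(4), patient_id = "unknown",
                      condition = c("pre", "post")) {
  condition <- match.arg(condition)
  if (length(dim(voxels)) != 3L || any(dim(voxels) <= 0L)) {
    stop("voxels must be a 3-D array with positive dimensions", call. = FALSE)
  }
  if (!is.matrix(affine) || any(dim(affine) != 4L)) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("affine has a singular linear part", call. = FALSE)
  }
  structure(
    list(voxels = voxels, affine = affine, patient_id = patient_id,
         condition = condition),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> patient:", x$patient_id, " condition:", x$condition,
      "\n  grid:", paste(dim(x$voxels), collapse = " x "),
      " voxel volume:", format(voxel_volume_ml(x$affine)), "mL\n")
  invisible(x)
}

#' Binary structure mask
#'
#' @param voxels 3-D array restricted to values 0/1 (logical accepted).
#' @param structure_name Name of the segmented structure.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, structure_name) {
  if (length(dim(voxels)) != 3L) {
    stop("mask voxels must be a 3-D array", call. = FALSE)
  }
  if (is.logical(voxels)) {
    v <- array(as.integer(voxels), dim = dim(voxels))
  } else {
    if (!all(voxels %in% c(0, 1))) {
      stop("mask '", structure_name, "' contains values other than 0/1",
           call. = FALSE)
    }
    v <- array(as.integer(voxels), dim = dim(voxels))
  }
  structure(list(voxels = v, structure_name = structure_name),
            class = "structure_mask")
}

#' Named set of structure masks on one grid
#'
#' @param masks Named list of [structure_mask] objects (names must match each
#'   mask's `structure_name` and be unique); all masks must share one grid
#'   shape.
#' @param source `"anatomical"` or `"tissue"`.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(masks, source = c("anatomical", "tissue")) {
  source <- match.arg(source)
  nm <- vapply(masks, function(m) m$structure_name, character(1))
  names(masks) <- nm
  if (anyDuplicated(nm)) {
    stop("duplicate structure names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (length(masks) > 1L) {
    shapes <- vapply(masks, function(m) paste(dim(m$voxels), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) > 1L) {
      stop("masks do not share one grid shape", call. = FALSE)
    }
  }
  structure(list(masks = masks, source = source), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat("<mask_set> source:", x$source, " structures:", length(x$masks), "\n")
  invisible(x)
}

#' @export
length.mask_set <- function(x) length(x$masks)

#' Read a CT volume from a NIfTI file
#'
#' Voxel values are returned in Hounsfield units: any `scl_slope`/`scl_inter`
#' intensity scaling declared in the header is applied on read. The affine is
#' chosen with the standard precedence used by mainstream NIfTI readers
#' (sform if present, else qform, else pixdim diagonal).
#'
#' @param path Path to a 3-D NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`).
#' @param patient_id Patient label; defaults to the file basename without
#'   extensions.
#' @param condition `"pre"` or `"post"`.
#' @return A [ct_volume].
#' @export
read_ct <- function(path, patient_id = NULL, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  nii <- read_nifti(path)
  if (is.null(patient_id)) patient_id <- strip_nii_ext(basename(path))
  ct_volume(nii$data, nii$affine, patient_id = patient_id,
            condition = condition)
}

#' Write a CT volume to a NIfTI-1 file
#'
#' @param ct A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Storage type; the default `"float64"` round-trips HU
#'   values exactly.
#' @return `path`, invisibly.
#' @export
write_ct <- function(ct, path, datatype = "float64") {
  stopifnot(inherits(ct, "ct_volume"))
  write_nifti(ct$voxels, ct$affine, path, datatype = datatype)
}

strip_nii_ext <- function(x) sub("\\.nii(\\.gz)?$", "", x)

#' Read a mask set from a directory or a label image
#'
#' Two on-disk dialects are accepted, standing in for the external
#' deep-learning segmenters whose outputs this package consumes:
#' \itemize{
#'   \item a directory of per-structure binary NIfTI files named
#'     `<structure_name>.nii(.gz)`;
#'   \item a single integer label image plus a two-column plain-text table
#'     mapping integer labels to structure names (label 0 is background and
#'     never a structure).
#' }
#' Every mask is verified against the companion CT grid; mismatching shapes
#' are an error, never resampled.
#'
#' @param path Directory of binary masks, or path to a label NIfTI.
#' @param grid A [ct_volume] defining the reference grid.
#' @param label_table For the label-image dialect: path to a two-column text
#'   file (integer label, structure name) or a data.frame with columns
#'   `label` and `name`.
#' @param source Mask provenance, `"anatomical"` or `"tissue"`.
#' @return A [mask_set].
#' @export
read_mask_set <- function(path, grid, label_table = NULL,
                          source = c("anatomical", "tissue")) {
  source <- match.arg(source)
  stopifnot(inherits(grid, "ct_volume"))
  shape <- dim(grid$voxels)

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop("no NIfTI mask files found in directory: ", path, call. = FALSE)
    }
    nm <- strip_nii_ext(basename(files))
    if (anyDuplicated(nm)) {
      stop("duplicate structure names in ", path, ": ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    }
    masks <- lapply(seq_along(files), function(i) {
      nii <- read_nifti(files[i])
      if (!identical(dim(nii$data), shape)) {
        stop("mask '", nm[i], "' grid ", paste(dim(nii$data), collapse = "x"),
             " does not match CT grid ", paste(shape, collapse = "x"),
             call. = FALSE)
      }
      structure_mask(nii$data != 0, nm[i])
    })
    names(masks) <- nm
    return(mask_set(masks, source = source))
  }

  # label-image dialect
  if (is.null(label_table)) {
    stop("label_table is required when path is a label image", call. = FALSE)
  }
  if (is.character(label_table)) {
    label_table <- utils::read.table(label_table, header = FALSE,
                                     col.names = c("label", "name"),
                                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "name") %in% names(label_table)))
  nii <- read_nifti(path)
  if (!identical(dim(nii$data), shape)) {
    stop("label image grid ", paste(dim(nii$data), collapse = "x"),
         " does not match CT grid ", paste(shape, collapse = "x"),
         call. = FALSE)
  }
  tab <- label_table[label_table$label != 0, , drop = FALSE]
  if (anyDuplicated(tab$name)) {
    stop("duplicate structure names in label table: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  masks <- lapply(seq_len(nrow(tab)), function(i) {
    structure_mask(nii$data == tab$label[i], tab$name[i])
  })
  names(masks) <- tab$name
  mask_set(masks, source = source)
}

#' Write a mask set as binary NIfTI files
#'
#' One `<structure_name>.nii.gz` file per mask (uint8), carrying the supplied
#' affine.
#'
#' @param masks A [mask_set].
#' @param dir Output directory (created if needed).
#' @param affine 4x4 voxel-to-world transform shared by the masks.
#' @return The directory path, invisibly.
#' @export
write_mask_set <- function(masks, dir, affine = diag(4)) {
  stopifnot(inherits(masks, "mask_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in masks$masks) {
    write_nifti(m$voxels, affine,
                file.path(dir, paste0(m$structure_name, ".nii.gz")),
                datatype = "uint8")
  }
  invisible(dir)
}

#' Voxel volume in millilitres
#'
#' The volume of one voxel is the absolute determinant of the affine's
#' upper-left 3x3 block (mm^3 per voxel), converted to millilitres. Rotations
#' leave it unchanged.
#'
#' @param affine 4x4 voxel-to-world transform in millimetres.
#' @return Volume of a single voxel in mL.
#' @export
#' @examples
#' voxel_volume_ml(diag(4))                    # 1 mm isotropic -> 0.001 mL
#' voxel_volume_ml(diag(c(2, 2, 3, 1)))        # 12 mm^3 -> 0.012 mL
voxel_volume_ml <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  d <- det(affine[1:3, 1:3])
  if (abs(d) < .Machine$double.eps) {
    stop("affine has a singular linear part; voxel volume undefined",
         call. = FALSE)
  }
  abs(d) / 1000
}
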