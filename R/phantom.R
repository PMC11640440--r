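# Seeded ellipsoid phantoms: synthetic paired CT volumes plus exact masks
# with controlled longitudinal volume and HU changes, so every pipeline stage
# is testable without clinical data.
#
# Geometry uses voxel-center inclusion: voxel (i,j,k) belongs to an ellipsoid
# iff sum(((idx - center)/semi_axes)^2) <= 1 in voxel coordinates. HU noise is
# independent per voxel and per condition (no spatial correlation; real CT
# noise is textured — a documented limitation). All randomness flows from the
# spec seed through a per-structure, per-condition derived stream, so volumes
# are reproducible structure by structure.

.derive_seed <- function(seed, name, offset = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + offset) %% 2147483629)
}

#' Phantom specification
#'
#' @param grid_shape Three positive integers (voxels).
#' @param spacing_mm Three positive voxel spacings in millimetres.
#' @param structures List of structures, each a list with `name`, `center`
#'   (voxel coordinates), `semi_axes` (voxels), `hu_mean`, `hu_sd`.
#' @param background_hu Background intensity (default -1000 HU, air).
#' @param seed Integer master seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm = c(1, 1, 1), structures,
                         background_hu = -1000, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  for (s in structures) {
    stopifnot(all(c("name", "center", "semi_axes", "hu_mean", "hu_sd")
                  %in% names(s)))
    if (s$hu_sd < 0) stop("hu_sd must be >= 0", call. = FALSE)
    if (any(s$center - s$semi_axes < 1) ||
        any(s$center + s$semi_axes > grid_shape)) {
      stop("ellipsoid '", s$name, "' does not fit inside the grid",
           call. = FALSE)
    }
  }
  nm <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate structure names in phantom spec", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 structures = structures,
                 background_hu = background_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.ellipsoid_voxels <- function(grid_shape, center, semi_axes) {
  # bounding box keeps this O(structure), not O(grid)
  lo <- pmax(1L, floor(center - semi_axes))
  hi <- pmin(grid_shape, ceiling(center + semi_axes))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  r2 <- ((g$i - center[1]) / semi_axes[1])^2 +
        ((g$j - center[2]) / semi_axes[2])^2 +
        ((g$k - center[3]) / semi_axes[3])^2
  g <- g[r2 <= 1, , drop = FALSE]
  cbind(g$i, g$j, g$k)
}

#' Generate a phantom CT volume and its mask set
#'
#' HU values at structure voxels are drawn from `Normal(hu_mean, hu_sd)`
#' using a per-structure seeded stream; masks are exactly the ellipsoid voxel
#' sets. Overlapping ellipsoids are a fatal error so per-structure statistics
#' stay analytic.
#'
#' @param spec A [phantom_spec].
#' @param patient_id,condition Labels for the emitted [ct_volume].
#' @param condition_offset Internal stream offset distinguishing conditions;
#'   leave at default unless generating extra independent replicates.
#' @return A list with elements `ct` ([ct_volume]) and `masks` ([mask_set]).
#' @export
make_phantom <- function(spec, patient_id = "phantom",
                         condition = c("pre", "post"),
                         condition_offset = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  condition <- match.arg(condition)
  if (is.null(condition_offset)) {
    condition_offset <- if (condition == "pre") 0L else 500000L
  }
  vox <- array(spec$background_hu, dim = spec$grid_shape)
  masks <- vector("list", length(spec$structures))
  occupied <- array(FALSE, dim = spec$grid_shape)
  for (i in seq_along(spec$structures)) {
    s <- spec$structures[[i]]
    idx <- .ellipsoid_voxels(spec$grid_shape, s$center, s$semi_axes)
    if (any(occupied[idx])) {
      stop("ellipsoids overlap at structure '", s$name, "'", call. = FALSE)
    }
    occupied[idx] <- TRUE
    set.seed(.derive_seed(spec$seed, s$name, condition_offset))
    vox[idx] <- if (s$hu_sd > 0) {
      stats::rnorm(nrow(idx), s$hu_mean, s$hu_sd)
    } else {
      s$hu_mean
    }
    mvox <- array(FALSE, dim = spec$grid_shape)
    mvox[idx] <- TRUE
    masks[[i]] <- structure_mask(mvox, s$name)
  }
  names(masks) <- vapply(masks, `[[`, character(1), "structure_name")
  affine <- diag(c(spec$spacing_mm, 1))
  list(ct = ct_volume(vox, affine, patient_id = patient_id,
                      condition = condition),
       masks = mask_set(masks, source = "anatomical"))
}

#' Generate a paired pre/post phantom with controlled changes
#'
#' The post-condition phantom rescales each structure's semi-axes
#' isotropically by `(1 + volume_change_pct/100)^(1/3)` and shifts its HU
#' mean by `hu_shift`; noise draws are independent between conditions.
#'
#' @param spec A [phantom_spec] describing the pre-condition state.
#' @param change Named list (by structure name) of lists with
#'   `volume_change_pct` (> -100) and `hu_shift` (HU); structures not listed
#'   are left unchanged.
#' @param patient_id Patient label for both volumes.
#' @return A list with elements `pre` and `post`, each a
#'   `list(ct, masks)` as from [make_phantom()].
#' @export
make_paired_phantoms <- function(spec, change = list(),
                                 patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  post_structures <- lapply(spec$structures, function(s) {
    ch <- change[[s$name]]
    if (!is.null(ch)) {
      pct <- if (!is.null(ch$volume_change_pct)) ch$volume_change_pct else 0
      if (pct <= -100) {
        stop("volume_change_pct must be > -100", call. = FALSE)
      }
      s$semi_axes <- s$semi_axes * (1 + pct / 100)^(1 / 3)
      if (!is.null(ch$hu_shift)) s$hu_mean <- s$hu_mean + ch$hu_shift
    }
    s
  })
  post_spec <- phantom_spec(spec$grid_shape, spec$spacing_mm, post_structures,
                            background_hu = spec$background_hu,
                            seed = spec$seed)
  list(pre = make_phantom(spec, patient_id, "pre"),
       post = make_phantom(post_spec, patient_id, "post"))
}

#' Generate a seeded phantom cohort on disk
#'
#' Writes `n_patients` paired pre/post phantom volumes plus per-patient
#' binary mask directories in the layout [run_pipeline()] consumes. Each
#' patient gets an independent noise stream (derived from `seed`); geometry
#' and injected changes are shared across patients, emulating a homogeneous
#' treatment effect.
#'
#' @param dir Output directory; `pre/`, `post/`, `masks_pre/`, `masks_post/`
#'   are created inside.
#' @param n_patients Number of patients.
#' @param spec A [phantom_spec]; its `seed` is re-derived per patient.
#' @param change Per-structure change list as in [make_paired_phantoms()].
#' @param seed Cohort master seed.
#' @return Invisibly, the vector of patient ids.
#' @export
make_phantom_cohort <- function(dir, n_patients, spec, change = list(),
                                seed = 1L) {
  pids <- sprintf("patient%02d", seq_len(n_patients))
  for (sub in c("pre", "post", "masks_pre", "masks_post")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  affine <- diag(c(spec$spacing_mm, 1))
  for (i in seq_len(n_patients)) {
    pspec <- spec
    pspec$seed <- .derive_seed(seed, pids[i])
    pair <- make_paired_phantoms(pspec, change, patient_id = pids[i])
    write_ct(pair$pre$ct, file.path(dir, "pre", paste0(pids[i], ".nii.gz")))
    write_ct(pair$post$ct, file.path(dir, "post", paste0(pids[i], ".nii.gz")))
    write_mask_set(pair$pre$masks, file.path(dir, "masks_pre", pids[i]),
                   affine = affine)
    write_mask_set(pair$post$masks, file.path(dir, "masks_post", pids[i]),
                   affine = affine)
  }
  invisible(pids)
}
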