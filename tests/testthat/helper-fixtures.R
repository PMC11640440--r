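# Fixture builders shared across the suite. Everything is generated in code:
# no binary files ship with the package.

# small CT volume with deterministic voxel values
make_test_ct <- function(shape = c(8L, 8L, 8L), affine = diag(4),
                         values = NULL, patient_id = "p1",
                         condition = "pre") {
  if (is.null(values)) values <- seq_len(prod(shape)) %% 97 - 48
  ct_volume(array(values, dim = shape), affine, patient_id = patient_id,
            condition = condition)
}

# cuboid mask on a grid
make_box_mask <- function(shape, from, to, name = "box") {
  v <- array(FALSE, dim = shape)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  structure_mask(v, name)
}

# random rotation matrix (Haar via QR), det +1
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# standard two-structure phantom spec used in several files
default_phantom_spec <- function(seed = 7L, hu_sd = 15, semi = 12,
                                 grid = c(48L, 48L, 48L)) {
  phantom_spec(
    grid_shape = grid, spacing_mm = c(1, 1, 1),
    structures = list(
      list(name = "C3", center = c(grid[1] / 3, grid[2] / 3, grid[3] / 2),
           semi_axes = rep(semi, 3), hu_mean = -80, hu_sd = hu_sd),
      list(name = "liver", center = c(3 * grid[1] / 4, 3 * grid[2] / 4,
                                      grid[3] / 2),
           semi_axes = rep(semi / 2, 3), hu_mean = 60, hu_sd = hu_sd / 2)
    ),
    seed = seed
  )
}

# patch bytes of an uncompressed .nii in place (offset is 0-based)
patch_nii_bytes <- function(path, offset, bytes) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  raw[(offset + 1):(offset + length(bytes))] <- bytes
  writeBin(raw, path)
  invisible(path)
}

float32_raw <- function(x) writeBin(as.double(x), raw(), size = 4,
                                    endian = "little")
int16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
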