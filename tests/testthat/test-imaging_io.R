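# NIfTI I/O, containers, and voxel geometry.

test_that("NIfTI round-trip is exact for integer HU grids across datatypes", {
  shape <- c(9L, 7L, 5L)
  set.seed(42)
  vals <- array(sample(-1024:2000, prod(shape), replace = TRUE), dim = shape)
  aff <- diag(c(0.8, 0.8, 2.5, 1))
  aff[1:3, 4] <- c(-100, -120, 40)

  for (dt in c("float64", "float32", "int32", "int16")) {
    path <- tempfile(fileext = if (dt == "int16") ".nii" else ".nii.gz")
    write_nifti(vals, aff, path, datatype = dt)
    back <- read_nifti(path)
    expect_identical(back$data, array(as.double(vals), dim = shape),
                     info = dt)
    expect_equal(back$affine, aff, tolerance = 1e-6, info = dt)
    unlink(path)
  }
})

test_that("header intensity scaling is applied on read", {
  # stored value 1024 with slope 1, intercept -1024 must come back as HU 0
  shape <- c(4L, 4L, 4L)
  stored <- array(1024, dim = shape)
  path <- tempfile(fileext = ".nii")
  write_nifti(stored, diag(4), path, datatype = "int16")
  patch_nii_bytes(path, 112, float32_raw(1))      # scl_slope
  patch_nii_bytes(path, 116, float32_raw(-1024))  # scl_inter
  back <- read_nifti(path)
  expect_identical(unique(as.vector(back$data)), 0)

  # slope 2, intercept -1024: stored 1024 -> 1024
  patch_nii_bytes(path, 112, float32_raw(2))
  expect_identical(unique(as.vector(read_nifti(path)$data)), 1024)
  unlink(path)
})

test_that("reader agrees with nibabel on data, scaling and affine", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # same image as the package environment
  dir <- tempfile("nib")
  dir.create(dir)
  script <- file.path(dir, "gen.py")
  writeLines(c(
    "import numpy as np, nibabel as nib, sys",
    "out = sys.argv[1]",
    "rng = np.random.default_rng(3)",
    "data = rng.integers(-1024, 2000, size=(7,6,5)).astype(np.int16)",
    "th = np.deg2rad(30.0)",
    "aff = np.array([[np.cos(th), -np.sin(th), 0, 5.],",
    "                [np.sin(th),  np.cos(th), 0, -7.],",
    "                [0, 0, 2.0, 1.], [0, 0, 0, 1.]])",
    "nib.save(nib.Nifti1Image(data, aff), out + '/ref1.nii.gz')",
    "nib.save(nib.Nifti2Image(data.astype(np.float32), aff), out + '/ref2.nii.gz')",
    "img3 = nib.Nifti1Image(data, None)",
    "img3.header.set_qform(aff, code=1)",
    "img3.header.set_sform(None, code=0)",
    "nib.save(img3, out + '/ref3.nii')",
    "np.savetxt(out + '/data.txt', nib.load(out + '/ref1.nii.gz')",
    "           .get_fdata(dtype=np.float64).ravel(order='F'))",
    "np.savetxt(out + '/affine.txt', aff)"
  ), script)
  status <- system2(py, c(script, dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "ref1.nii.gz")),
              info = paste(status, collapse = "\n"))

  oracle_data <- scan(file.path(dir, "data.txt"), quiet = TRUE)
  oracle_aff <- as.matrix(utils::read.table(file.path(dir, "affine.txt")))
  dimnames(oracle_aff) <- NULL

  for (f in c("ref1.nii.gz", "ref2.nii.gz", "ref3.nii")) {
    r <- read_nifti(file.path(dir, f))
    expect_equal(as.vector(r$data), oracle_data, tolerance = 1e-6, info = f)
    expect_equal(r$affine, oracle_aff, tolerance = 1e-5, info = f)
  }
  unlink(dir, recursive = TRUE)
})

test_that("corrupt, truncated and 4-D inputs raise informative errors", {
  expect_error(read_ct(tempfile(fileext = ".nii")), "does not exist")

  garbage <- tempfile(fileext = ".nii")
  writeBin(as.raw(sample(0:255, 100, replace = TRUE)), garbage)
  expect_error(read_nifti(garbage), "NIfTI")

  ok <- tempfile(fileext = ".nii")
  write_nifti(array(0, dim = c(6L, 6L, 6L)), diag(4), ok, datatype = "int16")
  truncated <- tempfile(fileext = ".nii")
  raw <- readBin(ok, "raw", n = file.info(ok)$size)
  writeBin(raw[1:400], truncated)
  expect_error(read_nifti(truncated), "runcat")

  fourd <- tempfile(fileext = ".nii")
  file.copy(ok, fourd)
  patch_nii_bytes(fourd, 40, int16_raw(4))  # dim[0] = 4
  patch_nii_bytes(fourd, 48, int16_raw(2))  # dim[4] = 2
  expect_error(read_nifti(fourd), "single 3-D series")
  unlink(c(garbage, ok, truncated, fourd))
})

test_that("voxel_volume_ml matches the determinant and ignores rotation", {
  expect_equal(voxel_volume_ml(diag(4)), 0.001)
  expect_equal(voxel_volume_ml(diag(c(2, 2, 3, 1))), 0.012)

  # 30-degree in-plane rotation, spacing (1, 1, 2): volume unchanged
  th <- pi / 6
  aff <- diag(4)
  aff[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  aff[3, 3] <- 2
  expect_equal(voxel_volume_ml(aff), 0.002)

  # property: |det| invariant under random rotations
  set.seed(11)
  base <- diag(c(0.7, 1.3, 2.1, 1))
  for (i in 1:25) {
    rot <- diag(4)
    rot[1:3, 1:3] <- random_rotation()
    expect_equal(voxel_volume_ml(rot %*% base), voxel_volume_ml(base),
                 tolerance = 1e-12)
  }

  singular <- diag(4)
  singular[3, 3] <- 0
  expect_error(voxel_volume_ml(singular), "singular")
})

test_that("mask-set dialects (binary directory vs label image) agree", {
  shape <- c(10L, 10L, 10L)
  ct <- make_test_ct(shape)
  labels <- array(0L, dim = shape)
  labels[2:4, 2:4, 2:4] <- 1L
  labels[6:9, 6:9, 6:9] <- 2L

  # dialect 1: binary directory
  dir1 <- tempfile("masks")
  dir.create(dir1)
  write_nifti(array(as.integer(labels == 1L), shape), diag(4),
              file.path(dir1, "liver.nii.gz"), datatype = "uint8")
  write_nifti(array(as.integer(labels == 2L), shape), diag(4),
              file.path(dir1, "spleen.nii.gz"), datatype = "uint8")
  ms1 <- read_mask_set(dir1, ct)

  # dialect 2: label image + table (label 0 is background, never a structure)
  lab_path <- tempfile(fileext = ".nii.gz")
  write_nifti(labels, diag(4), lab_path, datatype = "uint8")
  tab_path <- tempfile(fileext = ".txt")
  writeLines(c("0 background", "1 liver", "2 spleen"), tab_path)
  ms2 <- read_mask_set(lab_path, ct, label_table = tab_path)

  expect_setequal(names(ms1$masks), c("liver", "spleen"))
  expect_setequal(names(ms2$masks), c("liver", "spleen"))
  for (nm in c("liver", "spleen")) {
    expect_identical(ms1$masks[[nm]]$voxels, ms2$masks[[nm]]$voxels)
  }

  # shape mismatch is fatal, never resampled
  small_ct <- make_test_ct(c(6L, 6L, 6L))
  expect_error(read_mask_set(dir1, small_ct), "does not match CT grid")
  expect_error(read_mask_set(lab_path, small_ct, label_table = tab_path),
               "does not match CT grid")

  # duplicate structure names are fatal
  writeLines(c("1 liver", "2 liver"), tab_path)
  expect_error(read_mask_set(lab_path, ct, label_table = tab_path),
               "duplicate")
  unlink(c(dir1, lab_path, tab_path), recursive = TRUE)
})

test_that("ct_volume and mask_set enforce their invariants", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3-D")
  bad_aff <- diag(4)
  bad_aff[1, 1] <- 0
  expect_error(ct_volume(array(0, c(2, 2, 2)), bad_aff), "singular")
  expect_error(structure_mask(array(2, c(2, 2, 2)), "m"), "0/1")
  m1 <- structure_mask(array(TRUE, c(2, 2, 2)), "a")
  m2 <- structure_mask(array(TRUE, c(3, 3, 3)), "b")
  expect_error(mask_set(list(m1, m2)), "share one grid")
  expect_error(mask_set(list(m1, m1)), "duplicate")
})
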