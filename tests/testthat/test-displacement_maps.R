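test_that("magnitude map is the per-voxel Euclidean norm", {
  vec <- array(0, c(8, 8, 8, 3))
  vec[2, 3, 4, ] <- c(3, 4, 0)
  vec[5, 5, 5, ] <- c(1, 2, 2)
  f <- displacement_field(vec)
  m <- magnitude_map(f)
  expect_s3_class(m, "volume_grid")
  expect_equal(m$values[2, 3, 4], 5)
  expect_equal(m$values[5, 5, 5], 3)
  expect_equal(m$values[1, 1, 1], 0)
})

test_that("slice_spec validates plane and stride", {
  expect_s3_class(slice_spec("axial", 4), "slice_spec")
  expect_error(slice_spec("oblique", 4))
  expect_error(slice_spec("axial", 4, stride = 0), "stride")
})

test_that("arrow data carry correct coordinates, labels and components", {
  dict <- c(background = 0L, blob = 1L)
  lab <- array(0L, c(12, 12, 12)); lab[4:9, 4:9, 4:9] <- 1L
  labels <- label_volume(lab, dict, spacing = c(1, 2, 1), origin = c(10, 0, -5))
  vec <- array(0, c(12, 12, 12, 3))
  vec[, , , 1] <- 0.5; vec[, , , 2] <- -0.25; vec[, , , 3] <- 1
  f <- displacement_field(vec, spacing = c(1, 2, 1), origin = c(10, 0, -5))

  s <- slice_spec("axial", 5, stride = 2)     # fixed z = voxel 5 (0-based)
  csv <- file.path(tempdir(), "arrows.csv")
  png <- file.path(tempdir(), "arrows.png")
  a <- arrow_plot(f, labels, s, out_path = png, export_csv = csv)

  expect_true(file.exists(png), file.exists(csv))
  expect_true(all(a$plane == "axial"), all(a$slice_index == 5))
  expect_true(all(a$label == "blob"))
  # axial slice: in-plane axes are x and y
  expect_true(all(a$u_inplane1 == 0.5), all(a$u_inplane2 == -0.25))
  expect_equal(a$magnitude_mm, rep(sqrt(0.5^2 + 0.25^2 + 1), nrow(a)))
  expect_equal(a$mm1, 10 + a$vox1 * 1)
  expect_equal(a$mm2, 0 + a$vox2 * 2)
  # stride 2 on 0-based in-mask voxels 3..8 keeps even indices 4, 6, 8
  expect_setequal(unique(a$vox1), c(4, 6, 8))
  expect_equal(utils::read.csv(csv)$vox1, a$vox1, ignore_attr = TRUE)
})

test_that("out-of-range slice index is an error", {
  f <- linear_field(0.05, n = 8)
  dict <- c(background = 0L, blob = 1L)
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
  labels <- label_volume(lab, dict)
  expect_error(arrow_plot(f, labels, slice_spec("coronal", 8)), "out of range")
  expect_error(arrow_plot(f, labels, slice_spec("coronal", -1)), "out of range")
})

test_that("rendering is deterministic: identical CSV bytes across reruns", {
  s <- small_series()
  f <- s$true_fields[[1]]
  spec <- slice_spec("sagittal", 12, stride = 3)
  p1 <- file.path(tempdir(), "a1.csv"); p2 <- file.path(tempdir(), "a2.csv")
  arrow_plot(f, s$labels[[1]], spec, export_csv = p1)
  arrow_plot(f, s$labels[[1]], spec, export_csv = p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
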