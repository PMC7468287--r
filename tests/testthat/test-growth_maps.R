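test_that("jacobian of the zero field is exactly 1 everywhere", {
  zero <- displacement_field(array(0, c(16, 16, 16, 3)))
  j <- jacobian_determinant(zero)
  expect_true(all(j$values == 1))
  expect_identical(j$kind, "raw")
})

test_that("jacobian of a linear field matches the closed form", {
  # u(x) = a x  =>  J = (1 + a)^3 at interior voxels, exactly for central
  # differences because the field is linear
  a <- 0.1
  j <- jacobian_determinant(linear_field(a, n = 32))
  interior <- j$values[2:31, 2:31, 2:31]
  expect_equal(max(abs(interior - (1 + a)^3)), 0, tolerance = 1e-6)
})

test_that("jacobian is spacing-invariant for fields given in mm", {
  a <- 0.07
  j1 <- jacobian_determinant(linear_field(a, n = 16, spacing = c(1, 1, 1)))
  j2 <- jacobian_determinant(linear_field(a, n = 16, spacing = c(0.5, 2, 1.3)))
  expect_equal(j1$values[8, 8, 8], j2$values[8, 8, 8], tolerance = 1e-10)
})

test_that("global growth ratio is the mask volume ratio in mm^3", {
  dict <- c(background = 0L, blob = 1L)
  la <- array(0L, c(16, 16, 16)); la[4:8, 4:8, 4:8] <- 1L      # 125 voxels
  lb <- array(0L, c(16, 16, 16)); lb[4:9, 4:8, 4:8] <- 1L      # 150 voxels
  a <- label_volume(la, dict, spacing = c(2, 1, 1))
  b <- label_volume(lb, dict, spacing = c(2, 1, 1))
  expect_equal(global_growth(a, b), 150 / 125)
})

test_that("normalization divides by the global ratio and records it", {
  j <- jacobian_determinant(linear_field(0.1, n = 16))
  jn <- normalize_jacobian(j, 1.1)
  expect_equal(jn$values, j$values / 1.1)
  expect_identical(jn$kind, "normalized")
  expect_equal(jn$global_ratio, 1.1)
  expect_error(normalize_jacobian(j, 0), "positive")
})

test_that("absolute_growth reproduces the worked normalization arithmetic", {
  expect_equal(absolute_growth(0.95, 0.09), 3.5)
  expect_equal(absolute_growth(0.95, 0.09, digits = NA), 3.55, tolerance = 1e-12)
  expect_equal(absolute_growth(1, 0), 0)
  expect_equal(absolute_growth(1.1, 0), 10)
  expect_error(absolute_growth(-0.1, 0), "positive")
})

test_that("region growth summary ranks regions by mean Jacobian", {
  s <- small_series()
  j <- jacobian_determinant(s$true_fields[[1]])
  R <- global_growth(s$labels[[1]], s$labels[[2]])
  summ <- region_growth_summary(normalize_jacobian(j, R), s$labels[[1]])
  expect_true(all(c("label", "mean_jacobian", "volume_mm3",
                    "mean_absolute_growth_pct", "present") %in% names(summ)))
  expect_false(is.unsorted(rev(summ$mean_jacobian)))
  ins <- summ$mean_jacobian[summ$label == "insula"]
  ops <- summ$mean_jacobian[summ$label %in% c("frontal_operculum",
                                              "parietal_operculum",
                                              "temporal_operculum")]
  expect_true(all(ops > ins))
})

test_that("both global-ratio estimators agree on the phantom truth", {
  # the mean-Jacobian estimator differs from the mask-volume ratio by
  # boundary-voxel and voxelization effects, which shrink with grid size;
  # at 32^3 they agree to ~2%
  s <- mid_series()
  j <- jacobian_determinant(s$true_fields[[1]])
  r_mask <- global_growth(s$labels[[1]], s$labels[[2]])
  r_jac <- global_growth_from_jacobian(j, s$labels[[1]])
  expect_equal(r_mask, r_jac, tolerance = 0.03)
})
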