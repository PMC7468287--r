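test_that("registration_params validates invariants", {
  expect_s3_class(registration_params(), "registration_params")
  expect_error(registration_params(levels = 0), "levels")
  expect_error(registration_params(sigma_update_vox = -1), "sigma")
  expect_error(registration_params(step = 0), "step")
})

test_that("affine_transform rejects singular linear parts", {
  expect_error(affine_transform(matrix(0, 3, 3), c(0, 0, 0)), "singular")
})

test_that("affine registration recovers a known translation", {
  s <- small_series()
  fixed <- s$volumes[[1]]
  shift <- affine_transform(diag(3), c(1.5, -1, 0.5))
  moving <- apply_affine(fixed, shift)
  fit <- affine_register(moving, fixed, quick_params())
  expect_lt(fit$final_mse, 0.25 * fit$initial_mse)
  realigned <- apply_affine(moving, fit$transform)
  expect_lt(mean((realigned$values - fixed$values)^2), 0.3 * fit$initial_mse)
})

test_that("affine registration never returns worse than identity", {
  s <- small_series()
  fit <- affine_register(s$volumes[[1]], s$volumes[[1]], quick_params())
  expect_lte(fit$final_mse, fit$initial_mse)
  expect_lt(fit$final_mse, 1e-8)
})

test_that("diffeomorphic registration reduces MSE monotonically per level", {
  s <- small_series()
  fit <- diffeo_register(s$volumes[[2]], s$volumes[[1]], quick_params())
  expect_lt(fit$final_mse, fit$initial_mse)
  for (tr in fit$mse_trace$forward)
    expect_false(is.unsorted(rev(tr)))
})

test_that("recovered field is diffeomorphic (positive Jacobian)", {
  s <- small_series()
  fit <- diffeo_register(s$volumes[[2]], s$volumes[[1]], quick_params())
  expect_gt(fit$min_jacobian, 0)
  j <- jacobian_determinant(fit$field)
  expect_gt(min(j$values), 0)
})

test_that("registration is deterministic", {
  s <- small_series()
  f1 <- diffeo_register(s$volumes[[2]], s$volumes[[1]], quick_params())
  f2 <- diffeo_register(s$volumes[[2]], s$volumes[[1]], quick_params())
  expect_identical(f1$field$vectors, f2$field$vectors)
})

test_that("recovered Jacobian correlates with the ground truth over the mask", {
  # property: the method must recover the spatial growth pattern, not just
  # match intensities; computed at 32^3 where the planted pattern is
  # resolvable (see helper-fixtures.R)
  s <- mid_series()
  fit <- diffeo_register(s$volumes[[2]], s$volumes[[1]],
                         registration_params(iterations = c(120, 60)))
  j_est <- jacobian_determinant(fit$field)$values
  j_true <- jacobian_determinant(s$true_fields[[1]])$values
  mask <- s$labels[[1]]$values != 0L
  expect_gt(stats::cor(j_est[mask], j_true[mask]), 0.8)
})

test_that("warping with the zero field is the identity", {
  s <- small_series()
  zero <- displacement_field(array(0, c(dim(s$volumes[[1]]$values), 3)),
                             s$volumes[[1]]$spacing, s$volumes[[1]]$origin)
  w <- warp_volume(s$volumes[[1]], zero)
  expect_equal(w$values, s$volumes[[1]]$values, tolerance = 1e-12)
  wl <- warp_volume(s$labels[[1]], zero, "nearest")
  expect_identical(wl$values, s$labels[[1]]$values)
  expect_s3_class(wl, "label_volume")
})

test_that("invert_field composes with the field to near zero", {
  s <- small_series()
  f <- s$true_fields[[1]]
  inv <- invert_field(f)
  # x + u_inv(x) + u(x + u_inv(x)) should be ~ x on the interior
  dm <- dim(f$vectors)[1:3]
  mid <- as.integer(dm / 2)
  ivals <- vapply(1:3, function(a) inv$vectors[mid[1], mid[2], mid[3], a], 0)
  pt <- (mid - 1) * f$spacing + f$origin + ivals
  vox <- (pt - f$origin) / f$spacing
  fwd <- vapply(1:3, function(a)
    morphogrowth:::interp3(f$vectors[, , , a], matrix(vox, 1), mode = "clamp"), 0)
  expect_lt(sqrt(sum((ivals + fwd)^2)), 0.05)
})
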