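test_that("phantom_spec validates its invariants", {
  expect_s3_class(small_spec(), "phantom_spec")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "16")
  expect_error(phantom_spec(n_weeks = 1), "n_weeks")
  expect_error(phantom_spec(global_growth_per_week = -1), "growth")
  expect_error(phantom_spec(convergence_amplitude_mm = -0.1), "convergence")
})

test_that("generated series has the expected structure and labels", {
  s <- small_series()
  expect_s3_class(s, "growth_series")
  expect_length(s$volumes, 2)
  expect_length(s$labels, 2)
  expect_length(s$true_fields, 1)
  present <- sort(unique(as.vector(s$labels[[1]]$values)))
  expect_setequal(present, unname(s$label_dict))
  expect_true(all(c("insula", "frontal_operculum", "parietal_operculum",
                    "temporal_operculum") %in% names(s$label_dict)))
  expect_true(all(s$volumes[[1]]$values >= -0.1 & s$volumes[[1]]$values <= 1.1))
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(small_spec(seed = 11))
  b <- generate_phantom(small_spec(seed = 11))
  c <- generate_phantom(small_spec(seed = 12))
  expect_identical(a$volumes[[2]]$values, b$volumes[[2]]$values)
  expect_identical(a$true_fields[[1]]$vectors, b$true_fields[[1]]$vectors)
  expect_false(identical(a$volumes[[2]]$values, c$volumes[[2]]$values))
})

test_that("degenerate phantom (uniform expansion only) has J equal to 1 + g", {
  g <- 0.05
  s <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24), n_weeks = 2,
                                     global_growth_per_week = g,
                                     opercular_excess_growth = 0,
                                     convergence_amplitude_mm = 0))
  j <- jacobian_determinant(s$true_fields[[1]])
  mask <- s$labels[[1]]$values != 0L
  inner <- array(FALSE, dim(mask))
  inner[3:22, 3:22, 3:22] <- TRUE
  expect_equal(mean(j$values[mask & inner]), 1 + g, tolerance = 5e-3)
  expect_lt(stats::sd(j$values[mask & inner]), 5e-3)
})

test_that("true field is diffeomorphic and mask growth tracks the planted rate", {
  s <- small_series()
  j <- jacobian_determinant(s$true_fields[[1]])
  mask <- s$labels[[1]]$values != 0L
  expect_gt(min(j$values[mask]), 0)
  # quantitative rate check on the 32^3 series (see helper-fixtures.R)
  m <- mid_series()
  R <- global_growth(m$labels[[1]], m$labels[[2]])
  expect_equal(R, 1 + m$spec$global_growth_per_week, tolerance = 0.02)
})

test_that("planted regional ordering: opercula grow faster than insula", {
  s <- small_series()
  j <- jacobian_determinant(s$true_fields[[1]])
  lab <- s$labels[[1]]$values
  d <- s$label_dict
  op <- j$values[lab %in% d[c("frontal_operculum", "parietal_operculum",
                              "temporal_operculum")]]
  ins <- j$values[lab == d[["insula"]]]
  expect_gt(mean(op), mean(ins))
})

test_that("write_phantom emits per-week volumes, labels, fields and a YAML spec", {
  dir <- file.path(tempdir(), "phantom_out")
  files <- write_phantom(small_series(), dir)
  expect_true(all(file.exists(files)))
  expect_length(grep("intensity", files), 2)
  expect_length(grep("labels", files), 2)
  expect_length(grep("true_field", files), 1)
  spec_read <- yaml::read_yaml(file.path(dir, "phantom_spec.yaml"))
  expect_equal(spec_read$n_weeks, 2)
  v <- read_volume(file.path(dir, "week00_intensity.nii.gz"))
  expect_equal(v$values, small_series()$volumes[[1]]$values, tolerance = 1e-6)
})
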