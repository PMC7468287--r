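make_labels <- function(fill) {
  arr <- array(0L, c(10, 10, 10))
  fill(arr)
}

test_that("identical segmentations score Dice 1 for every label", {
  s <- small_series()
  rep <- multiclass_dice(s$labels[[1]], s$labels[[1]])
  expect_true(all(rep$per_label$dice == 1))
  expect_equal(rep$macro_dice, 1)
  expect_equal(rep$weighted_dice, 1)
})

test_that("disjoint segmentations score 0; partial overlap matches closed form", {
  dict <- c(background = 0L, blob = 1L)
  a <- array(0L, c(10, 10, 10)); a[1:4, , ] <- 1L
  b <- array(0L, c(10, 10, 10)); b[7:10, , ] <- 1L
  expect_equal(multiclass_dice(label_volume(a, dict),
                               label_volume(b, dict))$macro_dice, 0)
  # half-overlapping slabs: |A|=|B|=400, intersection 200 -> Dice 0.5
  b2 <- array(0L, c(10, 10, 10)); b2[3:6, , ] <- 1L
  expect_equal(multiclass_dice(label_volume(a, dict),
                               label_volume(b2, dict))$macro_dice, 0.5)
})

test_that("labels absent from both inputs are excluded, background never counts", {
  dict <- c(background = 0L, blob = 1L, ghost = 2L)
  a <- array(0L, c(10, 10, 10)); a[1:5, , ] <- 1L
  b <- a
  rep <- multiclass_dice(label_volume(a, dict), label_volume(b, dict))
  expect_identical(rep$per_label$label, "blob")
  expect_equal(rep$macro_dice, 1)
  # all-background comparison is an error, not a vacuous 1
  z <- label_volume(array(0L, c(10, 10, 10)), dict)
  expect_error(multiclass_dice(z, z), "foreground")
})

test_that("a label present in only one input scores 0 and drags the macro mean", {
  dict <- c(background = 0L, blob = 1L, extra = 2L)
  a <- array(0L, c(10, 10, 10)); a[1:5, , ] <- 1L
  b <- a; b[8, 8, 8] <- 2L
  rep <- multiclass_dice(label_volume(a, dict), label_volume(b, dict))
  expect_equal(sort(rep$per_label$dice), c(0, 2 * 500 / (500 + 500)))
  expect_equal(rep$macro_dice, 0.5)
})

test_that("dice is symmetric", {
  s <- small_series()
  zero <- displacement_field(array(0, c(dim(s$labels[[1]]$values), 3)))
  shifted <- warp_volume(s$labels[[2]], s$true_fields[[1]], "nearest")
  r1 <- multiclass_dice(s$labels[[1]], shifted)
  r2 <- multiclass_dice(shifted, s$labels[[1]])
  expect_equal(r1$macro_dice, r2$macro_dice, tolerance = 1e-12)
})

test_that("validate_registration with the true fields gives near-perfect overlap", {
  s <- small_series()
  out <- validate_registration(s, s$true_fields)
  expect_equal(nrow(out), 1)
  expect_gt(out$macro_dice, 0.85)
  expect_gt(out$weighted_dice, 0.9)
  reports <- attr(out, "reports")
  expect_s3_class(reports[[1]], "dice_report")
  expect_error(validate_registration(s, c(s$true_fields, s$true_fields)),
               "one displacement field per")
})
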