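test_that("dice_score matches hand counts and is symmetric", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  expect_identical(dice_score(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_identical(dice_score(a, b), 0)
  # |pred| = 8, |truth| = 8, overlap 4 -> 2*4/16
  p <- array(FALSE, c(4, 4, 4)); p[1:2, 1:2, 1:2] <- TRUE
  t <- array(FALSE, c(4, 4, 4)); t[1:2, 1:2, 2:3] <- TRUE
  expect_equal(dice_score(p, t), 0.5)
  set.seed(11)
  for (rep in 1:5) {
    x <- array(runif(64) < 0.4, c(4, 4, 4))
    y <- array(runif(64) < 0.4, c(4, 4, 4))
    expect_equal(dice_score(x, y), dice_score(y, x))
  }
  expect_warning(res <- dice_score(array(FALSE, c(2, 2, 2)),
                                   array(FALSE, c(2, 2, 2))), "empty")
  expect_equal(res, 1)
  expect_error(dice_score(a, array(FALSE, c(3, 3, 3))),
               class = "fp_error_value")
})

test_that("multiclass_dice reports per-class and macro values", {
  set.seed(12)
  vox <- array(sample(0:3, 16^3, TRUE), c(16, 16, 16))
  v <- label_volume(vox, spacing = rep(0.5, 3))
  self <- multiclass_dice(v, v)
  expect_equal(unname(self$per_class_dice), rep(1, 3))
  expect_equal(self$mean_dice, 1)
  expect_equal(self$pooled_dice, 1)

  # erode class 2 by one voxel and check against an exhaustive count
  m2 <- vox == 2L
  er <- erode6_oracle(m2)
  vox2 <- vox; vox2[m2 & !er] <- 0L
  v2 <- label_volume(vox2, spacing = rep(0.5, 3))
  rep2 <- multiclass_dice(v2, v)
  expect_equal(unname(rep2$per_class_dice["ulna"]),
               2 * sum(er & m2) / (sum(er) + sum(m2)))
  expect_equal(rep2$mean_dice, mean(rep2$per_class_dice))

  # prediction missing a class entirely scores 0 there
  vox3 <- vox; vox3[vox3 == 3L] <- 0L
  rep3 <- multiclass_dice(label_volume(vox3, spacing = rep(0.5, 3)), v)
  expect_equal(unname(rep3$per_class_dice["tfcc"]), 0)
})

test_that("soft_iou_loss equals direct formula evaluation", {
  # perfect binary prediction of 100 foreground voxels, eta = 1
  t <- array(TRUE, c(10, 10, 1))
  expect_equal(soft_iou_loss(array(1, c(10, 10, 1)), t, eta = 1),
               1 - 100 / 101)
  # all-zero prediction against non-empty truth
  expect_equal(soft_iou_loss(array(0, c(10, 10, 1)), t, eta = 0.5), 1)
  # y = (1,1), yhat = (1,0), eta = 0: numerator 1, denominator 2
  expect_equal(soft_iou_loss(array(c(1, 0), c(2, 1, 1)),
                             array(c(TRUE, TRUE), c(2, 1, 1)), eta = 0),
               0.5)
  expect_error(soft_iou_loss(array(1.5, c(1, 1, 1)),
                             array(TRUE, c(1, 1, 1))),
               class = "fp_error_value")
  expect_error(soft_iou_loss(array(1, c(1, 1, 1)),
                             array(TRUE, c(1, 1, 1)), eta = -1),
               class = "fp_error_value")
})

test_that("binary soft IoU reduces to 1 - IoU and links to Dice", {
  set.seed(13)
  for (rep in 1:10) {
    p <- array(runif(125) < 0.5, c(5, 5, 5))
    t <- array(runif(125) < 0.5, c(5, 5, 5))
    if (!any(p | t)) next
    iou <- sum(p & t) / sum(p | t)
    loss <- soft_iou_loss(array(as.numeric(p), dim(p)), t, eta = 0)
    expect_equal(loss, 1 - iou, tolerance = 1e-12)
    if (sum(p) + sum(t) > 0)
      expect_equal(dice_score(p, t), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("soft IoU loss stays within [0, 1] for random probability maps", {
  set.seed(14)
  for (rep in 1:10) {
    p <- array(runif(64), c(4, 4, 4))
    t <- array(runif(64) < 0.5, c(4, 4, 4))
    l <- soft_iou_loss(p, t, eta = runif(1, 0, 2))
    expect_gte(l, 0); expect_lte(l, 1)
  }
})
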