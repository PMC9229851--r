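# Dice objective and the evaluation suite.

test_that("dice coefficient follows the smoothed overlap formula", {
  m <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_coefficient(m, m), 1, tolerance = 1e-6)
  expect_equal(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2), w = 1e-5), 1)
  P <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2)
  G <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2)
  expect_equal(dice_coefficient(P, G, w = 0), 0.5)   # |P|=|G|=4, overlap 2
  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("dice loss is exactly one minus soft dice and spans [0,1]", {
  set.seed(1)
  p <- array(runif(200), c(10, 20))
  g <- array(rbinom(200, 1, 0.3), c(10, 20))
  expect_equal(dice_loss(p, g, 1e-5) + dice_coefficient(p, g, 1e-5), 1)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)
  gh <- array(rep(c(0, 1), 100), c(10, 20))
  expect_equal(dice_loss(1 - gh, gh, w = 1e-12), 1, tolerance = 1e-9)
  # probs all 0.5 against a half-foreground mask: soft intersection |G|/2,
  # totals N/2 + |G| = 2|G|, so soft Dice is 1/2 and the loss is 1/2
  expect_equal(dice_loss(array(0.5, dim(gh)), gh, w = 0), 0.5)
})

test_that("confusion counts classify every FOV pixel exactly once", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]), c(TP = 1, FP = 1,
                                                        FN = 1, TN = 1))
  set.seed(2)
  pred <- rbinom(500, 1, 0.4); g <- rbinom(500, 1, 0.3)
  fov <- rbinom(500, 1, 0.8)
  cc <- confusion(pred, g, fov)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, sum(fov))
  cc2 <- confusion(pred, g)
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 500)
  perfect <- confusion(g, g)
  expect_equal(perfect$FP + perfect$FN, 0)
  # removing a pixel from the FOV removes it from exactly one cell
  fov3 <- rep(1, 4); fov3[2] <- 0
  cc3 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), fov3)
  expect_equal(unlist(cc3[c("TP", "FP", "FN", "TN")]), c(TP = 1, FP = 0,
                                                         FN = 1, TN = 1))
})

test_that("the report reproduces the five ratio formulas and flags undefined
           ratios instead of zeroing them", {
  r <- report(c(1, 1, 0, 0), c(1, 0, 1, 0), threshold = 0.5)
  for (k in c("dice", "accuracy", "sensitivity", "specificity", "precision"))
    expect_equal(r[[k]], 0.5)
  w <- testthat::capture_warnings(r0 <- report(c(0, 0), c(0, 0),
                                               threshold = 0.5))
  expect_true(any(grepl("sensitivity", w)))
  expect_true(is.na(r0$sensitivity))
  expect_false(isTRUE(r0$specificity == 0))
})

test_that("trapezoidal AUCs agree with the Mann-Whitney rank statistic", {
  ns <- asNamespace("mtpaunet")
  set.seed(3)
  for (n in c(200, 1000)) {
    s <- runif(n); y <- rbinom(n, 1, 0.4)
    a <- ns$roc_pr_curves(s, y)$auc_roc
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    rk <- rank(s)
    mw <- (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_lt(abs(a - mw), 1e-6)
  }
  # heavy ties
  s <- round(runif(600), 1); y <- rbinom(600, 1, 0.5)
  a <- ns$roc_pr_curves(s, y)$auc_roc
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  mw <- (sum(rank(s)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_lt(abs(a - mw), 1e-6)
  # perfect scores give area 1; random scores on many pixels give ~0.5
  g <- rbinom(100, 1, 0.5)
  expect_equal(ns$roc_pr_curves(g, g)$auc_roc, 1)
  set.seed(4)
  s <- runif(1e5); y <- rbinom(1e5, 1, 0.3)
  expect_lt(abs(ns$roc_pr_curves(s, y)$auc_roc - 0.5), 0.05)
})

test_that("reports serialize to flat records and curve tables", {
  set.seed(5)
  s <- runif(256); g <- rbinom(256, 1, 0.3)
  r <- report(s, g, threshold = 0.5)
  lines <- write_report(r)
  expect_true(any(grepl("^dice\t", lines)))
  expect_true(any(grepl("^TP\t", lines)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, path)
  expect_true(file.exists(path))
  curve <- write_curve(r, "roc")
  expect_identical(colnames(curve), c("fpr", "tpr"))
  expect_equal(curve[1, ], c(fpr = 0, tpr = 0))
  expect_equal(unname(curve[nrow(curve), ]), c(1, 1))
})
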