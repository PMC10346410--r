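test_that("confusion tabulates pixel pairs exactly", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  pred  <- matrix(c(0L, 2L, 2L, 1L), 2, 2)
  cm <- confusion(truth, pred, num_classes = 3L)
  expect_equal(sum(cm), 4)
  expect_equal(unclass(cm)[1, 1], 1)   # background right
  expect_equal(unclass(cm)[2, 2], 1)   # one trunk right
  expect_equal(unclass(cm)[2, 3], 1)   # one trunk called branch
  expect_equal(unclass(cm)[3, 3], 1)

  m <- matrix(sample(0:2, 64, TRUE), 8, 8)
  expect_true(all(unclass(confusion(m, m)) == diag(as.vector(table(factor(m, 0:2))))))
  expect_error(confusion(m, m[1:4, ]), "shape")
})

test_that("segmentation metrics follow the per-class definitions", {
  perfect <- confusion(matrix(0:2, 3, 3), matrix(0:2, 3, 3))
  sm <- seg_metrics(perfect)
  expect_equal(unlist(sm[c("miou", "precision", "recall", "f1")]),
               c(miou = 1, precision = 1, recall = 1, f1 = 1))

  # every class TP=50 FP=10 FN=10: IoU 5/7, P=R=F1=5/6
  cm <- matrix(5L, 3, 3); diag(cm) <- 50L
  sm2 <- seg_metrics(cm)
  expect_equal(sm2$miou, 50 / 70)
  expect_equal(sm2$precision, 5 / 6)
  expect_equal(sm2$recall, 5 / 6)
  expect_equal(sm2$f1, 5 / 6)

  # all-wrong single-class prediction on a two-class truth
  truth <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  pred <- matrix(1L, 2, 2)
  sm3 <- suppressWarnings(seg_metrics(confusion(truth, pred)))
  expect_lt(sm3$miou, 0.5)
})

test_that("metrics agree with a brute-force oracle and respect invariants", {
  set.seed(5)
  for (i in 1:20) {
    truth <- matrix(sample(0:2, 256, TRUE), 16, 16)
    pred <- matrix(sample(0:2, 256, TRUE), 16, 16)
    sm <- seg_metrics(confusion(truth, pred, 3L))
    bf <- brute_seg_metrics(truth, pred, 3L)
    expect_equal(sm$miou, bf$miou)
    expect_equal(sm$precision, bf$precision)
    expect_equal(sm$recall, bf$recall)
    expect_equal(sm$f1, bf$f1)
    vals <- unlist(sm[c("miou", "precision", "recall", "f1")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(sm$f1, 2 * sm$precision * sm$recall /
                   (sm$precision + sm$recall))
    # label permutation applied to both masks leaves MIoU unchanged
    perm <- sample(0:2)
    sm_p <- seg_metrics(confusion(matrix(perm[truth + 1L], 16, 16),
                                  matrix(perm[pred + 1L], 16, 16), 3L))
    expect_equal(sm_p$miou, sm$miou)
  }
})

test_that("empty classes contribute zero with a warning", {
  truth <- matrix(0L, 4, 4)
  pred <- matrix(0L, 4, 4)
  w <- capture_warnings(sm <- seg_metrics(confusion(truth, pred, 3L)))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 3L)   # IoU, precision, recall each warn once
  expect_equal(sm$miou, 1 / 3)
})

test_that("agreement computes R2 and RMSE as defined", {
  ex <- agreement(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ex$r2, 1)
  expect_equal(ex$rmse, 0)

  toy <- agreement(c(1, 2, 3), c(2, 2, 2))
  expect_equal(toy$rmse, sqrt(2 / 3))
  expect_equal(toy$r2, 0)

  off <- agreement(c(1, 2, 3), c(1, 2, 3) + 0.5)
  expect_equal(off$rmse, 0.5)

  expect_warning(cst <- agreement(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(cst$r2))
  expect_error(agreement(1:3, 1:2), "length")
  # R2 = 1 iff RMSE = 0 on non-constant references
  set.seed(8)
  t <- rnorm(10); m <- t + rnorm(10, 0, 0.1)
  a <- agreement(t, m)
  expect_lt(a$r2, 1)
  expect_gt(a$rmse, 0)
})
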