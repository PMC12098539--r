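# Brute-force HD95 oracle: boundary = pixels with a 4-neighbour outside the
# mask (or on the image edge), all-pairs distances, pooled 95th percentile.
hd95_oracle <- function(pred, truth) {
  bnd <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    keep <- apply(idx, 1, function(rc) {
      i <- rc[1]; j <- rc[2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      any(apply(nb, 1, function(p) {
        p[1] < 1 || p[1] > nrow(m) || p[2] < 1 || p[2] > ncol(m) ||
          m[p[1], p[2]] == 0
      }))
    })
    idx[keep, , drop = FALSE]
  }
  a <- bnd(pred); b <- bnd(truth)
  dists <- c()
  for (r in seq_len(nrow(a)))
    dists <- c(dists, min(sqrt((a[r, 1] - b[, 1])^2 + (a[r, 2] - b[, 2])^2)))
  for (r in seq_len(nrow(b)))
    dists <- c(dists, min(sqrt((b[r, 1] - a[, 1])^2 + (b[r, 2] - a[, 2])^2)))
  unname(stats::quantile(dists, 0.95))
}

test_that("confusion counts are exact on constructed masks", {
  ten <- matrix(1, 2, 5)
  expect_equal(confusion_counts(ten, ten), list(TP = 10L, TN = 0L, FP = 0L, FN = 0L))
  expect_equal(confusion_counts(ten, 1 - ten)[c("TP", "TN")], list(TP = 0L, TN = 0L))
  # constructed 10-pixel pair with TP=3, TN=4, FP=2, FN=1
  pred <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2, 5)
  truth <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0), 2, 5)
  k <- confusion_counts(pred, truth)
  expect_equal(k, list(TP = 3L, TN = 4L, FP = 2L, FN = 1L))
  expect_equal(k$TP + k$TN + k$FP + k$FN, 10L)
  expect_error(confusion_counts(pred, truth * 2), "binary")
  expect_error(confusion_counts(pred, matrix(0, 3, 3)), "shape")
})

test_that("ratio metrics match the hand-worked example and the Dice-Jaccard identity", {
  k <- list(TP = 3, TN = 4, FP = 2, FN = 1)
  expect_equal(metric_oa(k), 0.7)
  expect_equal(metric_aa(k), (3 / 4 + 4 / 6) / 2)
  expect_equal(metric_dsc(k), 6 / 9)
  expect_equal(metric_jaccard(k), 0.5)
  expect_equal(dsc_from_jaccard(0.5), metric_dsc(k))
  # perfect prediction
  m <- random_mask(6, 6)
  expect_equal(metric_oa(m, m), 1)
  expect_equal(metric_dsc(m, m), 1)
  expect_equal(metric_jaccard(m, m), 1)
  # per-image identity DSC = 2J/(1+J) on random pairs, and J <= DSC
  set.seed(31)
  for (r in 1:25) {
    a <- random_mask(8, 8, stats::runif(1, 0.2, 0.8))
    b <- random_mask(8, 8, stats::runif(1, 0.2, 0.8))
    if (sum(a) + sum(b) == 0) next
    j <- metric_jaccard(a, b); d <- metric_dsc(a, b)
    expect_equal(d, dsc_from_jaccard(j), tolerance = 1e-12)
    expect_lte(j, d)
  }
  # undefined cases are NA with a warning
  z <- matrix(0, 3, 3)
  expect_warning(expect_true(is.na(metric_dsc(z, z))), "undefined")
  expect_warning(expect_true(is.na(metric_aa(matrix(1, 2, 2), matrix(1, 2, 2)))),
                 "undefined")
})

test_that("metrics are invariant to pixel order; OA also to label swap", {
  set.seed(32)
  a <- random_mask(5, 5); b <- random_mask(5, 5)
  perm <- sample(25)
  ap <- matrix(as.vector(a)[perm], 5, 5); bp <- matrix(as.vector(b)[perm], 5, 5)
  expect_equal(metric_oa(ap, bp), metric_oa(a, b))
  expect_equal(metric_dsc(ap, bp), metric_dsc(a, b))
  expect_equal(metric_jaccard(ap, bp), metric_jaccard(a, b))
  # OA is symmetric under simultaneous label flip; Dice generally is not
  expect_equal(metric_oa(1 - a, 1 - b), metric_oa(a, b))
})

test_that("HD95 agrees with the brute-force oracle on small masks", {
  # identical masks -> 0
  m <- matrix(0, 6, 6); m[2:4, 2:4] <- 1
  expect_equal(metric_hd95(m, m), 0)
  # one-pixel shift -> 1
  a <- matrix(0, 5, 5); a[2:3, 2:3] <- 1
  b <- matrix(0, 5, 5); b[3:4, 2:3] <- 1
  expect_equal(metric_hd95(a, b), hd95_oracle(a, b))
  expect_equal(metric_hd95(a, b), 1.0)
  # random masks up to 12x12, exhaustive against the oracle
  set.seed(33)
  for (r in 1:20) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    x <- random_mask(h, w, 0.5); y <- random_mask(h, w, 0.5)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(metric_hd95(x, y), hd95_oracle(x, y), tolerance = 1e-12)
    expect_equal(metric_hd95(x, y), metric_hd95(y, x))
  }
  expect_warning(expect_true(is.na(metric_hd95(a, matrix(0, 5, 5)))), "empty")
})

test_that("aggregation reports mean/sd and exposes the Dice-averaging gap", {
  r1 <- data.frame(OA = 0.9, AA = 0.8, DSC = dsc_from_jaccard(0.5), Jaccard = 0.5,
                   HD95 = 2)
  agg1 <- aggregate_reports(r1)
  expect_equal(agg1$mean[agg1$metric == "DSC"], 2 / 3)
  expect_equal(agg1$sd, rep(0, 5))
  # two folds with Jaccard 0.5 and 0.8: mean DSC != f(mean J)
  r2 <- rbind(r1, data.frame(OA = 0.95, AA = 0.9, DSC = dsc_from_jaccard(0.8),
                             Jaccard = 0.8, HD95 = 1))
  agg2 <- aggregate_reports(r2)
  mean_dsc <- agg2$mean[agg2$metric == "DSC"]
  mean_j <- agg2$mean[agg2$metric == "Jaccard"]
  expect_equal(mean_dsc, (dsc_from_jaccard(0.5) + dsc_from_jaccard(0.8)) / 2)
  expect_false(isTRUE(all.equal(mean_dsc, dsc_from_jaccard(mean_j))))
  expect_gt(dsc_from_jaccard(mean_j), mean_dsc)  # concavity direction
  # identical folds close the gap
  r3 <- rbind(r1, r1)
  agg3 <- aggregate_reports(r3)
  expect_equal(agg3$mean[agg3$metric == "DSC"],
               dsc_from_jaccard(agg3$mean[agg3$metric == "Jaccard"]))
  # undefined entries are excluded
  r4 <- rbind(r1, data.frame(OA = 0.9, AA = NA, DSC = NA, Jaccard = NA, HD95 = NA))
  agg4 <- aggregate_reports(r4)
  expect_equal(agg4$n[agg4$metric == "DSC"], 1L)
})
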