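test_that("AJI matches the hand-derived worked example and edge cases", {
  gt <- matrix(0L, 4, 4)
  gt[1, 1] <- 1L; gt[1, 2] <- 1L   # G1 = {(0,0),(0,1)}
  gt[4, 4] <- 2L                   # G2 = {(3,3)}
  pr <- matrix(0L, 4, 4)
  pr[1, 1] <- 1L; pr[1, 2] <- 1L   # P1 = G1
  pr[3, 3] <- 2L                   # P2 disjoint
  # G1 matches P1 (2/2); G2 has no intersecting prediction (+1); P2 unused (+1)
  expect_equal(aji(gt, pr), 2 / (2 + 1 + 1))
  expect_equal(aji(gt, gt), 1.0)
  expect_equal(aji(gt, matrix(0L, 4, 4)), 0.0)
  expect_equal(aji(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1.0)
  expect_error(aji(gt, matrix(0L, 3, 3)), "shape mismatch")
})

test_that("Dice follows its definition and conventions", {
  g <- matrix(c(rep(1, 4), rep(0, 6)), 2, 5)
  p <- matrix(c(0, rep(1, 6), rep(0, 3)), 2, 5)
  # |G| = 4, |P| = 6, |G intersect P| = 3 -> 0.6
  expect_equal(sum(g), 4); expect_equal(sum(p), 6); expect_equal(sum(g & p), 3)
  expect_equal(dice(g, p), 0.6)
  expect_equal(dice(g, g), 1.0)
  expect_equal(dice(g, 1 - g), 0.0)
  expect_equal(dice(g * 0, g * 0), 1.0)
})

test_that("panoptic quality implements the IoU > 0.5 matching rule", {
  gt <- matrix(0L, 8, 8)
  gt[1:3, 1:3] <- 1L
  gt[6:8, 6:8] <- 2L
  pr <- matrix(0L, 8, 8)
  pr[1:3, 1:3] <- 1L   # exact reproduction of G1
  pr[6:7, 1:2] <- 2L   # spurious blob
  r <- panoptic_quality(gt, pr)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 1L)
  expect_equal(r$sq, 1.0)
  expect_equal(r$rq, 0.5)
  expect_equal(r$pq, 0.5)
  perfect <- panoptic_quality(gt, gt)
  expect_equal(perfect$pq, 1.0)
  empty <- panoptic_quality(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(empty$pq, 1.0)
  expect_equal(empty$tp + empty$fp + empty$fn, 0L)
})

test_that("extract_instances thresholds, labels and filters", {
  p <- matrix(0, 10, 10)
  p[2:3, 2:3] <- 0.9
  p[8:9, 7:9] <- 0.8
  m <- extract_instances(p, 0.5, min_size = 0L)
  expect_equal(max(m), 2L)
  expect_equal(m[2, 2], 1L)  # raster-scan order: top blob first
  expect_equal(m[8, 8], 2L)
  expect_equal(max(extract_instances(matrix(0, 5, 5), 0.5, 0L)), 0L)
  # a 100-pixel blob removed by min_size = 150
  q <- matrix(0, 20, 20)
  q[1:10, 1:10] <- 1 - 1e-9
  expect_equal(sum(q > 0.5), 100)
  expect_equal(max(extract_instances(q, 0.5, min_size = 150L)), 0L)
  expect_equal(max(extract_instances(q, 0.5, min_size = 100L)), 1L)
  # connectivity: diagonal pixels split under 4, joined under 8
  dg <- matrix(0, 4, 4); dg[1, 1] <- 1; dg[2, 2] <- 1
  expect_equal(max(extract_instances(dg, 0.5, 0L, 4L)), 2L)
  expect_equal(max(extract_instances(dg, 0.5, 0L, 8L)), 1L)
})

test_that("metrics agree exactly with brute-force oracles under fuzzing", {
  set.seed(424)
  for (rep in 1:60) {
    gt <- random_instance_map(16, 16, 5)
    pr <- random_instance_map(16, 16, 5)
    expect_identical(aji(gt, pr), oracle_aji(gt, pr))
    expect_identical(dice(gt > 0, pr > 0), oracle_dice(gt, pr))
    r <- panoptic_quality(gt, pr)
    o <- oracle_pq(gt, pr)
    expect_identical(r$pq, o$pq)
    expect_identical(c(r$tp, r$fp, r$fn), as.integer(c(o$tp, o$fp, o$fn)))
    # bounds and self-perfection
    expect_true(r$pq >= 0 && r$pq <= 1)
    expect_true(aji(gt, pr) >= 0 && aji(gt, pr) <= 1)
    expect_equal(aji(gt, gt), 1)
    # PQ uniqueness: no gt id matched twice
    expect_false(any(duplicated(r$pairs$gt)))
    expect_false(any(duplicated(r$pairs$pred)))
  }
})

test_that("eroding a perfect prediction strictly decreases Dice", {
  gt <- matrix(0L, 12, 12)
  gt[3:9, 3:9] <- 1L
  eroded <- gt
  eroded[3, ] <- 0L  # shave one boundary row
  expect_lt(dice(gt, eroded), dice(gt, gt))
})

test_that("evaluate_pair composes extraction and all three metrics", {
  gt <- matrix(0L, 12, 12)
  gt[2:4, 2:4] <- 1L
  gt[8:10, 8:11] <- 2L
  prob <- (gt > 0) * 0.95
  r <- evaluate_pair(gt, prob, threshold = 0.5, min_size = 0L)
  expect_equal(r$aji, 1.0)
  expect_equal(r$dice, 1.0)
  expect_equal(r$pq, 1.0)
  z <- evaluate_pair(gt, matrix(0, 12, 12) + 1e-6, threshold = 0.5,
                     min_size = 0L)
  expect_equal(z$aji, 0.0)
  expect_equal(z$dice, 0.0)
  expect_equal(z$fn, 2L)
  expect_error(evaluate_pair(gt, matrix(0.1, 5, 5)), "shape mismatch")
})
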