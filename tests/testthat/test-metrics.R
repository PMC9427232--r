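test_that("psnr matches its closed form and a loop oracle", {
  m <- rand_gray(6, 6, seed = 2)
  expect_identical(psnr(m, m), Inf)
  expect_equal(psnr(matrix(10, 4, 4), matrix(11, 4, 4)),
               10 * log10(255^2), tolerance = 1e-10)  # 48.1308 dB at MSE 1
  n <- rand_gray(6, 6, seed = 3)
  mse <- 0
  for (i in 1:6) for (j in 1:6) mse <- mse + (m[i, j] - n[i, j])^2 / 36
  expect_equal(psnr(m, n), 10 * log10(255^2 / mse))
  expect_equal(psnr(m, n), psnr(n, m))
  expect_error(psnr(m, matrix(0, 2, 2)), "shape")
})

test_that("psnr decreases as noise amplitude grows", {
  ref <- rand_gray(16, 16, seed = 4)
  set.seed(5)
  eps <- matrix(rnorm(256), 16, 16)
  vals <- sapply(c(1, 4, 16), function(a)
    psnr(ref, pmin(pmax(round(ref + a * eps), 0), 255)))
  expect_true(all(diff(vals) < 0))
})

test_that("global SSIM matches hand-computed factors", {
  m <- rand_gray(8, 8, seed = 6)
  expect_equal(ssim(m, m), 1)
  # all-0 vs all-255: contrast and structure factors are 1, luminance
  # factor is b1 / (255^2 + b1)
  expect_equal(ssim(matrix(0, 8, 8), matrix(255, 8, 8)),
               6.5025 / (255^2 + 6.5025), tolerance = 1e-10)
  n <- rand_gray(8, 8, seed = 7)
  expect_equal(ssim(m, n), ssim(n, m))
})

test_that("FSIM is 1 on identical images, bounded, and orders distortions", {
  m <- rand_gray(48, 48, seed = 8)
  expect_equal(fsim(m, m), 1)
  n <- rand_gray(48, 48, seed = 9)
  v <- fsim(m, n)
  expect_true(v >= 0 && v <= 1)
  expect_equal(v, fsim(n, m))
  # a shifted ridge is closer to the ridge than pure noise is
  ridge <- ridge_image(48, row = 24)
  shifted <- ridge_image(48, row = 25)
  noise <- rand_gray(48, 48, seed = 10)
  expect_lt(fsim(ridge, shifted), 1)
  expect_gt(fsim(ridge, shifted), fsim(ridge, noise))
  expect_error(fsim(matrix(0, 8, 8), matrix(0, 8, 8)), "32x32")
})

test_that("dice and jaccard match set arithmetic and each other", {
  a <- matrix(0, 3, 3); a[1, 1:3] <- 1          # |A| = 3
  b <- matrix(0, 3, 3); b[1, 2:3] <- 1; b[2, 1:2] <- 1  # |B| = 4, |A^B| = 2
  expect_equal(dice(a, b), 4 / 7)
  expect_equal(jaccard(a, b), 2 / 5)
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  z <- matrix(0, 3, 3)
  expect_equal(dice(z, z), 1)
  expect_equal(jaccard(z, z), 1)
  d <- matrix(0, 3, 3); d[3, ] <- 1
  expect_equal(dice(a, d), 0)
  expect_equal(jaccard(a, d), 0)
  expect_error(dice(matrix(2, 2, 2), matrix(1, 2, 2)), "binary")
  for (s in 1:100) {
    x <- rand_mask(5, 5, 0.4, seed = s)
    y <- rand_mask(5, 5, 0.4, seed = 1000 + s)
    dd <- dice(x, y); jj <- jaccard(x, y)
    expect_equal(jj, dd / (2 - dd), tolerance = 1e-12)
    expect_lte(jj, dd)
  }
})

test_that("confusion counts and rates match a per-pixel oracle", {
  gt <- rand_mask(10, 10, 0.3, seed = 11)
  pred <- rand_mask(10, 10, 0.3, seed = 12)
  cc <- confusion(gt, pred)
  ref <- c(Tp = 0, TN = 0, Fp = 0, FN = 0)
  for (i in 1:10) for (j in 1:10) {
    k <- if (gt[i, j] == 1 && pred[i, j] == 1) "Tp"
    else if (gt[i, j] == 0 && pred[i, j] == 0) "TN"
    else if (gt[i, j] == 0 && pred[i, j] == 1) "Fp" else "FN"
    ref[k] <- ref[k] + 1
  }
  expect_equal(unlist(cc), ref)
  expect_equal(sum(unlist(cc)), 100)
  rates <- se_sp_acc(list(Tp = 40, FN = 10, TN = 45, Fp = 5))
  expect_equal(rates$sensitivity, 0.8)
  expect_equal(rates$specificity, 0.9)
  expect_equal(rates$accuracy, 0.85)
  perfect <- se_sp_acc(confusion(gt, gt))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  accuracy = 1))
  # zero denominator yields NA
  expect_true(is.na(se_sp_acc(list(Tp = 0, FN = 0, TN = 5, Fp = 5))$sensitivity))
})

test_that("shannon entropy of class proportions behaves as expected", {
  lab <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(shannon_entropy(lab), 1)
  expect_equal(shannon_entropy(matrix(3L, 4, 4)), 0)
  lab2 <- matrix(0L, 10, 10); lab2[1, 1:2] <- 1L; lab2[1, 3] <- 2L
  expect_equal(shannon_entropy(lab2),
               -(0.97 * log2(0.97) + 0.02 * log2(0.02) + 0.01 * log2(0.01)))
  # maximal iff equal proportions
  lab3 <- matrix(rep(0:3, each = 4), 4, 4)
  expect_equal(shannon_entropy(lab3), 2)
})

test_that("region uniformity is 1 for constant regions, else hand value", {
  img <- matrix(7, 4, 4)
  expect_equal(region_uniformity(img, matrix(0L, 4, 4)), 1)
  img2 <- matrix(c(10, 10, 200, 200), 2, 2)
  lab2 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(region_uniformity(img2, lab2), 1)
  # 3x3: region 0 holds values {0, 10} (range 10, mean 5, SS = 50),
  # region 1 is constant
  img3 <- matrix(100, 3, 3); img3[1, 1] <- 0; img3[1, 2] <- 10
  lab3 <- matrix(1L, 3, 3); lab3[1, 1:2] <- 0L
  expect_equal(region_uniformity(img3, lab3), 1 - (50 / 100) / 9)
})

test_that("metrics_report assembles all ten indicators", {
  img <- rand_gray(48, 48, seed = 13)
  tv <- c(80, 170)
  lab <- apply_thresholds(img, tv)
  rec <- reconstruct_classes(img, tv)
  rep <- metrics_report(img, rec, lab, gt_mask = rand_mask(48, 48, seed = 14),
                        pred_mask = rand_mask(48, 48, seed = 15))
  expect_named(rep, c("psnr", "ssim", "fsim", "shannon_entropy",
                      "region_uniformity", "dice", "jaccard", "sensitivity",
                      "specificity", "accuracy"), ignore.order = TRUE)
  expect_true(all(sapply(rep, is.numeric)))
  rep2 <- metrics_report(img, rec, lab)
  expect_true(is.na(rep2$dice))
})
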