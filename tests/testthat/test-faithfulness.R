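test_that("top-k masks mark exactly ceil(p%) pixels with raster-order ties", {
  sal <- matrix(runif(100, 0.2, 0.8), 10, 10)
  expect_true(all(topk_mask(sal, 100)))
  expect_equal(sum(topk_mask(sal, 18)), 18L)
  for (p in c(18, 30, 40, 50)) {
    expect_equal(sum(topk_mask(sal, p)), ceiling(p))
  }
  # constant map: first pixels in column-major raster order
  const <- matrix(1, 10, 10)
  m <- topk_mask(const, 50)
  expect_identical(which(as.vector(m)), 1:50)
  # masks along the grid are nested (shared ordering)
  m18 <- topk_mask(sal, 18); m50 <- topk_mask(sal, 50)
  expect_true(all(m50[m18]))
})

test_that("perturbation round-trips between original and blurred images", {
  withr::with_seed(1, img <- matrix(runif(32 * 32), 32, 32))
  blurred <- blur_image(img)
  none <- matrix(FALSE, 32, 32)
  full <- matrix(TRUE, 32, 32)
  expect_identical(perturb(img, none, "deletion", blurred = blurred), img)
  expect_identical(perturb(img, full, "insertion", blurred = blurred), img)
  expect_identical(perturb(img, full, "deletion", blurred = blurred), blurred)
  expect_identical(perturb(img, none, "insertion", blurred = blurred), blurred)
  expect_error(perturb(img, none[1:10, 1:10], "deletion"),
               class = "coopAS_invalid_input")
})

test_that("baseline saliencies are area-matched random or deterministic uniform", {
  r1 <- baseline_saliency("random", c(12, 12), seed = 1)
  r2 <- baseline_saliency("random", c(12, 12), seed = 2)
  expect_equal(sum(topk_mask(r1, 30)), sum(topk_mask(r2, 30)))
  expect_false(identical(topk_mask(r1, 30), topk_mask(r2, 30)))
  expect_equal(baseline_saliency("uniform", c(5, 7)), matrix(1, 5, 7))
  # each pixel's inclusion frequency at p=50 is binomial around 1/2
  freq <- withr::with_seed(3, {
    acc <- matrix(0, 8, 8)
    for (i in 1:500) {
      acc <- acc + topk_mask(baseline_saliency("random", c(8, 8)), 50)
    }
    acc / 500
  })
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 500)))
})

test_that("perturbation curves evaluate the score over the coverage grid", {
  withr::with_seed(4, img <- matrix(runif(32 * 32), 32, 32))
  region <- matrix(FALSE, 32, 32); region[8:16, 8:16] <- TRUE
  score_fn <- function(im) mean(im[region])
  sal <- matrix(0, 32, 32); sal[region] <- 1  # oracle saliency
  del <- perturbation_curve(score_fn, img, sal,
                            perturbation_protocol("deletion"))
  expect_equal(nrow(del), 4L)
  expect_equal(del$coverage, c(18, 30, 40, 50))
  # full-coverage insertion restores the original image's score bit-exactly
  ins <- perturbation_curve(score_fn, img, sal,
                            perturbation_protocol("insertion",
                                                  coverage_grid = c(50, 100)))
  expect_identical(ins$score[2], score_fn(img))
})

test_that("AOPC variants reduce curves as documented", {
  curve <- data.frame(coverage = c(18, 30, 40, 50), score = c(4, 3, 2, 1))
  expect_equal(aopc(curve, reference = 5, mode = "deletion"), 2.5)
  expect_equal(aopc(data.frame(coverage = 1:4, score = c(1, 2, 3, 4)),
                    variant = "raw-average"), 2.5)
  flat <- data.frame(coverage = c(18, 30), score = c(2, 2))
  expect_equal(aopc(flat, reference = 2, mode = "deletion"), 0)
  # insertion drop is measured against the blurred reference
  expect_equal(aopc(curve, reference = 0.5, mode = "insertion"), 2.0)
})

test_that("AOPC bootstrap gives seeded percentile intervals covering the mean", {
  expect_error(bootstrap_aopc(1), class = "coopAS_invalid_input")
  deg <- bootstrap_aopc(rep(1.8, 10), n = 200, seed = 1)
  expect_equal(deg$ci_low, 1.8)
  expect_equal(deg$ci_high, 1.8)
  withr::with_seed(5, vals <- rnorm(100))
  b1 <- bootstrap_aopc(vals, n = 1000, seed = 3)
  b2 <- bootstrap_aopc(vals, n = 1000, seed = 3)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, mean(vals))
  expect_gte(b1$ci_high, mean(vals))
})

test_that("oracle saliency separates from area-matched random on planted signal", {
  # toy model scoring the mean intensity inside a known region
  region <- matrix(FALSE, 32, 32); region[10:20, 10:20] <- TRUE
  score_fn <- function(im) mean(im[region])
  oracle <- matrix(0, 32, 32); oracle[region] <- 1
  proto <- perturbation_protocol("deletion")
  res <- withr::with_seed(6, vapply(seq_len(40), function(i) {
    # bright planted region on a dark background: blurring removes signal
    img <- matrix(runif(32 * 32, 0, 0.3), 32, 32)
    img[region] <- runif(sum(region), 0.7, 1)
    rand <- baseline_saliency("random", c(32, 32))
    c(oracle = aopc(perturbation_curve(score_fn, img, oracle, proto)),
      random = aopc(perturbation_curve(score_fn, img, rand, proto)))
  }, numeric(2)))
  # deleting the known region always hurts more than chance deletion
  expect_gt(mean(res["oracle", ]), mean(res["random", ]))
  expect_true(all(res["oracle", ] > res["random", ]))
})
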