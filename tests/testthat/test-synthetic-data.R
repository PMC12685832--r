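test_that("AS labelling reproduces OR logic over all threshold-side combinations", {
  # one value below and one at-or-beyond each criterion's threshold
  pv <- c(below = 2.0, beyond = 3.0)
  mg <- c(below = 10, beyond = 25)
  av <- c(below = 2.0, beyond = 1.0)  # 'beyond' means area <= 1.5
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    echo <- echo_measurements(pv[i], mg[j], av[k])
    expect_identical(label_as(echo),
                     (i == 2) || (j == 2) || (k == 2),
                     info = sprintf("combo %d%d%d", i, j, k))
  }
})

test_that("AS thresholds are inclusive and match reported cohort values", {
  # means of the AS / non-AS columns of the source cohort's echo measures
  expect_true(label_as(echo_measurements(3.72, 35.6, 0.94)))
  expect_false(label_as(echo_measurements(2.02, 12.8, 1.8)))
  # inclusive boundaries, each criterion alone
  expect_true(label_as(echo_measurements(2.5, 19, 1.6)))
  expect_true(label_as(echo_measurements(2.0, 20, 1.6)))
  expect_true(label_as(echo_measurements(2.0, 19, 1.5)))
  expect_false(label_as(echo_measurements(2.499, 19.99, 1.501)))
})

test_that("missing echo fields are skipped; all-missing is a labelling error", {
  expect_true(label_as(echo_measurements(valve_area = 1.2)))
  expect_false(label_as(echo_measurements(peak_velocity = 2.0)))
  expect_error(label_as(echo_measurements()), class = "coopAS_label_error")
  expect_error(echo_measurements(peak_velocity = -1),
               class = "coopAS_invalid_input")
})

test_that("echo generator is calibrated and monotone in severity", {
  lo <- synth_echo(0, noise = 0, seed = 1)
  hi <- synth_echo(1, noise = 0, seed = 1)
  expect_false(label_as(lo))
  expect_true(label_as(hi))
  expect_error(synth_echo(1.2), class = "coopAS_invalid_input")
  draws <- function(sev) {
    withr::with_seed(99, replicate(1000, {
      e <- synth_echo(sev)
      c(e$peak_velocity, e$mean_gradient, e$valve_area)
    }))
  }
  m2 <- rowMeans(draws(0.2)); m8 <- rowMeans(draws(0.8))
  expect_gt(m8[1], m2[1])   # peak velocity rises
  expect_gt(m8[2], m2[2])   # gradient rises
  expect_lt(m8[3], m2[3])   # valve area falls
})

test_that("ECG simulator has the declared shape, bounds, determinism and strain analogue", {
  w <- synth_ecg(0.5, seed = 3)
  expect_equal(dim(w), c(12L, 7500L))
  expect_identical(rownames(w), ecg_lead_names())
  expect_true(all(abs(w) <= 5))
  expect_identical(w, synth_ecg(0.5, seed = 3))
  # severity scales QRS amplitude in the lateral leads (noise off)
  w0 <- synth_ecg(0, noise_sd = 0, heart_rate = 70, seed = 5)
  w1 <- synth_ecg(1, noise_sd = 0, heart_rate = 70, seed = 5)
  lat <- c("I", "aVL", "V5", "V6")
  for (l in lat) expect_gt(max(abs(w1[l, ])), max(abs(w0[l, ])))
  other <- setdiff(ecg_lead_names(), lat)
  expect_equal(w1[other, ], w0[other, ], tolerance = 1e-12)
})

test_that("image simulator plants a severity-dependent ellipse with a valid mask", {
  im0 <- synth_image(0, noise_sd = 0, seed = 2)
  expect_true(all(im0$image >= 0 & im0$image <= 255))
  expect_true(is.logical(im0$mask) && any(im0$mask))
  expect_identical(im0$image, synth_image(0, noise_sd = 0, seed = 2)$image)
  # mean planted-signal area grows with severity (ellipse width + blob)
  area <- function(sev) {
    withr::with_seed(7, mean(replicate(200, sum(synth_image(sev)$mask))))
  }
  expect_gt(area(1), area(0))
  expect_error(synth_image(0.5, image_size = 16),
               class = "coopAS_invalid_input")
})

test_that("record linkage applies the closest-study rule and both windows", {
  ev <- data.frame(
    patient_id = "A",
    modality = c("echo", "cxr", "cxr", "ecg"),
    day = c(0L, -10L, 5L, 4L))
  tr <- link_records(ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$cxr_day, 5L)   # |5| < |-10|
  expect_equal(tr$ecg_day, 4L)

  # CXR outside the 90-day window
  ev2 <- data.frame(patient_id = "A", modality = c("echo", "cxr", "ecg"),
                    day = c(0L, 100L, 0L))
  expect_equal(nrow(link_records(ev2)), 0L)
  expect_equal(attr(link_records(ev2), "n_unmatched"), 1L)

  # boundary day 90 is inclusive; ECG at +8 days from the CXR is excluded
  ev3 <- data.frame(patient_id = "A", modality = c("echo", "cxr", "ecg"),
                    day = c(0L, 90L, 98L))
  expect_equal(nrow(link_records(ev3)), 0L)
  ev3$day[3] <- 97L
  expect_equal(nrow(link_records(ev3)), 1L)

  # equidistant CXRs resolve to the earlier study
  ev4 <- data.frame(patient_id = "A",
                    modality = c("echo", "cxr", "cxr", "ecg"),
                    day = c(0L, -5L, 5L, -4L))
  expect_equal(link_records(ev4)$cxr_day, -5L)
})

test_that("linkage is invariant to event order", {
  withr::with_seed(11, {
    ev <- data.frame(
      patient_id = sample(c("A", "B"), 40, replace = TRUE),
      modality = sample(c("echo", "cxr", "ecg"), 40, replace = TRUE),
      day = sample(-120:120, 40, replace = TRUE))
  })
  a <- link_records(ev)
  b <- link_records(ev[sample(nrow(ev)), ])
  key <- function(d) d[order(d$patient_id, d$echo_day), ]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("cohort generation hits the target prevalence and keeps patients coherent", {
  coh <- generate_cohort(cohort_config(n_patients = 200,
                                       records_per_patient = 1,
                                       image_size = 32, seed = 1))
  man <- cohort_manifest(coh)
  prev <- mean(man$label)
  tol <- 3 * sqrt(0.08 * 0.92 / 200)
  expect_lt(abs(prev - 0.08), tol)
  # same-patient records share severity and label
  coh2 <- tiny_cohort()
  man2 <- cohort_manifest(coh2)
  sev <- vapply(coh2, `[[`, numeric(1), "severity")
  for (p in unique(man2$patient_id)) {
    idx <- man2$patient_id == p
    expect_equal(length(unique(sev[idx])), 1L)
    expect_equal(length(unique(man2$label[idx])), 1L)
  }
  expect_true(all(vapply(coh2, function(r)
    identical(r$label, label_as(r$echo)), logical(1))))
})

test_that("cohort generation is reproducible and honors fixed record counts", {
  cc <- cohort_config(n_patients = 5, records_per_patient = 3,
                      image_size = 32, seed = 42)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_length(a, 15L)
  expect_identical(cohort_manifest(a), cohort_manifest(b))
  expect_identical(a[[7]]$ecg, b[[7]]$ecg)
  expect_identical(a[[7]]$image, b[[7]]$image)
})
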