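# Synthetic paired-cohort generator -----------------------------------------
#
# Emulates the structure of a hospital AS-screening cohort: patients with a
# latent disease severity that drives (i) echocardiographic measurements used
# to derive the binary aortic-stenosis label, (ii) a 12-lead ECG waveform, and
# (iii) a chest-radiograph-like grayscale image, with per-modality noise,
# multi-record patients and linkable study timestamps.

#' Canonical 12-lead names, in device-export order
#' @return Character vector of length 12.
#' @export
ecg_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# Leads in which severity expresses the hypertrophy/strain analogue.
lateral_leads <- function() c("I", "aVL", "V5", "V6")

#' Aortic-stenosis labelling rule
#'
#' Echocardiographic thresholds defining AS: peak aortic-valve velocity
#' >= 2.5 m/s, mean pressure gradient >= 20 mmHg, or aortic valve area
#' <= 1.5 cm^2. Any single criterion suffices.
#'
#' @param velocity_threshold Peak velocity threshold, m/s.
#' @param gradient_threshold Mean pressure gradient threshold, mmHg.
#' @param area_threshold Valve area threshold, cm^2.
#' @return An object of class `as_rule`.
#' @export
as_rule <- function(velocity_threshold = 2.5,
                    gradient_threshold = 20,
                    area_threshold = 1.5) {
  assert_that(velocity_threshold > 0 && gradient_threshold > 0 &&
                area_threshold > 0,
              "AS rule thresholds must be strictly positive")
  structure(list(velocity_threshold = velocity_threshold,
                 gradient_threshold = gradient_threshold,
                 area_threshold = area_threshold),
            class = "as_rule")
}

#' Echocardiographic measurements
#'
#' @param peak_velocity Peak aortic-valve velocity, m/s; `NA` if missing.
#' @param mean_gradient Mean pressure gradient, mmHg; `NA` if missing.
#' @param valve_area Aortic valve area, cm^2; `NA` if missing.
#' @return An object of class `echo_measurements`.
#' @export
echo_measurements <- function(peak_velocity = NA_real_,
                              mean_gradient = NA_real_,
                              valve_area = NA_real_) {
  chk <- function(x, name, upper = Inf) {
    if (!is.na(x)) {
      assert_that(is.finite(x) && x > 0 && x <= upper,
                  "echo measurement '", name, "' must be positive and finite",
                  if (is.finite(upper)) paste0(" and <= ", upper) else "")
    }
  }
  chk(peak_velocity, "peak_velocity")
  chk(mean_gradient, "mean_gradient")
  chk(valve_area, "valve_area", upper = 10)
  structure(list(peak_velocity = peak_velocity,
                 mean_gradient = mean_gradient,
                 valve_area = valve_area),
            class = "echo_measurements")
}

#' Apply the AS labelling rule to echo measurements
#'
#' Returns `TRUE` iff at least one present measurement meets its threshold
#' (velocity and gradient compared with `>=`, valve area with `<=`). Missing
#' measurements are skipped; if all three are missing the record cannot be
#' labelled and an error of class `coopAS_label_error` is raised.
#'
#' @param echo An [echo_measurements()] object (or plain list with the same
#'   fields).
#' @param rule An [as_rule()]; defaults to the standard thresholds.
#' @return Logical scalar.
#' @export
label_as <- function(echo, rule = as_rule()) {
  pv <- echo$peak_velocity
  mg <- echo$mean_gradient
  av <- echo$valve_area
  if (is.na(pv) && is.na(mg) && is.na(av)) {
    stop_coop("cannot label a record with all echo measurements missing",
              class = "coopAS_label_error")
  }
  hit <- c(if (!is.na(pv)) pv >= rule$velocity_threshold,
           if (!is.na(mg)) mg >= rule$gradient_threshold,
           if (!is.na(av)) av <= rule$area_threshold)
  any(hit)
}

#' Cohort generator configuration
#'
#' @param n_patients Number of patients.
#' @param records_per_patient Either a single integer (fixed count) or a
#'   length-2 integer vector `c(min, max)` for a discrete-uniform draw per
#'   patient. Default `c(1, 5)` (mean 3, matching multi-record hospital use).
#' @param target_prevalence Fraction of patients drawn as diseased, in (0,1).
#' @param severity_effect_ecg,severity_effect_image Unitless effect sizes
#'   scaling how strongly severity expresses in each modality; 0 removes the
#'   modality's severity signal entirely.
#' @param severity_jitter_ecg,severity_jitter_image SD of the per-record
#'   modality-specific component: each record expresses
#'   `clamp01(severity + N(0, jitter))` in that modality, so either modality
#'   alone sees the shared disease severity only through independent noise
#'   (the mechanism that makes the modalities complementary rather than
#'   redundant).
#' @param noise_sd_ecg Additive Gaussian noise on the waveform, mV.
#' @param noise_sd_image Additive Gaussian noise on the image, gray levels.
#' @param image_size Image side length in pixels (>= 32).
#' @param seed Integer seed for full reproducibility, or `NULL`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200,
                          records_per_patient = c(1L, 5L),
                          target_prevalence = 0.08,
                          severity_effect_ecg = 1,
                          severity_effect_image = 1,
                          severity_jitter_ecg = 0.3,
                          severity_jitter_image = 0.3,
                          noise_sd_ecg = 0.03,
                          noise_sd_image = 8,
                          image_size = 64L,
                          seed = NULL) {
  assert_that(is_count(n_patients), "n_patients must be a positive integer")
  assert_that(is_fraction(target_prevalence),
              "target_prevalence must lie in (0, 1)")
  assert_that(is.numeric(records_per_patient) &&
                length(records_per_patient) %in% c(1L, 2L) &&
                all(records_per_patient >= 1),
              "records_per_patient must be an integer or c(min, max)")
  assert_that(image_size >= 32, "image_size must be at least 32 pixels")
  assert_that(noise_sd_ecg >= 0 && noise_sd_image >= 0,
              "noise standard deviations must be nonnegative")
  structure(list(n_patients = as.integer(n_patients),
                 records_per_patient = as.integer(records_per_patient),
                 target_prevalence = target_prevalence,
                 severity_effect_ecg = severity_effect_ecg,
                 severity_effect_image = severity_effect_image,
                 severity_jitter_ecg = severity_jitter_ecg,
                 severity_jitter_image = severity_jitter_image,
                 noise_sd_ecg = noise_sd_ecg,
                 noise_sd_image = noise_sd_image,
                 image_size = as.integer(image_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

#' Draw echo measurements for a given disease severity
#'
#' Measurements are affine in severity with Gaussian noise, clipped to
#' physiologic ranges, and calibrated so that severity 0 lies below all AS
#' thresholds and severity 1 above (velocity/gradient) or below (area) them
#' in the noise-free limit.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param noise Multiplier on the per-measurement noise SDs (0 = noise-free).
#' @param seed Optional integer seed.
#' @return An [echo_measurements()] object.
#' @export
synth_echo <- function(severity, noise = 1, seed = NULL) {
  assert_that(is.numeric(severity) && length(severity) == 1L &&
                severity >= 0 && severity <= 1,
              "severity must lie in [0, 1]")
  with_seed(seed, {
    pv <- 1.0 + 3.0 * severity + stats::rnorm(1, 0, 0.15 * noise)
    mg <- 2.0 + 40 * severity + stats::rnorm(1, 0, 2.0 * noise)
    av <- 3.2 - 2.0 * severity + stats::rnorm(1, 0, 0.12 * noise)
    echo_measurements(
      peak_velocity = min(max(pv, 0.5), 7),
      mean_gradient = min(max(mg, 1), 120),
      valve_area    = min(max(av, 0.3), 5)
    )
  })
}

# Bump parameters of the quasi-periodic P-QRS-T template: centre offset from
# the R wave (s), Gaussian width (s), base amplitude (mV).
ecg_bumps <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    offset = c(-0.16, -0.03, 0.00, 0.035, 0.30),
    width  = c(0.025, 0.010, 0.015, 0.012, 0.060),
    amp    = c(0.15, -0.12, 1.00, -0.25, 0.35)
  )
}

# Per-lead projection multipliers (rough surface-ECG realism; aVR inverted).
ecg_lead_scale <- function() {
  c(I = 0.70, II = 1.00, III = 0.40, aVR = -0.90, aVL = 0.45, aVF = 0.75,
    V1 = 0.50, V2 = 0.90, V3 = 1.10, V4 = 1.20, V5 = 1.00, V6 = 0.80)
}

#' Simulate a 12-lead ECG waveform
#'
#' Each lead is a quasi-periodic sum of localized Gaussian bumps (P, Q, R, S,
#' T) at a heart rate drawn near 70 bpm. Severity scales the QRS amplitude in
#' the lateral leads (I, aVL, V5, V6) by `1 + effect * severity` and
#' continuously flips the T-wave polarity there (multiplier
#' `1 - 2 * severity`), an analogue of the hypertrophy-with-strain pattern.
#' Amplitudes are clipped to +/- 5 mV.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param duration_s Recording length in seconds (default 15).
#' @param fs Sampling rate, Hz (default 500).
#' @param effect Unitless severity effect size (0 removes the signal).
#' @param noise_sd Additive Gaussian noise SD, mV.
#' @param heart_rate Beats per minute; drawn from N(70, 5) when `NULL`.
#' @param seed Optional integer seed.
#' @return A 12 x (duration_s * fs) numeric matrix in mV, rows named by lead.
#' @export
synth_ecg <- function(severity, duration_s = 15, fs = 500, effect = 1,
                      noise_sd = 0.03, heart_rate = NULL, seed = NULL) {
  assert_that(is.numeric(severity) && length(severity) == 1L &&
                severity >= 0 && severity <= 1,
              "severity must lie in [0, 1]")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    hr <- if (is.null(heart_rate)) stats::rnorm(1, 70, 5) else heart_rate
    hr <- min(max(hr, 40), 140)
    period <- 60 / hr
    centres <- seq(0.4, duration_s, by = period)
    centres <- centres + stats::rnorm(length(centres), 0, 0.008)

    bumps <- ecg_bumps()
    leads <- ecg_lead_names()
    base <- ecg_lead_scale()
    lat <- leads %in% lateral_leads()

    # amplitude matrix: 12 leads x 5 bump types
    amp <- outer(base, bumps$amp)
    qrs <- bumps$wave %in% c("Q", "R", "S")
    amp[lat, qrs] <- amp[lat, qrs] * (1 + effect * severity)
    amp[lat, bumps$wave == "T"] <-
      amp[lat, bumps$wave == "T"] * (1 - 2 * effect * severity)

    # bump basis: (5 * n_beats) x n; lead waveform = linear combination
    nb <- length(centres)
    cen <- rep(centres, each = nrow(bumps)) + rep(bumps$offset, nb)
    wid <- rep(bumps$width, nb)
    g <- exp(-(outer(cen, t, "-"))^2 / (2 * wid^2))
    amp_full <- amp[, rep(seq_len(nrow(bumps)), nb), drop = FALSE]
    w <- amp_full %*% g
    if (noise_sd > 0) w <- w + matrix(stats::rnorm(length(w), 0, noise_sd),
                                      nrow(w), ncol(w))
    w <- pmin(pmax(w, -5), 5)
    rownames(w) <- leads
    w
  })
}

#' Simulate a chest-radiograph-like grayscale image
#'
#' Smooth background texture plus a central ellipse (cardiac silhouette)
#' whose width fraction grows with severity, and a bright blob (valve
#' calcification analogue) appearing with probability `0.9 * severity`.
#' Returns the 8-bit image and a binary ground-truth mask of the planted
#' signal (ellipse plus blob) for use as a localization oracle; real
#' radiographs carry no such mask.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param image_size Side length in pixels (>= 32).
#' @param effect Unitless severity effect size on the silhouette width.
#' @param noise_sd Additive Gaussian noise SD, gray levels.
#' @param seed Optional integer seed.
#' @return List with `image` (integer matrix in \[0, 255\]) and `mask`
#'   (logical matrix of the planted signal region).
#' @export
synth_image <- function(severity, image_size = 64L, effect = 1,
                        noise_sd = 8, seed = NULL) {
  assert_that(is.numeric(severity) && length(severity) == 1L &&
                severity >= 0 && severity <= 1,
              "severity must lie in [0, 1]")
  assert_that(image_size >= 32, "image_size must be at least 32 pixels")
  with_seed(seed, {
    s <- as.integer(image_size)
    xy <- expand.grid(x = seq_len(s), y = seq_len(s))

    # low-frequency background texture
    bg <- matrix(stats::rnorm(s * s), s, s)
    bg <- as_plain_matrix(EBImage::gblur(bg, sigma = s / 12))
    bg <- 45 + 12 * bg / max(stats::sd(bg), 1e-8)

    # cardiac silhouette: ellipse with severity-dependent width fraction
    cx <- s * 0.5
    cy <- s * 0.58
    a <- s * (0.18 + 0.12 * effect * severity) + stats::rnorm(1, 0, 0.01 * s)
    a <- max(a, s * 0.05)
    b <- s * 0.30
    inside <- ((xy$x - cx) / a)^2 + ((xy$y - cy) / b)^2 <= 1
    ellipse <- matrix(inside, s, s)

    # calcification analogue: bright blob, probability rising with severity
    blob <- matrix(FALSE, s, s)
    if (stats::runif(1) < 0.9 * severity) {
      bx <- cx + stats::rnorm(1, 0, 0.03 * s)
      by <- s * 0.42 + stats::rnorm(1, 0, 0.03 * s)
      r <- s * 0.05
      blob <- matrix((xy$x - bx)^2 + (xy$y - by)^2 <= r^2, s, s)
    }

    img <- bg + 70 * ellipse + 110 * blob
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(s * s, 0, noise_sd), s, s)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), s, s)
    list(image = img, mask = ellipse | blob)
  })
}

#' Link echo, CXR and ECG study events into analysis triples
#'
#' For each echocardiography event, the chest radiograph closest in time
#' within `cxr_window` days is selected (ties resolved toward the earlier
#' study), then the ECG closest to that radiograph within `ecg_window` days
#' (same tie rule). Echo events with no qualifying pair yield no triple and
#' are counted in the `n_unmatched` attribute.
#'
#' @param events Data frame with columns `patient_id`, `modality` (one of
#'   `"echo"`, `"cxr"`, `"ecg"`) and integer `day`.
#' @param cxr_window CXR-to-echo window in days (inclusive, default 90).
#' @param ecg_window ECG-to-CXR window in days (inclusive, default 7).
#' @param verbose Emit a message with the unmatched-echo count.
#' @return Data frame with columns `patient_id`, `echo_day`, `cxr_day`,
#'   `ecg_day`; attribute `n_unmatched` carries the dropped-echo count.
#' @export
link_records <- function(events, cxr_window = 90, ecg_window = 7,
                         verbose = FALSE) {
  assert_that(is.data.frame(events) &&
                all(c("patient_id", "modality", "day") %in% names(events)),
              "events must have columns patient_id, modality, day")
  bad <- setdiff(unique(events$modality), c("echo", "cxr", "ecg"))
  assert_that(length(bad) == 0,
              "unknown modality: ", paste(bad, collapse = ", "))
  assert_that(all(nzchar(as.character(events$patient_id))),
              "patient_id must be non-empty")

  pick_closest <- function(days, ref, window) {
    if (length(days) == 0) return(NA_integer_)
    d <- abs(days - ref)
    ok <- d <= window
    if (!any(ok)) return(NA_integer_)
    days <- days[ok]; d <- d[ok]
    # minimal distance; equidistant before/after -> earlier study
    cand <- days[d == min(d)]
    min(cand)
  }

  out <- list()
  n_unmatched <- 0L
  for (pid in unique(events$patient_id)) {
    ev <- events[events$patient_id == pid, , drop = FALSE]
    echo_days <- sort(ev$day[ev$modality == "echo"])
    cxr_days <- ev$day[ev$modality == "cxr"]
    ecg_days <- ev$day[ev$modality == "ecg"]
    for (ed in echo_days) {
      cd <- pick_closest(cxr_days, ed, cxr_window)
      if (is.na(cd)) { n_unmatched <- n_unmatched + 1L; next }
      gd <- pick_closest(ecg_days, cd, ecg_window)
      if (is.na(gd)) { n_unmatched <- n_unmatched + 1L; next }
      out[[length(out) + 1L]] <-
        data.frame(patient_id = pid, echo_day = ed, cxr_day = cd,
                   ecg_day = gd, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), echo_day = integer(),
               cxr_day = integer(), ecg_day = integer())
  rownames(res) <- NULL
  attr(res, "n_unmatched") <- n_unmatched
  if (verbose && n_unmatched > 0) {
    message(n_unmatched, " echo event(s) had no qualifying CXR/ECG pair")
  }
  res
}

#' Generate a synthetic paired cohort
#'
#' Draws one latent severity per patient (diseased patients, selected with
#' probability `target_prevalence`, from U(0.6, 1); others from U(0, 0.35)),
#' one set of echo measurements per patient (so all records of a patient
#' share a label), and per record an ECG waveform, an image with its planted
#' signal mask, and linkable study days.
#'
#' @param config A [cohort_config()].
#' @return An object of class `coop_cohort`: a list of paired records, each
#'   with fields `patient_id`, `record_id`, `ecg`, `image`, `signal_mask`,
#'   `echo`, `label`, `severity`, `echo_day`, `cxr_day`, `ecg_day`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"),
              "config must be a cohort_config()")
  with_seed(config$seed, {
    records <- list()
    rid <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", p)
      diseased <- stats::runif(1) < config$target_prevalence
      severity <- if (diseased) stats::runif(1, 0.6, 1) else
        stats::runif(1, 0, 0.35)
      echo <- synth_echo(severity)
      label <- label_as(echo)
      rpp <- config$records_per_patient
      n_rec <- if (length(rpp) == 1L) rpp else
        sample(seq(rpp[1], rpp[2]), 1L)
      for (r in seq_len(n_rec)) {
        rid <- rid + 1L
        clamp01 <- function(x) min(max(x, 0), 1)
        sev_ecg <- clamp01(severity +
                             stats::rnorm(1, 0, config$severity_jitter_ecg))
        sev_img <- clamp01(severity +
                             stats::rnorm(1, 0, config$severity_jitter_image))
        ecg <- synth_ecg(sev_ecg, effect = config$severity_effect_ecg,
                         noise_sd = config$noise_sd_ecg)
        im <- synth_image(sev_img, image_size = config$image_size,
                          effect = config$severity_effect_image,
                          noise_sd = config$noise_sd_image)
        echo_day <- sample(0:3000, 1L)
        cxr_day <- echo_day + sample(-60:60, 1L)
        ecg_day <- cxr_day + sample(-7:7, 1L)
        records[[rid]] <- list(
          patient_id = pid,
          record_id = sprintf("R%05d", rid),
          ecg = ecg,
          image = im$image,
          signal_mask = im$mask,
          echo = echo,
          label = label,
          severity = severity,
          severity_ecg = sev_ecg,
          severity_image = sev_img,
          echo_day = echo_day,
          cxr_day = cxr_day,
          ecg_day = ecg_day
        )
      }
    }
    structure(records, class = "coop_cohort")
  })
}

#' Cohort manifest table
#'
#' @param cohort A `coop_cohort`.
#' @return Data frame with one row per record: ids, study days, echo
#'   measurements and label.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, record_id = r$record_id,
               echo_day = r$echo_day, cxr_day = r$cxr_day,
               ecg_day = r$ecg_day,
               peak_velocity = r$echo$peak_velocity,
               mean_gradient = r$echo$mean_gradient,
               valve_area = r$echo$valve_area,
               label = r$label, stringsAsFactors = FALSE)
  }))
}

#' @export
print.coop_cohort <- function(x, ...) {
  man <- cohort_manifest(x)
  cat("Synthetic paired cohort: ", length(x), " records from ",
      length(unique(man$patient_id)), " patients; prevalence ",
      sprintf("%.1f%%", 100 * mean(man$label)), "\n", sep = "")
  invisible(x)
}
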