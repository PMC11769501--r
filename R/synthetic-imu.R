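# Synthetic multi-sensor IMU session generator.
#
# The generator emulates the design of a wrist-sensor variability study:
# a cohort of subjects walks on a treadmill at five speeds and then performs
# an unstructured non-walking activity, while several tri-axial accelerometers
# are worn simultaneously on both wrists, differing in orientation (rotation
# about the sensor Z axis), position (left vs right wrist) and device class
# (100 Hz vs 64 Hz hardware with different noise floors). All sensors on one
# wrist observe a single latent wrist-motion trajectory, defined in closed
# form so it can be sampled exactly at any rate. Units are g throughout, with
# gravity (0, 0, 1) in the sensor frame at rest.

#' Describe one virtual wearable sensor
#'
#' @param code Short identifier, e.g. `"BR1"`.
#' @param wrist `"left"` or `"right"`.
#' @param rotation_deg Mounting rotation about the sensor Z axis, degrees in
#'   `[0, 360)`.
#' @param rate_hz Sampling frequency in Hz.
#' @param noise_sd Standard deviation of the white sensor noise, in g.
#' @param device Device class: `"A"` (100 Hz-class hardware) or `"B"`
#'   (64 Hz-class hardware).
#' @param lowpass_hz Cut-off of the device's first-order analog front-end
#'   low-pass filter in Hz, or `NA` for an unfiltered front end.
#' @return A `sensor_spec` object.
#' @export
sensor_spec <- function(code, wrist = c("right", "left"), rotation_deg = 0,
                        rate_hz = 100, noise_sd = 0.02,
                        device = c("A", "B"), lowpass_hz = NA_real_) {
  wrist <- match.arg(wrist)
  device <- match.arg(device)
  if (rate_hz <= 0) stop_invalid("rate_hz must be positive, got %g", rate_hz)
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative, got %g", noise_sd)
  rotation_deg <- rotation_deg %% 360
  structure(
    list(code = code, wrist = wrist, rotation_deg = rotation_deg,
         rate_hz = rate_hz, noise_sd = noise_sd, device = device,
         lowpass_hz = lowpass_hz),
    class = "sensor_spec"
  )
}

#' The default five-sensor wrist layout
#'
#' Three 100 Hz class-A sensors (right wrist upright, right wrist rotated 45
#' degrees about Z, left wrist upright) and two 64 Hz class-B sensors (one per
#' wrist). Class-B hardware carries a 2x higher noise floor and a 3 Hz
#' first-order front-end low-pass, the minimal proxies for hardware
#' differences between device families.
#'
#' @param noise_sd_a Noise floor of class-A devices in g.
#' @return Named list of [sensor_spec()] objects (`BR1`, `BR2`, `BL`, `ER`,
#'   `EL`).
#' @export
harvar_sensors <- function(noise_sd_a = 0.02) {
  b_noise <- 2 * noise_sd_a
  list(
    BR1 = sensor_spec("BR1", "right", 0, 100, noise_sd_a, "A"),
    BR2 = sensor_spec("BR2", "right", 45, 100, noise_sd_a, "A"),
    BL  = sensor_spec("BL", "left", 0, 100, noise_sd_a, "A"),
    ER  = sensor_spec("ER", "right", 0, 64, b_noise, "B", lowpass_hz = 3),
    EL  = sensor_spec("EL", "left", 0, 64, b_noise, "B", lowpass_hz = 3)
  )
}

#' Draw a cohort of subject gait profiles
#'
#' Per-subject gait parameters are drawn once from fixed distributions:
#' base step frequency uniform on \[1.2, 2.4\] Hz, amplitude scale log-normal
#' (mu 0, sigma 0.25), harmonic weights Dirichlet(4, 2, 1), per-axis phase
#' offsets uniform on \[0, 2 pi).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sidebar_ids Integer ids of subjects who hold the treadmill sidebars
#'   while walking (their walking oscillation amplitude is reduced to 25%).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return List of `subject_profile` objects.
#' @export
make_cohort <- function(n_subjects, sidebar_ids = integer(), seed = 1L) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1) {
    stop_invalid("n_subjects must be a positive integer")
  }
  n_subjects <- as.integer(n_subjects)
  sidebar_ids <- as.integer(sidebar_ids)
  if (length(sidebar_ids) && (any(sidebar_ids < 1L) || any(sidebar_ids > n_subjects))) {
    stop_invalid("sidebar_ids must be a subset of 1..n_subjects")
  }
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      w <- stats::rgamma(3L, shape = c(4, 2, 1))
      w <- w / sum(w)
      structure(
        list(
          subject_id = i,
          step_freq_base = stats::runif(1L, 1.2, 2.4),
          amp_scale = stats::rlnorm(1L, 0, 0.25),
          harmonic_weights = w,
          phase_offsets = stats::runif(3L, 0, 2 * pi),
          holds_sidebar = i %in% sidebar_ids,
          seed = derive_seed(seed, "subject", i)
        ),
        class = "subject_profile"
      )
    })
  })
}

#' The default study cohort
#'
#' Sixteen subjects of whom three (ids 2, 4 and 9) hold the treadmill
#' sidebars.
#'
#' @param seed Integer seed.
#' @return List of `subject_profile` objects.
#' @export
harvar_cohort <- function(seed = 1L) {
  make_cohort(16L, sidebar_ids = c(2L, 4L, 9L), seed = seed)
}

# Per-axis base oscillation amplitudes (g) and fixed per-harmonic phase
# offsets shaping the walking waveform.
.axis_amp <- c(0.40, 0.37, 0.34)
.harmonic_phase <- c(0, 0.9, 1.7)
.sidebar_factor <- 0.25

# Systematic left-wrist kinematics, shared by all subjects: the swing-plane
# emphasis of the non-dominant arm differs per axis (broadband, so it
# survives any device front-end filtering), on top of the X-axis mirror and
# independent phases. Being systematic, it keeps the left-wrist population
# as internally homogeneous as the right one while shifting it away from the
# right in ways per-channel standardization cannot remove — same-wrist
# training stays easy, cross-wrist transfer is genuinely hard. The harmonic
# mix is shared between wrists (damp factors of 1) so that device-class
# filtering effects stay orthogonal to the position effect.
.left_harmonic_damp <- c(1, 1, 1)
.left_axis_factor <- c(0.5, 1.5, 0.7)

# Deterministic wrist-level latent-motion parameters for one subject.
.wrist_params <- function(profile, wrist) {
  if (wrist == "right") {
    list(phase = profile$phase_offsets, flip_x = FALSE,
         weights = profile$harmonic_weights,
         axis_amp = .axis_amp,
         burst_seed = derive_seed(profile$seed, "bursts-right"),
         mod_phase = profile$phase_offsets[1L])
  } else {
    ph <- with_seed(derive_seed(profile$seed, "left-phase"),
                    stats::runif(3L, 0, 2 * pi))
    w <- profile$harmonic_weights * .left_harmonic_damp
    list(phase = ph, flip_x = TRUE,
         weights = w / sum(w),
         axis_amp = .axis_amp * .left_axis_factor,
         burst_seed = derive_seed(profile$seed, "bursts-left"),
         mod_phase = ph[1L])
  }
}

# Non-walking latent: heterogeneous low-frequency bursts. Burst parameters are
# drawn once per (subject, wrist); the signal itself is a closed form in time.
.draw_bursts <- function(burst_seed, duration_s, amp_scale) {
  with_seed(burst_seed, {
    n <- stats::rpois(1L, lambda = max(1, duration_s / 60 * 8))
    n <- max(n, 1L)
    dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    list(
      center = stats::runif(n, 0, duration_s),
      width = stats::runif(n, 0.3, 1.5),
      freq = stats::runif(n, 0.3, 2.5),
      amp = stats::runif(n, 0.05, 0.5) * amp_scale,
      phase = stats::runif(n, 0, 2 * pi),
      dir = dir
    )
  })
}

# Evaluate the latent wrist acceleration (gravity included, g units) at times
# `t` (seconds from session start). Segment layout: walking blocks (one per
# speed) followed by one non-walking block.
.latent_eval <- function(t, profile, wp, walk_speeds_kmh, walk_s_per_speed,
                         nonwalk_s) {
  n <- length(t)
  out <- matrix(0, n, 3L)
  out[, 3L] <- 1  # gravity along sensor Z at rest
  amp <- profile$amp_scale * ifelse(profile$holds_sidebar, .sidebar_factor, 1)
  w <- wp$weights
  walk_total <- length(walk_speeds_kmh) * walk_s_per_speed

  for (i in seq_along(walk_speeds_kmh)) {
    t0 <- (i - 1) * walk_s_per_speed
    sel <- t >= t0 & t < t0 + walk_s_per_speed
    if (!any(sel)) next
    tau <- t[sel] - t0
    f <- profile$step_freq_base * (0.7 + 0.15 * walk_speeds_kmh[i] / 3.2)
    am <- 1 + 0.08 * sin(2 * pi * 0.25 * tau + wp$mod_phase)
    for (j in 1:3) {
      osc <- 0
      for (h in 1:3) {
        osc <- osc + w[h] * sin(2 * pi * h * f * tau + wp$phase[j] + .harmonic_phase[h])
      }
      out[sel, j] <- out[sel, j] + wp$axis_amp[j] * amp * am * osc
    }
  }

  sel <- t >= walk_total
  if (any(sel)) {
    tau <- t[sel] - walk_total
    bursts <- .draw_bursts(wp$burst_seed, nonwalk_s, profile$amp_scale)
    acc <- matrix(0, sum(sel), 3L)
    for (b in seq_along(bursts$center)) {
      env <- exp(-(tau - bursts$center[b])^2 / (2 * bursts$width[b]^2))
      osc <- bursts$amp[b] * env *
        sin(2 * pi * bursts$freq[b] * (tau - bursts$center[b]) + bursts$phase[b])
      acc <- acc + outer(osc, bursts$dir[b, ])
    }
    # slow postural wobble
    for (j in 1:3) {
      acc[, j] <- acc[, j] + 0.02 * sin(2 * pi * 0.05 * tau + wp$phase[j] + j)
    }
    out[sel, ] <- out[sel, ] + acc
  }
  if (wp$flip_x) out[, 1L] <- -out[, 1L]
  out
}

# First-order low-pass filter (discrete IIR) modelling a device front end.
.lowpass <- function(x, rate_hz, cutoff_hz) {
  if (is.na(cutoff_hz) || cutoff_hz <= 0) return(x)
  dt <- 1 / rate_hz
  rc <- 1 / (2 * pi * cutoff_hz)
  alpha <- dt / (rc + dt)
  for (j in seq_len(ncol(x))) {
    x[, j] <- stats::filter(alpha * x[, j], 1 - alpha, method = "recursive",
                            init = x[1L, j])
  }
  x
}

#' Rotate a tri-axial signal about the sensor Z axis
#'
#' @param samples N x 3 matrix of accelerations.
#' @param angle_deg Rotation angle in degrees (reduced modulo 360).
#' @return N x 3 rotated matrix; per-sample Euclidean norms are preserved.
#' @export
rotate_signal <- function(samples, angle_deg) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop_invalid("samples must have 3 columns")
  if (any(!is.finite(samples))) stop_invalid("samples must be finite")
  a <- (angle_deg %% 360) * pi / 180
  rot <- matrix(c(cos(a), -sin(a), 0,
                  sin(a), cos(a), 0,
                  0, 0, 1), 3L, 3L)
  samples %*% rot
}

#' Simulate one multi-sensor recording session
#'
#' All sensors observe the same latent wrist trajectories (one per wrist),
#' sampled at each sensor's own rate. The sensor mounting rotation is applied
#' as a Z-axis rotation, class-B devices pass the signal through their
#' front-end low-pass, and white noise with the sensor's `noise_sd` is added.
#' Walking samples are labelled 1, non-walking samples 0.
#'
#' @param profile A `subject_profile` from [make_cohort()].
#' @param sensors List of [sensor_spec()] objects.
#' @param walk_speeds_kmh Treadmill speeds; one walking block per speed.
#' @param walk_min_per_speed Minutes walked at each speed.
#' @param nonwalk_min Minutes of the non-walking activity.
#' @return Named list of `recording` objects, one per sensor, time aligned.
#' @export
simulate_session <- function(profile, sensors,
                             walk_speeds_kmh = c(3.2, 4, 4.8, 5.6, 6.4),
                             walk_min_per_speed = 2, nonwalk_min = 20) {
  if (length(sensors) == 0L) stop_invalid("sensors must be a non-empty list")
  if (any(walk_speeds_kmh <= 0)) stop_invalid("walk speeds must be positive")
  walk_s <- walk_min_per_speed * 60
  nonwalk_s <- nonwalk_min * 60
  total_s <- length(walk_speeds_kmh) * walk_s + nonwalk_s
  walk_total <- length(walk_speeds_kmh) * walk_s

  wps <- list(right = .wrist_params(profile, "right"),
              left = .wrist_params(profile, "left"))

  recs <- lapply(sensors, function(sp) {
    n <- round(total_s * sp$rate_hz)
    t <- (seq_len(n) - 1L) / sp$rate_hz
    x <- .latent_eval(t, profile, wps[[sp$wrist]], walk_speeds_kmh, walk_s,
                      nonwalk_s)
    x <- rotate_signal(x, sp$rotation_deg)
    x <- .lowpass(x, sp$rate_hz, sp$lowpass_hz)
    if (sp$noise_sd > 0) {
      nseed <- derive_seed(profile$seed, "noise", sp$code, sp$wrist,
                           round(sp$rotation_deg * 100), round(sp$rate_hz * 100),
                           round(sp$noise_sd * 1e6))
      x <- x + with_seed(nseed, matrix(stats::rnorm(n * 3L, sd = sp$noise_sd), n, 3L))
    }
    structure(
      list(sensor = sp, samples = x,
           labels = as.integer(t < walk_total),
           rate_hz = sp$rate_hz, subject_id = profile$subject_id,
           provenance = "synthetic"),
      class = "recording"
    )
  })
  if (is.null(names(recs))) {
    names(recs) <- vapply(sensors, function(s) s$code, "")
  }
  recs
}

#' Simulate sessions for a whole cohort
#'
#' @param profiles List of `subject_profile` objects.
#' @param sensors List of [sensor_spec()] objects.
#' @param ... Passed to [simulate_session()].
#' @return A `har_cohort`: list with `profiles`, `sensors` and `sessions`
#'   (one named recording list per subject).
#' @export
simulate_cohort <- function(profiles, sensors, ...) {
  sessions <- lapply(profiles, simulate_session, sensors = sensors, ...)
  names(sessions) <- vapply(profiles, function(p) as.character(p$subject_id), "")
  structure(list(profiles = profiles, sensors = sensors, sessions = sessions),
            class = "har_cohort")
}

#' Ratio of not-walking to walking samples
#'
#' @param x A `recording` or an integer label vector (0 = not walking,
#'   1 = walking).
#' @return `count(label == 0) / count(label == 1)`.
#' @export
label_ratio <- function(x) {
  labels <- if (inherits(x, "recording")) x$labels else as.integer(x)
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    stop_invalid("label_ratio needs both classes present (got %d not-walking, %d walking)",
                 n0, n1)
  }
  n0 / n1
}

#' Write a session to CSV files plus a JSON manifest
#'
#' One CSV per sensor with columns `t_s, ax_g, ay_g, az_g, label`, and a
#' `manifest.json` listing files, rates and sensor descriptions.
#'
#' @param session Named list of recordings from [simulate_session()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(names(session), function(code) {
    rec <- session[[code]]
    n <- nrow(rec$samples)
    df <- data.frame(
      t_s = (seq_len(n) - 1L) / rec$rate_hz,
      ax_g = rec$samples[, 1L], ay_g = rec$samples[, 2L],
      az_g = rec$samples[, 3L], label = rec$labels
    )
    file <- sprintf("subject%02d_%s.csv", rec$subject_id, code)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    c(list(file = file), rec$sensor[c("code", "wrist", "rotation_deg",
                                      "rate_hz", "noise_sd", "device")])
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a session written by [write_session_csv()]
#'
#' @param dir Directory containing the CSV files and `manifest.json`.
#' @return Named list of `recording` objects.
#' @export
read_session_csv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  recs <- lapply(manifest, function(e) {
    df <- utils::read.csv(file.path(dir, e$file))
    sp <- sensor_spec(e$code, e$wrist, as.numeric(e$rotation_deg),
                      as.numeric(e$rate_hz), as.numeric(e$noise_sd), e$device)
    sid <- as.integer(sub("subject0*([0-9]+)_.*", "\\1", e$file))
    structure(
      list(sensor = sp,
           samples = unname(as.matrix(df[, c("ax_g", "ay_g", "az_g")])),
           labels = as.integer(df$label), rate_hz = e$rate_hz,
           subject_id = sid, provenance = "synthetic"),
      class = "recording"
    )
  })
  names(recs) <- vapply(manifest, function(e) e$code, "")
  recs
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> sensor %s (%s wrist, %g Hz): %d samples, %.1f%% walking\n",
              x$sensor$code, x$sensor$wrist, x$rate_hz, nrow(x$samples),
              100 * mean(x$labels == 1L)))
  invisible(x)
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> %s: %s wrist, %g deg, %g Hz, noise %g g, device %s\n",
              x$code, x$wrist, x$rotation_deg, x$rate_hz, x$noise_sd, x$device))
  invisible(x)
}
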