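# Synthetic cohort simulator: labelled multi-sensor IMU recordings with the
# statistical structure the downstream analysis assumes (4-6 Hz tremor,
# bradykinetic amplitude/bandwidth attenuation, medication-state change across
# sessions, sensor-replacement perturbation between days).

# Baseline movement intensity (acc RMS, G) by task group; gyro baselines are
# scaled from these. Fine-motor tasks are low-amplitude, locomotion highest.
.group_amp <- c(functional = 0.25, clinical = 0.15, fine_motor = 0.08,
                gross_motor = 0.20)

.sides <- c("left", "right")
.locations <- c("hand", "forearm", "thigh")

#' Standard task battery
#'
#' The 13 motor tasks used in the assessments, tagged by task group:
#' functional activities, standard clinical manoeuvres, fine-motor tasks and
#' gross-motor tasks.
#'
#' @return A data frame with columns `task` and `group`.
#' @export
default_tasks <- function() {
  data.frame(
    task = c("walking", "walking_counting", "finger_to_nose",
             "alternating_hand_movements", "sit_to_stand", "sitting",
             "standing", "drawing", "typing", "nuts_and_bolts",
             "pouring_water", "organizing_folders", "folding_towels"),
    group = c("functional", "functional", "clinical", "clinical",
              "functional", "functional", "functional", "fine_motor",
              "fine_motor", "fine_motor", "gross_motor", "gross_motor",
              "gross_motor"),
    stringsAsFactors = FALSE
  )
}

# Moment-matched truncated normal on [0,1]: find underlying (mu, sigma) whose
# truncated mean equals the target exactly and truncated SD is as close as the
# family allows (a truncated normal on the unit interval cannot exceed a
# coefficient of variation of ~1, so very dispersed targets are matched in
# mean first).
match_truncnorm <- function(mean, sd) {
  if (sd <= 0) return(c(mu = mean, sigma = 0))
  tm <- function(mu, sigma) {
    a <- (0 - mu) / sigma
    b <- (1 - mu) / sigma
    z <- pnorm(b) - pnorm(a)
    if (z < 1e-12) return(c(NA_real_, NA_real_))
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                      ((dnorm(a) - dnorm(b)) / z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    ms <- tm(par[1], exp(par[2]))
    if (any(is.na(ms))) return(1e6)
    100 * (ms[1] - mean)^2 + (ms[2] - sd)^2
  }
  fit <- optim(c(mean, log(max(sd, 1e-3))), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc01 <- function(n, mu, sigma) {
  if (sigma <= 0) return(rep(min(max(mu, 0), 1), n))
  lo <- pnorm((0 - mu) / sigma)
  hi <- pnorm((1 - mu) / sigma)
  qnorm(runif(n, lo, hi)) * sigma + mu
}

#' Cohort simulation configuration
#'
#' Defines the study structure (subjects, tasks, sessions, sensor locations),
#' the symptom prevalence distributions, and the signal-level effect sizes
#' used by [simulate_cohort()].
#'
#' @param n_subjects number of subjects (>= 2).
#' @param tasks data frame with columns `task`, `group`
#'   (`functional`/`clinical`/`fine_motor`/`gross_motor`); default
#'   [default_tasks()].
#' @param n_sessions_day1 repeated assessments on day 1 (default 6; the first
#'   is in the OFF-medication state, later ones after medication).
#' @param include_day2 simulate a single follow-up session on a second day.
#' @param day2_subjects how many subjects return for day 2 (default
#'   `min(15, n_subjects)`).
#' @param sampling_rate sensor sampling rate in Hz (default 62.5).
#' @param duration_s duration of each task performance in seconds (>= 5).
#' @param locations sensor locations to simulate (subset of hand, forearm,
#'   thigh; each on both sides).
#' @param sides body sides to instrument.
#' @param bradykinesia_prev_mean,bradykinesia_prev_sd mean/SD across subjects
#'   of the fraction of task performances showing bradykinesia
#'   (defaults 0.485 / 0.217).
#' @param tremor_prev_mean,tremor_prev_sd same for tremor
#'   (defaults 0.22 / 0.244).
#' @param dyskinesia_prev_mean,dyskinesia_prev_sd same for dyskinesia
#'   (annotated only; no signal model; defaults 0.08 / 0.115).
#' @param tremor_amp tremor acceleration amplitude in G per severity point
#'   (default 0.1).
#' @param brady_atten multiplicative attenuation of baseline movement
#'   amplitude and bandwidth per bradykinesia severity point, in (0,1)
#'   (default 0.6).
#' @param med_multiplier severity multiplier for sessions in the ON-medication
#'   state (sessions after the first on day 1, and day 2), in (0,1].
#' @param day2_rotation_sd SD in degrees of the random sensor-frame rotation
#'   applied to day-2 recordings (sensor replacement effect).
#' @param mounting_rotation_sd SD in degrees of the per-subject sensor
#'   mounting rotation (between-subject orientation heterogeneity).
#' @param subject_amp_sd SD of the log-normal per-subject movement-amplitude
#'   multiplier.
#' @param tremor_locations sensor locations whose channels carry the tremor
#'   oscillation (default hand and forearm).
#' @param brady_locations locations whose baseline motion is attenuated by
#'   bradykinesia (default hand and forearm).
#' @param group_expression named multipliers on symptom signal expression per
#'   task group (default: gross-motor tasks express symptoms at half
#'   amplitude).
#' @param noise_sd additive white measurement noise SD on the accelerometer, G.
#' @param rng_seed master seed; identical seed + config give a bit-identical
#'   cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20,
                          tasks = default_tasks(),
                          n_sessions_day1 = 6,
                          include_day2 = TRUE,
                          day2_subjects = min(15, n_subjects),
                          sampling_rate = 62.5,
                          duration_s = 30,
                          locations = c("hand", "forearm", "thigh"),
                          sides = c("left", "right"),
                          bradykinesia_prev_mean = 0.485,
                          bradykinesia_prev_sd = 0.217,
                          tremor_prev_mean = 0.22,
                          tremor_prev_sd = 0.244,
                          dyskinesia_prev_mean = 0.08,
                          dyskinesia_prev_sd = 0.115,
                          tremor_amp = 0.1,
                          brady_atten = 0.6,
                          med_multiplier = 0.7,
                          day2_rotation_sd = 15,
                          mounting_rotation_sd = 20,
                          subject_amp_sd = 0.4,
                          tremor_locations = c("hand", "forearm"),
                          brady_locations = c("hand", "forearm"),
                          group_expression = c(functional = 1, clinical = 1,
                                               fine_motor = 1,
                                               gross_motor = 0.5),
                          noise_sd = 0.02,
                          rng_seed = 1L) {
  if (!is_count(n_subjects, min = 2)) {
    stop("`n_subjects` must be an integer >= 2", call. = FALSE)
  }
  if (!is.data.frame(tasks) || !all(c("task", "group") %in% names(tasks)) ||
      nrow(tasks) < 1) {
    stop("`tasks` must be a data frame with columns task, group", call. = FALSE)
  }
  if (!all(tasks$group %in% names(.group_amp))) {
    stop("task groups must be among: ",
         paste(names(.group_amp), collapse = ", "), call. = FALSE)
  }
  if (!is_count(n_sessions_day1, min = 1)) {
    stop("`n_sessions_day1` must be a positive integer", call. = FALSE)
  }
  if (!is_count(day2_subjects) || day2_subjects > n_subjects) {
    stop("`day2_subjects` must be an integer in [0, n_subjects]", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  if (duration_s < 5) stop("`duration_s` must be >= 5 (one clip)", call. = FALSE)
  if (!all(locations %in% .locations)) {
    stop("`locations` must be among hand, forearm, thigh", call. = FALSE)
  }
  if (!all(sides %in% .sides)) stop("`sides` must be left/right", call. = FALSE)
  prevs <- c(bradykinesia_prev_mean, bradykinesia_prev_sd, tremor_prev_mean,
             tremor_prev_sd, dyskinesia_prev_mean, dyskinesia_prev_sd)
  if (any(prevs < 0) || any(c(bradykinesia_prev_mean, tremor_prev_mean,
                              dyskinesia_prev_mean) > 1)) {
    stop("prevalence means must lie in [0,1] and SDs be non-negative",
         call. = FALSE)
  }
  if (brady_atten <= 0 || brady_atten >= 1) {
    stop("`brady_atten` must lie in (0,1)", call. = FALSE)
  }
  if (med_multiplier <= 0 || med_multiplier > 1) {
    stop("`med_multiplier` must lie in (0,1]", call. = FALSE)
  }
  if (tremor_amp < 0 || noise_sd < 0) {
    stop("`tremor_amp` and `noise_sd` must be non-negative", call. = FALSE)
  }
  if (!is_count(rng_seed) && !is_count(-rng_seed)) {
    stop("`rng_seed` must be an integer", call. = FALSE)
  }
  ge <- .group_amp * 0 + 1
  ge[names(group_expression)] <- group_expression
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    tasks = tasks[, c("task", "group")],
    n_sessions_day1 = as.integer(n_sessions_day1),
    include_day2 = isTRUE(include_day2),
    day2_subjects = as.integer(day2_subjects),
    sampling_rate = sampling_rate,
    duration_s = duration_s,
    locations = locations,
    sides = sides,
    prevalence = list(
      bradykinesia = c(mean = bradykinesia_prev_mean, sd = bradykinesia_prev_sd),
      tremor = c(mean = tremor_prev_mean, sd = tremor_prev_sd),
      dyskinesia = c(mean = dyskinesia_prev_mean, sd = dyskinesia_prev_sd)
    ),
    tremor_amp = tremor_amp,
    brady_atten = brady_atten,
    med_multiplier = med_multiplier,
    day2_rotation_sd = day2_rotation_sd,
    mounting_rotation_sd = mounting_rotation_sd,
    subject_amp_sd = subject_amp_sd,
    tremor_locations = tremor_locations,
    brady_locations = brady_locations,
    group_expression = ge,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  )
  cfg$propensity_dist <- lapply(cfg$prevalence, function(p) {
    match_truncnorm(p[["mean"]], p[["sd"]])
  })
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration:", x$n_subjects, "subjects,",
      nrow(x$tasks), "tasks,", x$n_sessions_day1, "day-1 sessions",
      if (x$include_day2) sprintf("+ day 2 (%d subjects)", x$day2_subjects)
      else "", "\n")
  cat("  locations:", paste(x$locations, collapse = ", "),
      "| sides:", paste(x$sides, collapse = ", "), "\n")
  cat(sprintf("  fs = %g Hz, %g s per task performance, seed %d\n",
              x$sampling_rate, x$duration_s, x$rng_seed))
  invisible(x)
}

#' Draw subject-level parameters
#'
#' Subject phenotype: dominant (more affected) side, resting-tremor frequency
#' uniform on 4-6 Hz, per-symptom propensity (the subject's probability that a
#' task performance shows the symptom) drawn from a moment-matched truncated
#' normal on the unit interval, a log-normal movement-amplitude multiplier,
#' and a medication responsiveness multiplier.
#'
#' @param config a [cohort_config()].
#' @param index subject index in `1:n_subjects`.
#' @return An object of class `subject_params`.
#' @export
draw_subject <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is_count(index, min = 1) || index > config$n_subjects) {
    stop("`index` must be in 1..n_subjects", call. = FALSE)
  }
  with_seed(derive_seed(config$rng_seed, 101L, index), {
    pd <- config$propensity_dist
    structure(list(
      subject_id = sprintf("S%03d", as.integer(index)),
      index = as.integer(index),
      dominant_side = sample(.sides, 1),
      tremor_freq = runif(1, 4, 6),
      propensity_bradykinesia = rtrunc01(1, pd$bradykinesia[["mu"]],
                                         pd$bradykinesia[["sigma"]]),
      propensity_tremor = rtrunc01(1, pd$tremor[["mu"]],
                                   pd$tremor[["sigma"]]),
      propensity_dyskinesia = rtrunc01(1, pd$dyskinesia[["mu"]],
                                       pd$dyskinesia[["sigma"]]),
      base_amp = exp(rnorm(1, 0, config$subject_amp_sd)),
      med_responsiveness = runif(1, 0.8, 1.2)
    ), class = "subject_params")
  })
}

# Band-limited Gaussian noise with target RMS; a short run-in is discarded so
# filter transients do not colour the clip.
band_noise <- function(n, fs, f_lo, f_hi, rms_target) {
  if (rms_target <= 0) return(numeric(n))
  f_hi <- min(f_hi, 0.95 * fs / 2)
  f_lo <- min(f_lo, f_hi * 0.8)
  bp <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  w <- rnorm(n + 200)
  y <- signal::filtfilt(bp, w)[101:(100 + n)]
  s <- rms(y)
  if (s < 1e-12) return(numeric(n))
  y * rms_target / s
}

# Tremor waveform: a harmonically-distorted oscillation (flexion faster than
# extension) with slow amplitude modulation, matching the bursty character of
# parkinsonian rest tremor.
tremor_wave <- function(t, freq) {
  phi <- runif(2, 0, 2 * pi)
  th <- 2 * pi * freq * t + phi[1]
  (sin(th) + 0.4 * sin(2 * th + pi / 8)) *
    (1 + 0.25 * sin(2 * pi * 0.9 * t + phi[2]))
}

#' Simulate one task performance for one sensor
#'
#' Generates a six-channel recording (tri-axial accelerometer in G, tri-axial
#' gyroscope in degrees/s) for a single subject, task, sensor location and
#' symptom-severity pair. Baseline voluntary movement is band-limited
#' (0.5-3 Hz) Gaussian motion scaled by task group and subject; gravity is a
#' constant 1 G on the accelerometer z axis. Tremor severity adds an
#' amplitude-modulated, harmonically-distorted oscillation at the subject's
#' tremor frequency on the configured locations; bradykinesia severity
#' multiplies baseline amplitude and bandwidth by `brady_atten^severity`.
#' White measurement noise is added and channels are clipped to the sensor
#' ranges (+-4 G, +-1000 deg/s).
#'
#' @param subject a [draw_subject()] result.
#' @param task task name.
#' @param task_group task group (one of functional, clinical, fine_motor,
#'   gross_motor).
#' @param severity named numeric `c(bradykinesia =, tremor =)`, scores 0-4.
#' @param duration_s recording duration in seconds (>= 5, one clip).
#' @param config a [cohort_config()].
#' @param location sensor location.
#' @param side body side the sensor is worn on.
#' @param day,session visit indices stored as metadata.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `sensor_recording`: metadata plus a
#'   `samples x 6` matrix with columns `accX, accY, accZ, gyroX, gyroY,
#'   gyroZ`.
#' @export
simulate_task_signal <- function(subject, task, task_group,
                                 severity = c(bradykinesia = 0, tremor = 0),
                                 duration_s, config, location = "hand",
                                 side = subject$dominant_side,
                                 day = 1L, session = 1L, seed = 1L) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(config, "cohort_config"))
  if (duration_s < 5) {
    stop("`duration_s` below the 5 s clip length is rejected", call. = FALSE)
  }
  sev_b <- severity[["bradykinesia"]]
  sev_t <- severity[["tremor"]]
  stopifnot(sev_b >= 0, sev_b <= 4, sev_t >= 0, sev_t <= 4)
  fs <- config$sampling_rate
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  expr <- unname(config$group_expression[task_group])
  amp0 <- .group_amp[[task_group]] * subject$base_amp
  af <- if (location %in% config$brady_locations) {
    config$brady_atten^(sev_b * expr)   # group expression damps the effect
  } else {
    1
  }
  f_hi <- max(0.8, 3 * af)

  with_seed(seed, {
    acc <- cbind(
      band_noise(n, fs, 0.5, f_hi, amp0 * af),
      band_noise(n, fs, 0.5, f_hi, amp0 * af * 0.8),
      band_noise(n, fs, 0.5, f_hi, amp0 * af * 0.6)
    )
    gyr <- cbind(
      band_noise(n, fs, 0.5, f_hi, amp0 * af * 120),
      band_noise(n, fs, 0.5, f_hi, amp0 * af * 100),
      band_noise(n, fs, 0.5, f_hi, amp0 * af * 70)
    )
    if (sev_t > 0 && location %in% config$tremor_locations) {
      a_t <- config$tremor_amp * sev_t * expr
      w <- tremor_wave(t, subject$tremor_freq)
      acc[, 1] <- acc[, 1] + 0.8 * a_t * w
      acc[, 2] <- acc[, 2] + 0.4 * a_t * w
      acc[, 3] <- acc[, 3] + 0.8 * a_t * w
      w2 <- tremor_wave(t, subject$tremor_freq)
      gyr[, 1] <- gyr[, 1] + 150 * a_t * w
      gyr[, 2] <- gyr[, 2] + 75 * a_t * w2
    }
    acc <- acc + matrix(rnorm(3 * n, 0, config$noise_sd), n, 3)
    gyr <- gyr + matrix(rnorm(3 * n, 0, 0.5), n, 3)
    acc[, 3] <- acc[, 3] + 1          # gravity on the sensor z axis
    acc <- pmin(pmax(acc, -4), 4)     # sensor range +-4 G
    gyr <- pmin(pmax(gyr, -1000), 1000)
    data <- cbind(acc, gyr)
    colnames(data) <- c("accX", "accY", "accZ", "gyroX", "gyroY", "gyroZ")
    structure(list(
      data = data,
      subject_id = subject$subject_id,
      side = side,
      location = location,
      day = as.integer(day),
      session = as.integer(session),
      task = task,
      task_group = task_group,
      sampling_rate = fs,
      start_time = 0
    ), class = "sensor_recording")
  })
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %s %s %s | day %d session %d | %s (%s) | %d samples @ %g Hz\n",
    x$subject_id, x$side, x$location, x$day, x$session, x$task, x$task_group,
    nrow(x$data), x$sampling_rate))
  invisible(x)
}

# Small random rotation of the sensor frame, composed from independent
# normal angles about the three axes.
random_rotation <- function(sd_deg) {
  a <- rnorm(3, 0, sd_deg) * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

rotate_recording <- function(rec, rot) {
  rec$data[, 1:3] <- rec$data[, 1:3] %*% t(rot)
  rec$data[, 4:6] <- rec$data[, 4:6] %*% t(rot)
  rec
}

# Clinician score for one task performance. Presence is Bernoulli in the
# subject's propensity; if present, a latent severity scaled by side dominance
# and medication state is quantized to 1..4. Medication reduces severity
# magnitude but the clinician still rates mild residual symptoms as present,
# so prevalence tracks the propensity.
draw_score <- function(propensity, side_factor, med) {
  if (runif(1) >= propensity) return(0L)
  as.integer(min(4, max(1, round(4 * runif(1, 0.5, 1) * side_factor * med))))
}

#' Simulate a labelled cohort
#'
#' Generates one recording per (subject x side x location x session x task)
#' and a clinician-score annotation table. Severities are drawn per task
#' performance from the subject's propensity, reduced by the medication
#' multiplier for sessions after the first; each subject/side/location sensor
#' carries a fixed random mounting rotation, and day-2 recordings get an
#' additional random rotation emulating sensor replacement between visits.
#'
#' @param config a [cohort_config()].
#' @param signals if `FALSE`, skip signal synthesis and return annotations
#'   only (fast path for label-level analyses).
#' @return An object of class `pd_cohort` with elements `config`, `subjects`
#'   (list of [draw_subject()] results), `recordings` (list of
#'   `sensor_recording`), and `annotations` (data frame with one row per
#'   subject/day/session/task/side and integer 0-4 scores for bradykinesia,
#'   tremor and dyskinesia).
#' @export
simulate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    draw_subject(config, i)
  })

  visits <- data.frame(day = 1L, session = seq_len(config$n_sessions_day1))
  tasks <- config$tasks
  ann <- list()
  k <- 0L
  for (si in seq_len(config$n_subjects)) {
    subj <- subjects[[si]]
    vis <- visits
    if (config$include_day2 && si <= config$day2_subjects) {
      vis <- rbind(vis, data.frame(day = 2L, session = 1L))
    }
    for (vi in seq_len(nrow(vis))) {
      day <- vis$day[vi]; session <- vis$session[vi]
      med <- if (day == 1 && session == 1) 1 else {
        min(1, config$med_multiplier * subj$med_responsiveness)
      }
      for (ti in seq_len(nrow(tasks))) {
        for (side in config$sides) {
          side_code <- match(side, .sides)
          sf <- if (side == subj$dominant_side) 1 else 0.75
          sc <- with_seed(
            derive_seed(config$rng_seed, 202L, si, day, session, ti, side_code),
            c(draw_score(subj$propensity_bradykinesia, sf, med),
              draw_score(subj$propensity_tremor, sf, med),
              draw_score(subj$propensity_dyskinesia, sf, med))
          )
          k <- k + 1L
          ann[[k]] <- data.frame(
            subject = subj$subject_id, day = day, session = session,
            task = tasks$task[ti], task_group = tasks$group[ti], side = side,
            bradykinesia = sc[1], tremor = sc[2], dyskinesia = sc[3],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  annotations <- do.call(rbind, ann)

  recordings <- list()
  if (signals) {
    # fixed per-sensor mounting rotations and day-2 replacement rotations
    rot_key <- function(si, side_code, loc_code, tag) {
      derive_seed(config$rng_seed, tag, si, side_code, loc_code)
    }
    r <- 0L
    recordings <- vector("list",
                         nrow(annotations) / length(config$sides) *
                           length(config$sides) * length(config$locations))
    for (i in seq_len(nrow(annotations))) {
      a <- annotations[i, ]
      si <- match(a$subject, vapply(subjects, `[[`, "", "subject_id"))
      subj <- subjects[[si]]
      side_code <- match(a$side, .sides)
      ti <- match(a$task, tasks$task)
      for (loc in config$locations) {
        loc_code <- match(loc, .locations)
        rec <- simulate_task_signal(
          subj, a$task, a$task_group,
          severity = c(bradykinesia = a$bradykinesia, tremor = a$tremor),
          duration_s = config$duration_s, config = config, location = loc,
          side = a$side, day = a$day, session = a$session,
          seed = derive_seed(config$rng_seed, 303L, si, a$day, a$session,
                             ti, side_code, loc_code)
        )
        rot <- with_seed(rot_key(si, side_code, loc_code, 404L),
                         random_rotation(config$mounting_rotation_sd))
        if (a$day == 2) {
          rot2 <- with_seed(rot_key(si, side_code, loc_code, 505L),
                            random_rotation(config$day2_rotation_sd))
          rot <- rot2 %*% rot
        }
        r <- r + 1L
        recordings[[r]] <- rotate_recording(rec, rot)
      }
    }
    recordings <- recordings[seq_len(r)]
  }

  structure(list(config = config, subjects = subjects,
                 recordings = recordings, annotations = annotations),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort> %d subjects, %d recordings, %d annotations\n",
              x$config$n_subjects, length(x$recordings), nrow(x$annotations)))
  for (sym in c("bradykinesia", "tremor")) {
    cat(sprintf("  %s prevalence (task performances with score > 0): %.3f\n",
                sym, mean(x$annotations[[sym]] > 0)))
  }
  invisible(x)
}

#' Orientation-independent movement intensity series
#'
#' Euclidean magnitude of the tri-axial accelerometer signal with the gravity
#' (DC) component removed by a zero-phase high-pass on the magnitude itself.
#' Unlike per-axis high-passing, this preserves the fundamental of an
#' oscillation superposed on gravity, so a tremor clip shows its spectral
#' peak at the tremor frequency.
#'
#' @param x a `sensor_recording` or a numeric matrix whose first three
#'   columns are the accelerometer axes.
#' @param fs sampling rate in Hz (taken from the recording if available).
#' @param hp_cutoff high-pass cutoff in Hz (default 0.5).
#' @return Numeric vector: the gravity-free acceleration magnitude in G.
#' @export
gravity_free_magnitude <- function(x, fs = 62.5, hp_cutoff = 0.5) {
  if (inherits(x, "sensor_recording")) {
    fs <- x$sampling_rate
    x <- x$data
  }
  mag <- sqrt(rowSums(x[, 1:3, drop = FALSE]^2))
  hp <- signal::butter(4, hp_cutoff / (fs / 2), type = "high")
  zero_phase(mag, hp)
}

#' Write a cohort to plain-text files
#'
#' One CSV per recording (`t, accX, accY, accZ, gyroX, gyroY, gyroZ`), an
#' index CSV of recording metadata, the annotations CSV, and a JSON echo of
#' the configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    file <- sprintf("%s_d%d_s%02d_%s_%s_%s.csv", rec$subject_id, rec$day,
                    rec$session, rec$task, rec$side, rec$location)
    n <- nrow(rec$data)
    df <- data.frame(t = (seq_len(n) - 1) / rec$sampling_rate)
    df <- cbind(df, as.data.frame(rec$data))
    write.csv(df, file.path(dir, file), row.names = FALSE)
    data.frame(file = file, subject = rec$subject_id, side = rec$side,
               location = rec$location, day = rec$day, session = rec$session,
               task = rec$task, task_group = rec$task_group,
               sampling_rate = rec$sampling_rate, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, idx), file.path(dir, "recordings.csv"),
            row.names = FALSE)
  write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
            row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `recordings.csv`, `annotations.csv` and
#'   the per-recording CSVs.
#' @return A `pd_cohort` (without subject parameter objects; config is the
#'   JSON echo as a plain list).
#' @export
read_cohort <- function(dir) {
  idx <- read.csv(file.path(dir, "recordings.csv"), stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(idx)), function(i) {
    m <- idx[i, ]
    df <- read.csv(file.path(dir, m$file))
    data <- as.matrix(df[, c("accX", "accY", "accZ",
                             "gyroX", "gyroY", "gyroZ")])
    structure(list(data = data, subject_id = m$subject, side = m$side,
                   location = m$location, day = m$day, session = m$session,
                   task = m$task, task_group = m$task_group,
                   sampling_rate = m$sampling_rate, start_time = df$t[1]),
              class = "sensor_recording")
  })
  annotations <- read.csv(file.path(dir, "annotations.csv"),
                          stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path) else NULL
  structure(list(config = config, subjects = NULL, recordings = recordings,
                 annotations = annotations), class = "pd_cohort")
}
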