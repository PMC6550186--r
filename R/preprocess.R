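# Preprocessing: segmentation into 5-second clips with 50% overlap,
# symptom-specific zero-phase Butterworth filtering, score binarization, and
# assembly of labelled multi-sensor clip sets.

#' Segment a recording into fixed-length overlapping windows
#'
#' Windows are `floor(clip_seconds * fs)` samples long and start every
#' `L * (1 - overlap)` samples; a trailing partial window is discarded, so a
#' recording of `N` samples yields `floor((N - L) / S) + 1` windows.
#'
#' @param recording a `sensor_recording`, or a numeric matrix (then `fs` must
#'   be supplied).
#' @param clip_seconds window length in seconds (default 5).
#' @param overlap fractional overlap between consecutive windows (default 0.5).
#' @param fs sampling rate in Hz when `recording` is a bare matrix.
#' @return A list of sample matrices, each with attribute `start_sample`.
#'   A recording shorter than one window gives an empty list with a warning.
#' @export
segment_clips <- function(recording, clip_seconds = 5, overlap = 0.5,
                          fs = 62.5) {
  if (inherits(recording, "sensor_recording")) {
    fs <- recording$sampling_rate
    x <- recording$data
  } else {
    x <- as.matrix(recording)
  }
  stopifnot(clip_seconds > 0, overlap >= 0, overlap < 1)
  len <- floor(clip_seconds * fs)
  step <- max(1L, floor(len * (1 - overlap)))
  n <- nrow(x)
  if (n < len) {
    warning(sprintf("recording (%d samples) shorter than one %d-sample clip; no windows",
                    n, len), call. = FALSE)
    return(list())
  }
  starts <- seq.int(1L, n - len + 1L, by = step)
  lapply(starts, function(s) {
    w <- x[s:(s + len - 1L), , drop = FALSE]
    attr(w, "start_sample") <- s
    w
  })
}

#' Symptom-specific zero-phase filtering of one clip
#'
#' Accelerometer channels are high-passed at 0.5 Hz (removing the gravity /
#' limb-orientation component); for bradykinesia detection all six channels
#' are additionally low-passed at 3 Hz. Filters are 4th-order Butterworth
#' applied forward-backward (zero phase), with reflection padding to suppress
#' edge transients on short clips.
#'
#' @param clip numeric matrix, one column per channel; accelerometer columns
#'   are identified by names starting with `acc` (fallback: the first three
#'   of every block of six columns).
#' @param symptom `"tremor"` (high-pass only) or `"bradykinesia"` (high-pass
#'   plus 3 Hz low-pass on all channels).
#' @param fs sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @param hp_cutoff,lp_cutoff cutoff frequencies in Hz; must be below the
#'   Nyquist frequency.
#' @return The filtered clip matrix.
#' @export
filter_clip <- function(clip, symptom = c("tremor", "bradykinesia"),
                        fs = 62.5, order = 4, hp_cutoff = 0.5,
                        lp_cutoff = 3) {
  symptom <- match.arg(symptom)
  clip <- as.matrix(clip)
  if (hp_cutoff >= fs / 2 || lp_cutoff >= fs / 2) {
    stop("filter cutoff at or above the Nyquist frequency", call. = FALSE)
  }
  nm <- colnames(clip)
  acc_cols <- if (!is.null(nm) && any(grepl("acc", nm))) {
    grepl("acc", nm)
  } else {
    ((seq_len(ncol(clip)) - 1L) %% 6L) < 3L
  }
  hp <- signal::butter(order, hp_cutoff / (fs / 2), type = "high")
  for (j in which(acc_cols)) clip[, j] <- zero_phase(clip[, j], hp)
  if (symptom == "bradykinesia") {
    lp <- signal::butter(order, lp_cutoff / (fs / 2), type = "low")
    for (j in seq_len(ncol(clip))) {
      clip[, j] <- zero_phase(clip[, j], lp, keep_mean = TRUE)
    }
  }
  clip
}

#' Binarize a clinician score
#'
#' Scores above 0 mean the symptom is present.
#'
#' @param score integer vector with values in 0..4.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_score <- function(score) {
  if (any(!is.finite(score)) || any(score != round(score)) ||
      any(score < 0) || any(score > 4)) {
    stop("scores must be integers in [0, 4]", call. = FALSE)
  }
  as.integer(score > 0)
}

# Sensor blocks making up each named sensor set. Side is resolved per subject:
# "dominant" is the side with dominant symptoms.
sensor_set_blocks <- function(sensor_set) {
  switch(sensor_set,
    hand = data.frame(location = "hand", rel_side = "dominant",
                      label = "hand", stringsAsFactors = FALSE),
    hand_bi = data.frame(location = c("hand", "hand"),
                         rel_side = c("dominant", "nondominant"),
                         label = c("hand", "hand_contra"),
                         stringsAsFactors = FALSE),
    combo = data.frame(location = c("hand", "forearm", "thigh"),
                       rel_side = "dominant",
                       label = c("hand", "forearm", "thigh"),
                       stringsAsFactors = FALSE),
    stop("unknown sensor set: ", sensor_set, call. = FALSE)
  )
}

#' Assemble a labelled clip set from a cohort
#'
#' Segments every relevant recording into clips, joins clips from the
#' selected sensors of the same task performance (sample-aligned), and
#' attaches the clinician scores of the evaluation side (the side with
#' dominant symptoms). Recordings without a matching annotation are excluded
#' with a warning.
#'
#' @param cohort a [simulate_cohort()] result (recordings present).
#' @param sensor_set `"hand"` (dominant-side hand sensor), `"hand_bi"` (both
#'   hands) or `"combo"` (hand + forearm + thigh, dominant side).
#' @param clip_seconds,overlap segmentation parameters, see [segment_clips()].
#' @return An object of class `clip_set`: list of clip matrices (channels of
#'   all selected sensors side by side, names prefixed by sensor label),
#'   a `meta` data frame (subject, evaluation side, day, session, task,
#'   task group, raw scores and binary labels per symptom, clip index), the
#'   sampling rate and the sensor block labels. `filtered` records which
#'   symptom-specific filter has been applied (`NA` until
#'   [filter_clips()] is called).
#' @export
assemble_dataset <- function(cohort, sensor_set = "hand", clip_seconds = 5,
                             overlap = 0.5) {
  stopifnot(inherits(cohort, "pd_cohort"))
  if (length(cohort$recordings) == 0) {
    stop("cohort has no recordings (simulated with signals = FALSE?)",
         call. = FALSE)
  }
  blocks <- sensor_set_blocks(sensor_set)
  fs <- cohort$recordings[[1]]$sampling_rate

  rec_key <- vapply(cohort$recordings, function(r) {
    paste(r$subject_id, r$day, r$session, r$task, r$side, r$location,
          sep = "|")
  }, "")
  ann <- cohort$annotations
  ann_key <- paste(ann$subject, ann$day, ann$session, ann$task, ann$side,
                   sep = "|")

  dominant <- vapply(cohort$subjects, `[[`, "", "dominant_side")
  names(dominant) <- vapply(cohort$subjects, `[[`, "", "subject_id")

  perf <- unique(data.frame(subject = vapply(cohort$recordings, `[[`, "", "subject_id"),
                            day = vapply(cohort$recordings, `[[`, 1L, "day"),
                            session = vapply(cohort$recordings, `[[`, 1L, "session"),
                            task = vapply(cohort$recordings, `[[`, "", "task"),
                            task_group = vapply(cohort$recordings, `[[`, "", "task_group"),
                            stringsAsFactors = FALSE))

  clips <- list()
  meta <- list()
  n_missing_ann <- 0L
  k <- 0L
  other <- c(left = "right", right = "left")
  for (i in seq_len(nrow(perf))) {
    p <- perf[i, ]
    dom <- dominant[[p$subject]]
    sides <- ifelse(blocks$rel_side == "dominant", dom, other[[dom]])
    ridx <- match(paste(p$subject, p$day, p$session, p$task, sides,
                        blocks$location, sep = "|"), rec_key)
    if (any(is.na(ridx))) next  # sensor location not simulated
    ai <- match(paste(p$subject, p$day, p$session, p$task, dom, sep = "|"),
                ann_key)
    if (is.na(ai)) {
      n_missing_ann <- n_missing_ann + 1L
      next
    }
    wins <- lapply(ridx, function(j) {
      segment_clips(cohort$recordings[[j]], clip_seconds, overlap, fs)
    })
    n_win <- min(vapply(wins, length, 0L))
    if (n_win == 0L) next
    a <- ann[ai, ]
    for (w in seq_len(n_win)) {
      joined <- do.call(cbind, lapply(seq_along(wins), function(b) {
        m <- wins[[b]][[w]]
        colnames(m) <- paste(blocks$label[b], colnames(m), sep = "_")
        m
      }))
      k <- k + 1L
      clips[[k]] <- joined
      meta[[k]] <- data.frame(
        subject = p$subject, side = dom, day = p$day, session = p$session,
        task = p$task, task_group = p$task_group,
        score_bradykinesia = a$bradykinesia, score_tremor = a$tremor,
        label_bradykinesia = binarize_score(a$bradykinesia),
        label_tremor = binarize_score(a$tremor),
        clip_index = w, stringsAsFactors = FALSE
      )
    }
  }
  if (n_missing_ann > 0L) {
    warning(sprintf("%d task performance(s) without a matching annotation excluded",
                    n_missing_ann), call. = FALSE)
  }
  if (k == 0L) {
    stop("no labelled clips could be assembled for sensor set '", sensor_set,
         "'", call. = FALSE)
  }
  structure(list(clips = clips, meta = do.call(rbind, meta), fs = fs,
                 sensor_set = sensor_set, blocks = blocks$label,
                 clip_seconds = clip_seconds, filtered = NA_character_),
            class = "clip_set")
}

#' Apply symptom-specific filtering to every clip in a set
#'
#' @param clip_set an [assemble_dataset()] result.
#' @param symptom `"tremor"` or `"bradykinesia"`; see [filter_clip()].
#' @param ... passed to [filter_clip()].
#' @return The clip set with filtered clips and `filtered` set.
#' @export
filter_clips <- function(clip_set, symptom, ...) {
  stopifnot(inherits(clip_set, "clip_set"))
  clip_set$clips <- lapply(clip_set$clips, filter_clip, symptom = symptom,
                           fs = clip_set$fs, ...)
  clip_set$filtered <- symptom
  clip_set
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("<clip_set> %d clips of %d channels (%s), %d subjects, filtered: %s\n",
              length(x$clips), ncol(x$clips[[1]]), x$sensor_set,
              length(unique(x$meta$subject)),
              if (is.na(x$filtered)) "no" else x$filtered))
  invisible(x)
}

#' Stack a clip set into a numeric array
#'
#' @param clip_set a `clip_set`.
#' @return Array of dimension `clips x samples x channels`, the input format
#'   of [pd_cnn()].
#' @export
clips_to_array <- function(clip_set) {
  stopifnot(inherits(clip_set, "clip_set"))
  n <- length(clip_set$clips)
  d <- dim(clip_set$clips[[1]])
  a <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n)) a[i, , ] <- clip_set$clips[[i]]
  dimnames(a) <- list(NULL, NULL, colnames(clip_set$clips[[1]]))
  a
}
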