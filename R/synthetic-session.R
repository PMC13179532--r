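#' Stimulus inventory for a lateralised sound-presentation session
#'
#' Five audiometric stimuli are used per session: warble tones (500 ms,
#' 5 Hz modulation, 5% depth) at 0.5, 1 and 2 kHz carrier frequency, and
#' the single-syllable utterances "ba" and "da". Each is presented twice
#' per participant, in randomised order, from the left or right speaker.
#'
#' @return Character vector of the five stimulus codes.
#' @export
stimulus_types <- function() {
  c("warble500", "warble1000", "warble2000", "ba", "da")
}

#' Response-model parameters for the synthetic-session generator
#'
#' Bundles the kinematic and statistical parameters of the simulated
#' behavioural response. Group defaults emulate the sound-booth protocol
#' the pipeline targets: a baseline absolute head yaw of about 10 degrees
#' off-centre, a group-mean peak of the absolute-yaw timecourse of
#' 0.30 rad (17 degrees) for toddlers and 0.21 rad (12 degrees) for
#' infants at 2--3 s after stimulus onset, a minority of responder
#' trials, gaze strongly correlated with head yaw, and occasional missing
#' frames at the 2-s extraction point.
#'
#' `peak_yaw_rad` is defined at the group level: it is the value the
#' across-trials mean of absolute yaw reaches at the peak of the
#' timecourse. Responder trials orient toward an internally derived
#' target angle `(peak_yaw_rad - (1 - p) * baseline_yaw_rad) / p` (with
#' `p = responder_prob`) so that mixing responders with non-responders
#' reproduces that group mean for any responder rate; with
#' `responder_prob = 1` the target equals `peak_yaw_rad` itself.
#'
#' @param group `"toddler"` or `"infant"`; selects the default set.
#' @param responder_prob Probability that a trial produces an overt
#'   response (default 0.25, in line with reported unreinforced head-turn
#'   rates in this age range).
#' @param correct_side_prob Probability that a response is directed
#'   toward the presentation side (default 0.80 toddler, 0.65 infant).
#' @param peak_yaw_rad Group-mean peak absolute yaw, radians.
#' @param latency_peak_s Time of the response peak after onset, seconds.
#' @param baseline_yaw_rad Mean absolute resting off-centre yaw, radians
#'   (default 10 degrees).
#' @param gaze_head_corr Correlation of horizontal gaze angle with yaw,
#'   in \[0, 1\].
#' @param noise_sd Per-feature Gaussian noise SD (radians for angles).
#' @param missing_frame_prob Probability that the frame nearest
#'   onset + 2 s is absent from the recording.
#' @param frame_rate_hz Video frame rate.
#' @param au_reaction If `TRUE`, responder trials also carry a
#'   stimulus-locked activation bump on a few facial action units.
#' @return An object of class `response_model_params` (a validated list).
#' @examples
#' p <- response_model_params("toddler")
#' p$peak_yaw_rad # 0.30
#' @export
response_model_params <- function(group = c("toddler", "infant"),
                                  responder_prob = 0.25,
                                  correct_side_prob = NULL,
                                  peak_yaw_rad = NULL,
                                  latency_peak_s = NULL,
                                  baseline_yaw_rad = 10 * pi / 180,
                                  gaze_head_corr = 0.8,
                                  noise_sd = 0.02,
                                  missing_frame_prob = NULL,
                                  frame_rate_hz = 30,
                                  au_reaction = FALSE) {
  group <- match.arg(group)
  defaults <- switch(group,
    toddler = list(peak = 0.30, latency = 2.5, correct = 0.80, miss = 18 / 300),
    infant  = list(peak = 0.21, latency = 2.0, correct = 0.65, miss = 2 / 280)
  )
  p <- list(
    group = group,
    responder_prob = responder_prob,
    correct_side_prob = correct_side_prob %||% defaults$correct,
    peak_yaw_rad = peak_yaw_rad %||% defaults$peak,
    latency_peak_s = latency_peak_s %||% defaults$latency,
    baseline_yaw_rad = baseline_yaw_rad,
    gaze_head_corr = gaze_head_corr,
    noise_sd = noise_sd,
    missing_frame_prob = missing_frame_prob %||% defaults$miss,
    frame_rate_hz = frame_rate_hz,
    au_reaction = isTRUE(au_reaction)
  )
  for (nm in c("responder_prob", "correct_side_prob", "missing_frame_prob",
               "gaze_head_corr")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop_input(sprintf("'%s' must be a probability in [0, 1]", nm))
    }
  }
  if (p$peak_yaw_rad < 0) stop_input("'peak_yaw_rad' must be >= 0")
  if (p$frame_rate_hz <= 0) stop_input("'frame_rate_hz' must be > 0")
  if (p$noise_sd < 0) stop_input("'noise_sd' must be >= 0")
  structure(p, class = "response_model_params")
}

#' Generate a randomised stimulus schedule for one participant
#'
#' Produces 10 trials (each of the five stimulus types exactly twice) in
#' randomised order, with the speaker side drawn independently per trial
#' and successive onsets separated by at least 6 s (the protocol's
#' minimum inter-stimulus interval, plus a random re-centring delay).
#'
#' @param participant_id Opaque participant identifier.
#' @param group `"toddler"` or `"infant"`.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A `data.frame` of class `stimulus_schedule` with columns
#'   `participant_id`, `group`, `trial_index`, `stimulus`, `side`,
#'   `onset_time_s`.
#' @examples
#' s <- schedule_stimuli("P01", "toddler", seed = 1)
#' table(s$stimulus) # each type twice
#' min(diff(s$onset_time_s)) >= 6
#' @export
schedule_stimuli <- function(participant_id, group = c("toddler", "infant"),
                             seed = 1L) {
  group <- match.arg(group)
  withr::with_seed(seed, {
    stimuli <- sample(rep(stimulus_types(), 2L))
    sides <- sample(c("left", "right"), 10L, replace = TRUE)
    # first onset after the audio-visual primer; gaps = 6 s minimum ISI
    # plus a gamma-distributed re-centring delay (mean ~4.5 s)
    first <- 6 + stats::rgamma(1L, shape = 2, scale = 2)
    gaps <- 6 + stats::rgamma(9L, shape = 2, scale = 2.25)
    onsets <- first + c(0, cumsum(gaps))
  })
  out <- data.frame(
    participant_id = as.character(participant_id),
    group = group,
    trial_index = seq_len(10L),
    stimulus = stimuli,
    side = sides,
    onset_time_s = onsets,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

# Raised-cosine response envelope: 0 before onset + rise_start_s, rises to
# 1 at the peak latency, falls back to 0 by onset + 5 s.
response_envelope <- function(t_rel, latency_peak_s, rise_start_s = 0.5,
                              end_s = 5) {
  w <- numeric(length(t_rel))
  up <- t_rel >= rise_start_s & t_rel < latency_peak_s
  dn <- t_rel >= latency_peak_s & t_rel <= end_s
  w[up] <- 0.5 * (1 - cos(pi * (t_rel[up] - rise_start_s) /
                            (latency_peak_s - rise_start_s)))
  w[dn] <- 0.5 * (1 + cos(pi * (t_rel[dn] - latency_peak_s) /
                            (end_s - latency_peak_s)))
  w
}

# Target orientation angle for responder trials; see ?response_model_params.
responder_target_yaw <- function(params) {
  p <- params$responder_prob
  if (p <= 0) return(params$peak_yaw_rad)
  max(0, (params$peak_yaw_rad - (1 - p) * params$baseline_yaw_rad) / p)
}

# Unit gaze direction vector (camera looking along -z) from horizontal and
# vertical gaze angles; exactly unit norm by construction.
gaze_vector <- function(gx, gy) {
  cbind(
    x = cos(gy) * sin(gx),
    y = sin(gy),
    z = -cos(gy) * cos(gx)
  )
}

#' Simulate per-frame facial features for one trial
#'
#' Generates an OpenFace-dialect frame table spanning stimulus onset
#' -1 s to +5 s at `frame_rate_hz`. With probability `responder_prob`
#' the trial carries a smooth, unimodal head-yaw excursion: the head
#' rotates from its resting off-centre baseline toward a target angle on
#' the responded side (the presentation side with probability
#' `correct_side_prob`, otherwise the opposite side), peaking at
#' `latency_peak_s` and returning toward baseline by 5 s. Horizontal gaze
#' angle follows yaw with correlation `gaze_head_corr`. With probability
#' `missing_frame_prob` the frame nearest onset + 2 s is omitted,
#' emulating frames where no face was tracked.
#'
#' Sign convention: positive yaw and positive horizontal gaze mean the
#' head/gaze is directed toward the RIGHT speaker from the child's
#' perspective (mirrored OpenFace output can be accommodated downstream
#' with the `flip_yaw` ingest option).
#'
#' @param trial One-row `data.frame` with columns `side` and
#'   `onset_time_s` (a row of a [schedule_stimuli()] schedule).
#' @param params A [response_model_params()] object.
#' @param seed Integer seed.
#' @return A `data.frame` in [openface_columns()] order.
#' @export
simulate_trial_frames <- function(trial, params, seed = 1L) {
  stopifnot(inherits(params, "response_model_params"))
  fr <- params$frame_rate_hz
  onset <- trial$onset_time_s[1L]
  side <- trial$side[1L]
  t_rel <- seq(-1, 5, by = 1 / fr)
  n <- length(t_rel)

  withr::with_seed(seed, {
    # centred resting orientation whose mean absolute value equals
    # baseline_yaw_rad (half-normal identity), so the no-decision cluster
    # is unimodal at the origin
    baseline <- stats::rnorm(1L, 0, params$baseline_yaw_rad / sqrt(2 / pi))

    responder <- stats::runif(1L) < params$responder_prob
    if (responder) {
      correct <- stats::runif(1L) < params$correct_side_prob
      resp_side <- if (correct) side else setdiff(c("left", "right"), side)
      resp_sign <- if (resp_side == "right") 1 else -1
      # multiplicative jitter with mean exactly 1
      target <- responder_target_yaw(params) *
        stats::rlnorm(1L, meanlog = -0.005, sdlog = 0.1)
      w <- response_envelope(t_rel, params$latency_peak_s)
      yaw <- (1 - w) * baseline + w * resp_sign * target
    } else {
      yaw <- rep(baseline, n)
    }
    yaw <- yaw + stats::rnorm(n, 0, params$noise_sd)

    pitch <- stats::rnorm(1L, 0, 0.05) + stats::rnorm(n, 0, params$noise_sd)
    roll <- stats::rnorm(1L, 0, 0.03) + stats::rnorm(n, 0, params$noise_sd)

    rho <- params$gaze_head_corr
    gaze_x <- rho * yaw + sqrt(max(0, 1 - rho^2)) *
      stats::rnorm(n, 0, 0.15) + stats::rnorm(n, 0, params$noise_sd)
    gaze_y <- stats::rnorm(1L, 0, 0.05) + stats::rnorm(n, 0, params$noise_sd)

    g0 <- gaze_vector(gaze_x + stats::rnorm(n, 0, 0.01),
                      gaze_y + stats::rnorm(n, 0, 0.01))
    g1 <- gaze_vector(gaze_x + stats::rnorm(n, 0, 0.01),
                      gaze_y + stats::rnorm(n, 0, 0.01))

    pos <- cbind(stats::rnorm(n, 0, 5), stats::rnorm(n, 0, 5),
                 stats::rnorm(n, 600, 10))
    shape <- cbind(stats::rnorm(n, 1, 0.02),
                   matrix(stats::rnorm(n * 5L, 0, 0.05), n, 5L))
    au <- matrix(pmax(0, stats::rnorm(n * 35L, 0.2, 0.15)), n, 35L)
    if (params$au_reaction && responder) {
      w_au <- response_envelope(t_rel, params$latency_peak_s)
      au[, 1:5] <- au[, 1:5] + 0.5 * w_au
    }
    drop_extraction_frame <- stats::runif(1L) < params$missing_frame_prob
  })

  out <- data.frame(
    frame = as.integer(round((onset + t_rel) * fr)),
    timestamp = onset + t_rel,
    success = 1L,
    g0, g1,
    gaze_angle_x = gaze_x, gaze_angle_y = gaze_y,
    pos, pitch, yaw, roll, shape, au
  )
  names(out) <- openface_columns()
  if (drop_extraction_frame) {
    out <- out[-which.min(abs(out$timestamp - (onset + 2))), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Simulate a complete session for one participant
#'
#' Draws a stimulus schedule and simulates frames for all 10 trials.
#'
#' @inheritParams schedule_stimuli
#' @param params A [response_model_params()] object; defaults to the
#'   group's defaults.
#' @return List with elements `schedule` (a [schedule_stimuli()] table)
#'   and `frames` (one OpenFace-dialect `data.frame` covering all trials).
#' @export
simulate_session <- function(participant_id, group = c("toddler", "infant"),
                             params = NULL, seed = 1L) {
  group <- match.arg(group)
  params <- params %||% response_model_params(group)
  schedule <- schedule_stimuli(participant_id, group, seed = seed)
  frames <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
    simulate_trial_frames(schedule[i, ], params,
                          seed = derive_seed(seed, 100L + i))
  }))
  rownames(frames) <- NULL
  list(schedule = schedule, frames = frames)
}

#' Write a session (or cohort) to OpenFace-dialect CSV files
#'
#' Writes one feature CSV per participant (`<participant>_openface.csv`)
#' and one stimulus-log CSV (`stimulus_log.csv`) that together round-trip
#' losslessly through [read_session()].
#'
#' @param schedule Stimulus schedule covering one or more participants.
#' @param frames Either a single frame table (one participant) or a named
#'   list of frame tables keyed by participant id.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `features` (named vector of feature CSV
#'   paths) and `stimulus_log` (path).
#' @export
write_session <- function(schedule, frames, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory: ", out_dir)
  log_path <- file.path(out_dir, "stimulus_log.csv")
  utils::write.csv(
    schedule[, c("participant_id", "group", "trial_index", "stimulus",
                 "side", "onset_time_s"), drop = FALSE],
    log_path, row.names = FALSE
  )
  if (is.data.frame(frames)) {
    pid <- unique(schedule$participant_id)
    if (length(pid) > 1L) {
      stop_input("a single frame table requires a single-participant schedule")
    }
    frames <- if (length(pid) == 0L) list() else stats::setNames(list(frames), pid)
  }
  paths <- vapply(names(frames), function(pid) {
    p <- file.path(out_dir, paste0(pid, "_openface.csv"))
    utils::write.csv(frames[[pid]], p, row.names = FALSE)
    p
  }, character(1L))
  invisible(list(features = paths, stimulus_log = log_path))
}
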