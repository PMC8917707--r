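# Synthetic triaxial accelerometer signals for the five bed-net-use behaviours.
#
# Accelerations are in g. Gravity appears as a static offset on one axis
# (default y, the vertical axis of a net-mounted sensor); sensor noise is
# white Gaussian on all three axes. Motions add deterministic waveforms,
# scaled by a per-subject amplitude multiplier, on top of that baseline.

#' Behaviour label vocabulary
#'
#' The five base behaviour classes, in the canonical order used for factors
#' throughout the package. Children perform only the subset returned by
#' \code{child_labels()} (they cannot reach high enough for net-up/net-down).
#'
#' @return Character vector of labels.
#' @export
motion_labels <- function() c("sleep", "net_down", "net_up", "enter", "exit")

#' @rdname motion_labels
#' @export
child_labels <- function() c("sleep", "enter", "exit")

#' Simulator configuration
#'
#' @param sample_rate_hz Samples per second (device default 10 Hz).
#' @param noise_sd Baseline sensor noise standard deviation, in g.
#' @param gravity_axis Axis carrying the static gravity offset ("x","y","z").
#' @param gravity_g Static gravity offset, in g.
#' @param subject_scale Motion amplitude multiplier for adult entries
#'   (children use \code{child_scale}).
#' @param child_scale Amplitude multiplier applied to child entries; smaller
#'   bodies move the net less, which is what makes child motions harder to
#'   classify against the fixed sensor noise floor.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(sample_rate_hz = 10, noise_sd = 0.02, gravity_axis = "y",
                       gravity_g = 1.0, subject_scale = 1.0, child_scale = 0.5,
                       seed = 1L) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 || sample_rate_hz <= 0)
    stop("sim_config: sample_rate_hz must be a single positive number", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("sim_config: noise_sd must be >= 0", call. = FALSE)
  if (!gravity_axis %in% c("x", "y", "z"))
    stop("sim_config: gravity_axis must be one of 'x', 'y', 'z'", call. = FALSE)
  if (!is.numeric(subject_scale) || subject_scale <= 0)
    stop("sim_config: subject_scale must be > 0", call. = FALSE)
  if (!is.numeric(child_scale) || child_scale <= 0)
    stop("sim_config: child_scale must be > 0", call. = FALSE)
  structure(list(sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
                 gravity_axis = gravity_axis, gravity_g = gravity_g,
                 subject_scale = subject_scale, child_scale = child_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Default waveform shape parameters per label. Frequencies are well below the
# 5 Hz Nyquist limit of the default 10 Hz sampling.
default_shape <- function(label) {
  switch(label,
    sleep    = list(),
    net_down = list(jitter_sd = 0.15),
    net_up   = list(jitter_sd = 0.15),
    enter    = list(jitter_sd = 0.15, tau_frac = 0.25, f_y = 1.8, f_x = 1.3,
                    x_ratio = 0.5, drift_g = 0.004, drift_sign = +1),
    exit     = list(jitter_sd = 0.15, tau_frac = 0.25, f_y = 1.8, f_x = 1.3,
                    x_ratio = 0.5, drift_g = 0.004, drift_sign = -1),
    stop("unknown motion label: ", label, call. = FALSE)
  )
}

#' Motion waveform template
#'
#' Duration, peak amplitude and envelope-shape parameters for one behaviour.
#' Durations reflect how long each action takes at the net; amplitudes encode
#' that handling the whole net (net down / net up) shakes the sensor harder
#' than slipping under the edge (enter / exit), and that sleeping adds nothing
#' above the noise floor.
#'
#' @param label One of \code{motion_labels()}.
#' @param duration_s Motion length in seconds (defaults: net_down 3, net_up 4,
#'   enter 4, exit 4, sleep 60).
#' @param amplitude_g Peak acceleration above baseline in g (defaults:
#'   net_down/net_up 0.6, enter/exit 0.35, sleep 0).
#' @param shape Named list of envelope-shape parameters; defaults per label.
#' @return A list of class \code{motion_template}.
#' @export
motion_template <- function(label, duration_s = NULL, amplitude_g = NULL,
                            shape = NULL) {
  if (!label %in% motion_labels())
    stop("unknown motion label: ", label, call. = FALSE)
  dur <- c(sleep = 60, net_down = 3, net_up = 4, enter = 4, exit = 4)[[label]]
  amp <- c(sleep = 0, net_down = 0.6, net_up = 0.6, enter = 0.35, exit = 0.35)[[label]]
  if (!is.null(duration_s)) dur <- duration_s
  if (!is.null(amplitude_g)) amp <- amplitude_g
  if (dur <= 0) stop("motion_template: duration_s must be > 0", call. = FALSE)
  if (amp < 0) stop("motion_template: amplitude_g must be >= 0", call. = FALSE)
  if (label == "sleep" && amp != 0)
    stop("motion_template: sleep must have amplitude_g = 0", call. = FALSE)
  sh <- default_shape(label)
  if (!is.null(shape)) sh[names(shape)] <- shape
  structure(list(label = label, duration_s = dur, amplitude_g = amp, shape = sh),
            class = "motion_template")
}

# Biphasic vertical pulse with damped settling, unit peak magnitude: the net
# is pulled down (or pushed up) and the frame rings briefly afterwards. The
# two lobes are unequal so the waveform has a non-zero integral, giving the
# epoch mean on the vertical axis a signed shift that separates net_down from
# net_up.
pulse_wave <- function(n, sample_rate_hz) {
  t <- (seq_len(n) - 1) / sample_rate_hz
  dur <- n / sample_rate_hz
  t1 <- 0.4 * dur
  t2 <- 0.3 * dur
  w <- numeric(n)
  i1 <- t < t1
  w[i1] <- -1.25 * sin(pi * t[i1] / t1)
  i2 <- t >= t1 & t < (t1 + t2)
  w[i2] <- 0.75 * sin(pi * (t[i2] - t1) / t2)
  i3 <- t >= (t1 + t2)
  if (any(i3)) {
    ts <- t1 + t2
    rem <- max(dur - ts, 1 / sample_rate_hz)
    w[i3] <- 0.30 * exp(-4 * (t[i3] - ts) / rem) * sin(2 * pi * 3 * (t[i3] - ts))
  }
  w / 1.25
}

#' Amplitude envelope of a motion
#'
#' Unit-peak envelope sampled at the configured rate. Entering has a fast
#' rise and slow decay (the initial push on the net edge, then settling);
#' exiting is, by construction, the exact time reversal of entering, so that
#' the two motions are indistinguishable to order-insensitive 10-s summary
#' statistics. Net-down/net-up return the magnitude of the biphasic pulse;
#' sleep returns zeros.
#'
#' @param label One of \code{motion_labels()}.
#' @param duration_s Motion duration in seconds.
#' @param sample_rate_hz Sampling rate.
#' @param shape Shape parameter list (see \code{\link{motion_template}}).
#' @return Numeric vector of length \code{round(duration_s * sample_rate_hz)}.
#' @export
motion_envelope <- function(label, duration_s, sample_rate_hz,
                            shape = default_shape(label)) {
  if (!label %in% motion_labels())
    stop("unknown motion label: ", label, call. = FALSE)
  n <- round(duration_s * sample_rate_hz)
  if (label == "sleep") return(numeric(n))
  if (label %in% c("net_down", "net_up"))
    return(abs(pulse_wave(n, sample_rate_hz)))
  # enter/exit: gamma-shaped envelope (t/tau) exp(1 - t/tau), peak 1 at t = tau
  t <- (seq_len(n) - 1) / sample_rate_hz
  tau <- shape$tau_frac * duration_s
  env <- (t / tau) * exp(1 - t / tau)
  if (label == "exit") env <- rev(env)
  env
}

# Deterministic-plus-instance-random waveform for one motion: an n x 3 matrix
# of accelerations (in g) to add to the baseline. Consumes the RNG stream
# (instance amplitude jitter; carrier phases for enter/exit). `scale`
# multiplies every term, so two runs with the same seed and different scales
# differ by exactly that factor.
motion_signal <- function(label, cfg, template, scale) {
  rate <- cfg$sample_rate_hz
  n <- round(template$duration_s * rate)
  delta <- matrix(0, nrow = n, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  if (label == "sleep" || n == 0) return(delta)
  sh <- template$shape
  jitter <- exp(rnorm(1, 0, sh$jitter_sd))
  a <- template$amplitude_g * jitter * scale
  if (label %in% c("net_down", "net_up")) {
    w <- pulse_wave(n, rate)
    delta[, "y"] <- if (label == "net_down") a * w else -a * w
    return(delta)
  }
  # enter / exit
  t <- (seq_len(n) - 1) / rate
  env <- motion_envelope(label, template$duration_s, rate, sh)
  phase <- runif(2, 0, 2 * pi)
  delta[, "y"] <- a * env * sin(2 * pi * sh$f_y * t + phase[1])
  delta[, "x"] <- a * sh$x_ratio * env * sin(2 * pi * sh$f_x * t + phase[2])
  delta[, "x"] <- delta[, "x"] + sh$drift_sign * sh$drift_g * scale
  delta
}

new_recording <- function(samples, sample_rate_hz,
                          start_time = as.POSIXct("2022-01-10 20:00:00", tz = "UTC")) {
  rec <- data.frame(time = (seq_len(nrow(samples)) - 1) / sample_rate_hz,
                    x = samples[, "x"], y = samples[, "y"], z = samples[, "z"])
  attr(rec, "sample_rate_hz") <- sample_rate_hz
  attr(rec, "start_time") <- start_time
  class(rec) <- c("net_recording", "data.frame")
  rec
}

baseline_matrix <- function(n, cfg) {
  m <- matrix(rnorm(3 * n, 0, cfg$noise_sd), nrow = n, ncol = 3,
              dimnames = list(NULL, c("x", "y", "z")))
  m[, cfg$gravity_axis] <- m[, cfg$gravity_axis] + cfg$gravity_g
  m
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Simulate a single tagged motion
#'
#' Generates one motion segment embedded in the noisy gravity baseline,
#' together with its motion tag. The tag interval brackets the non-baseline
#' portion of the segment.
#'
#' @param label One of \code{motion_labels()}.
#' @param cfg A \code{\link{sim_config}}.
#' @param template A \code{\link{motion_template}} (defaults per label).
#' @param subject_class "adult" or "child"; children use \code{cfg$child_scale}.
#' @param subject_id Identifier recorded in the tag.
#' @return List with elements \code{recording} (a \code{net_recording}) and
#'   \code{tags} (a one-row \code{net_tags} data frame).
#' @export
simulate_motion <- function(label, cfg = sim_config(),
                            template = motion_template(label),
                            subject_class = "adult", subject_id = "s01") {
  if (!label %in% motion_labels())
    stop("unknown motion label: ", label, call. = FALSE)
  plan <- data.frame(label = label, subject_class = subject_class,
                     subject_id = subject_id, stringsAsFactors = FALSE)
  simulate_session(plan, cfg, gap_s = 0, tail_s = 0,
                   templates = stats::setNames(list(template), label))
}

validate_plan <- function(plan, on_child_violation) {
  if (!is.data.frame(plan) || nrow(plan) == 0)
    stop("simulate_session: plan must be a non-empty data frame", call. = FALSE)
  if (!"label" %in% names(plan))
    stop("simulate_session: plan must have a 'label' column", call. = FALSE)
  if (is.null(plan$subject_class)) plan$subject_class <- "adult"
  if (is.null(plan$subject_id)) plan$subject_id <- "s01"
  bad <- setdiff(unique(plan$label), motion_labels())
  if (length(bad))
    stop("simulate_session: unknown motion label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  viol <- plan$subject_class == "child" & !plan$label %in% child_labels()
  if (any(viol)) {
    msg <- sprintf("plan assigns %s to child entries; children perform only %s",
                   paste(unique(plan$label[viol]), collapse = "/"),
                   paste(child_labels(), collapse = "/"))
    if (on_child_violation == "error") stop("simulate_session: ", msg, call. = FALSE)
    warning("simulate_session: ", msg, call. = FALSE)
  }
  plan
}

#' Simulate a session of motions with baseline gaps
#'
#' Concatenates motion segments in plan order, separated by baseline-only
#' gaps (quiescent net, sensor noise only), and returns the recording with
#' time-ordered, non-overlapping tags. All randomness flows from
#' \code{cfg$seed}: identical (plan, cfg) inputs give bit-identical output.
#'
#' @param plan Data frame with columns \code{label} and optionally
#'   \code{subject_class} ("adult"/"child", default adult) and
#'   \code{subject_id}.
#' @param cfg A \code{\link{sim_config}}.
#' @param gap_s Baseline gap between consecutive motions, seconds.
#' @param tail_s Trailing baseline after the last motion, seconds (give at
#'   least 20 s when the last motion is shorter than one observation window).
#' @param on_child_violation "warning" or "error" when a child entry is given
#'   a net_up/net_down motion.
#' @param templates Optional named list of \code{\link{motion_template}}
#'   overrides, keyed by label.
#' @return List with \code{recording} and \code{tags} (data frame with
#'   columns label, start, end, subject_id, subject_class; times in seconds
#'   from recording start; intervals half-open).
#' @export
simulate_session <- function(plan, cfg = sim_config(), gap_s = 60, tail_s = 0,
                             on_child_violation = c("warning", "error"),
                             templates = list()) {
  on_child_violation <- match.arg(on_child_violation)
  plan <- validate_plan(plan, on_child_violation)
  rate <- cfg$sample_rate_hz
  k <- nrow(plan)
  tmpl <- lapply(plan$label, function(lb)
    if (!is.null(templates[[lb]])) templates[[lb]] else motion_template(lb))
  n_motion <- vapply(tmpl, function(tm) round(tm$duration_s * rate), numeric(1))
  n_gap <- round(gap_s * rate)
  n_tail <- round(tail_s * rate)
  offsets <- cumsum(c(0, head(n_motion, -1) + n_gap))
  n_total <- sum(n_motion) + (k - 1) * n_gap + n_tail

  with_seed(cfg$seed, {
    deltas <- vector("list", k)
    for (i in seq_len(k)) {
      scale <- if (plan$subject_class[i] == "child") cfg$child_scale else cfg$subject_scale
      deltas[[i]] <- motion_signal(plan$label[i], cfg, tmpl[[i]], scale)
    }
    samples <- baseline_matrix(n_total, cfg)
    for (i in seq_len(k)) {
      idx <- offsets[i] + seq_len(n_motion[i])
      samples[idx, ] <- samples[idx, ] + deltas[[i]]
    }
  })

  tags <- data.frame(label = plan$label,
                     start = offsets / rate,
                     end = (offsets + n_motion) / rate,
                     subject_id = plan$subject_id,
                     subject_class = plan$subject_class,
                     stringsAsFactors = FALSE)
  class(tags) <- c("net_tags", "data.frame")
  list(recording = new_recording(samples, rate), tags = tags)
}

#' Simulate a full multi-subject study
#'
#' Builds a study-protocol plan — each subject repeats their motion set
#' \code{reps} times with a baseline break between motions, children
#' restricted to enter/sleep/exit — and simulates it as one continuous
#' recording. Motion order within each repetition is randomized.
#'
#' @param n_subjects Total number of subjects.
#' @param child_fraction Fraction of subjects that are children.
#' @param reps Repetitions of each motion per subject.
#' @param cfg A \code{\link{sim_config}}; \code{cfg$seed} drives both the
#'   plan shuffle and the signal generation.
#' @param gap_s Baseline gap between motions, seconds.
#' @param tail_s Trailing baseline, seconds.
#' @return As \code{\link{simulate_session}}.
#' @export
simulate_study <- function(n_subjects = 27, child_fraction = 1 / 3, reps = 14,
                           cfg = sim_config(), gap_s = 60, tail_s = 30) {
  if (n_subjects < 1) stop("simulate_study: n_subjects must be >= 1", call. = FALSE)
  n_children <- round(child_fraction * n_subjects)
  classes <- c(rep("child", n_children), rep("adult", n_subjects - n_children))
  ids <- sprintf("s%02d", seq_len(n_subjects))
  res <- with_seed(cfg$seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      labs <- if (classes[s] == "child") child_labels() else motion_labels()
      for (r in seq_len(reps)) {
        ord <- sample(labs)
        rows[[length(rows) + 1]] <- data.frame(
          label = ord, subject_class = classes[s], subject_id = ids[s],
          stringsAsFactors = FALSE)
      }
    }
    plan <- do.call(rbind, rows)
    sess_seed <- sample.int(.Machine$integer.max, 1)
    list(plan = plan, sess_seed = sess_seed)
  })
  cfg$seed <- res$sess_seed
  simulate_session(res$plan, cfg, gap_s = gap_s, tail_s = tail_s)
}
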