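# Reduction of tagged recordings to fixed-length observations: each tag is a
# 20-s window, anchored at the tag start and split into two contiguous 10-s
# epochs, each summarized by per-axis means/SDs and a displacement-magnitude
# sum.

OBS_WINDOW_S <- 20
EPOCH_S <- 10

#' Per-epoch summary statistics
#'
#' Reduces one epoch of triaxial samples to per-axis means, per-axis sample
#' standard deviations (n - 1 denominator), and the displacement-magnitude
#' sum: the sum over consecutive sample pairs of the norm of the change in
#' (x, y, z). With \code{disp = "euclidean"} the norm is the Euclidean norm
#' of the difference vector; with \code{disp = "per_axis"} it is the sum of
#' the per-axis absolute differences (L1).
#'
#' @param samples Matrix or data frame with columns x, y, z; at least 2 rows.
#' @param disp Displacement-norm convention.
#' @return Named list: mean_x/y/z, sd_x/y/z, disp_sum.
#' @export
epoch_stats <- function(samples, disp = c("euclidean", "per_axis")) {
  disp <- match.arg(disp)
  m <- as.matrix(samples[, c("x", "y", "z")])
  if (nrow(m) < 2)
    stop("epoch_stats: need at least 2 samples in an epoch", call. = FALSE)
  d <- diff(m)
  disp_sum <- if (disp == "euclidean") sum(sqrt(rowSums(d^2))) else sum(abs(d))
  list(mean_x = mean(m[, "x"]), mean_y = mean(m[, "y"]), mean_z = mean(m[, "z"]),
       sd_x = sd(m[, "x"]), sd_y = sd(m[, "y"]), sd_z = sd(m[, "z"]),
       disp_sum = disp_sum)
}

# Per-epoch statistics kept by each feature scheme, in order. "paper10"
# retains the 10-feature set (means of all axes, SD of the vertical axis,
# displacement sum, per epoch); "full14" additionally keeps the x and z SDs.
scheme_stats <- function(scheme) {
  switch(scheme,
    paper10 = c("mean_x", "mean_y", "mean_z", "sd_y", "disp_sum"),
    full14  = c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z", "disp_sum"),
    stop("unknown feature scheme: ", scheme, " (use 'paper10' or 'full14')",
         call. = FALSE)
  )
}

#' Feature names of a scheme
#'
#' @param scheme "paper10" (10 features) or "full14" (14 features).
#' @return Character vector, epoch-1 block then epoch-2 block.
#' @export
feature_names <- function(scheme = "paper10") {
  st <- scheme_stats(scheme)
  c(paste0(st, "_e1"), paste0(st, "_e2"))
}

tag_start_seconds <- function(start, rec) {
  if (inherits(start, "POSIXct"))
    return(as.numeric(difftime(start, attr(rec, "start_time"), units = "secs")))
  as.numeric(start)
}

#' Extract one observation from a tagged recording
#'
#' Takes the 20-s window starting at the tag start, splits it into two
#' contiguous 10-s epochs, and assembles the feature vector for the given
#' scheme. The window may extend past the motion into baseline (that is the
#' design: short motions are padded by the surrounding quiescent signal), but
#' the recording itself must cover it.
#'
#' @param rec A \code{net_recording}.
#' @param tag One-row data frame with columns label, start, end,
#'   subject_class (start/end in seconds from recording start, or POSIXct).
#' @param scheme Feature scheme name.
#' @param disp Displacement-norm convention, see \code{\link{epoch_stats}}.
#' @return Named list: \code{features} (named numeric vector), \code{label},
#'   \code{subject_class}.
#' @export
extract_observation <- function(rec, tag, scheme = "paper10",
                                disp = c("euclidean", "per_axis")) {
  disp <- match.arg(disp)
  st <- scheme_stats(scheme)  # validates scheme before any work
  rate <- attr(rec, "sample_rate_hz")
  start_s <- tag_start_seconds(tag$start, rec)
  i0 <- round(start_s * rate)
  n_win <- round(OBS_WINDOW_S * rate)
  n_ep <- round(EPOCH_S * rate)
  if (i0 < 0 || i0 + n_win > nrow(rec))
    stop(sprintf(paste0("extract_observation: window [%g, %g) s extends past ",
                        "the recording (%g s)"),
                 start_s, start_s + OBS_WINDOW_S, nrow(rec) / rate),
         call. = FALSE)
  e1 <- epoch_stats(rec[i0 + seq_len(n_ep), ], disp = disp)
  e2 <- epoch_stats(rec[i0 + n_ep + seq_len(n_ep), ], disp = disp)
  feats <- c(unlist(e1[st]), unlist(e2[st]))
  names(feats) <- feature_names(scheme)
  list(features = feats,
       label = as.character(tag$label),
       subject_class = if (!is.null(tag$subject_class)) tag$subject_class else NA_character_)
}

#' Build the observation table for a tagged recording
#'
#' One row per tag, in tag order; feature columns per the scheme, plus
#' \code{label} (factor over \code{\link{motion_labels}}),
#' \code{subject_class}, and \code{subject_id}.
#'
#' @param rec A \code{net_recording}.
#' @param tags A \code{net_tags} data frame (non-overlapping intervals).
#' @inheritParams extract_observation
#' @return Data frame of observations (zero rows for an empty tag list).
#' @export
build_dataset <- function(rec, tags, scheme = "paper10",
                          disp = c("euclidean", "per_axis")) {
  disp <- match.arg(disp)
  fn <- feature_names(scheme)
  if (is.null(tags) || nrow(tags) == 0) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(fn),
                                dimnames = list(NULL, fn)))
    out$label <- factor(character(0), levels = motion_labels())
    out$subject_class <- character(0)
    out$subject_id <- character(0)
    return(out)
  }
  check_tag_overlap(tags)
  rows <- lapply(seq_len(nrow(tags)), function(i)
    extract_observation(rec, tags[i, ], scheme = scheme, disp = disp)$features)
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- factor(tags$label, levels = motion_labels())
  out$subject_class <- if (!is.null(tags$subject_class)) tags$subject_class else NA_character_
  out$subject_id <- if (!is.null(tags$subject_id)) tags$subject_id else NA_character_
  out
}

# Tags must be non-overlapping within a subject (one net, one notebook).
check_tag_overlap <- function(tags) {
  for (sid in unique(tags$subject_id %||% "s01")) {
    tg <- if (is.null(tags$subject_id)) tags else tags[tags$subject_id == sid, ]
    if (any(tg$end <= tg$start))
      stop("tags: end must be after start", call. = FALSE)
    o <- order(tg$start)
    if (nrow(tg) > 1 && any(tg$start[o][-1] < tg$end[o][-nrow(tg)]))
      stop("tags: overlapping intervals for subject ", sid, call. = FALSE)
  }
  invisible(tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
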