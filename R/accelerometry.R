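# Accelerometer preprocessing: nonwear detection, daily wear/MVPA summaries
# and per-child weekday/weekend means under the study inclusion rules.

#' Construct an epoch-level activity count series
#'
#' Holds one child's accelerometer record: activity counts at a fixed epoch
#' length (typically 10 s).  Timestamps must be strictly increasing at
#' constant spacing equal to the epoch length.
#'
#' @param child_id Identifier for the child.
#' @param timestamps `POSIXct` vector, one instant per epoch, strictly
#'   increasing at constant spacing `epoch_length_s`.
#' @param counts Non-negative integer activity counts, one per epoch.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(child_id, timestamps, counts, epoch_length_s = 10L) {
  if (length(timestamps) != length(counts))
    stop("timestamps and counts must have equal length")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (length(timestamps) > 1L) {
    d <- as.numeric(diff(timestamps), units = "secs")
    if (any(abs(d - epoch_length_s) > 1e-6))
      stop("timestamps must increase at constant spacing equal to epoch_length_s")
  }
  structure(list(child_id = child_id,
                 timestamps = timestamps,
                 counts = as.numeric(counts),
                 epoch_length_s = as.integer(epoch_length_s)),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> child %s: %d epochs of %d s (%.1f min)\n",
              x$child_id, length(x$counts), x$epoch_length_s,
              length(x$counts) * x$epoch_length_s / 60))
  invisible(x)
}

# epochs per minute; requires that a minute is a whole number of epochs
.epochs_per_minute <- function(epoch_length_s) {
  if (60 %% epoch_length_s != 0)
    stop("one minute must be an integer number of epochs (60 %% epoch_length_s == 0)")
  60L %/% epoch_length_s
}

#' Detect nonwear intervals in an epoch series
#'
#' A nonwear interval is a maximal stretch containing at least
#' `zero_run_min` minutes of zero counts, during which interrupting
#' (non-zero) epochs total at most `interruption_allow_min` minutes.
#' Interrupting epochs do not count toward the zero-minute requirement, and
#' intervals begin and end on zero-count epochs.  The default parameters
#' (60 min of zeros, up to 2 min of interruptions) are the standard
#' waist-worn accelerometer convention for children.
#'
#' The scan is greedy left to right: from each zero run not already inside a
#' detected interval, the window is extended through interruptions while the
#' cumulative interruption budget holds; the window is emitted if its zero
#' time reaches the threshold.
#'
#' @param series An [epoch_series()].
#' @param zero_run_min Minimum zero-count minutes for nonwear (default 60).
#' @param interruption_allow_min Maximum total interruption minutes allowed
#'   inside one interval (default 2).
#' @return A data.frame with one row per nonwear interval: `start` and `end`
#'   (epoch indices, inclusive), `minutes` (total span), `zero_minutes` and
#'   `interruption_minutes`.
#' @export
detect_nonwear <- function(series, zero_run_min = 60, interruption_allow_min = 2) {
  stopifnot(inherits(series, "epoch_series"))
  counts <- series$counts
  if (length(counts) == 0L)
    return(data.frame(start = integer(), end = integer(), minutes = numeric(),
                      zero_minutes = numeric(), interruption_minutes = numeric()))
  if (any(counts < 0)) stop("counts must be non-negative")
  epm <- .epochs_per_minute(series$epoch_length_s)
  min_per_epoch <- 1 / epm

  r <- rle(counts == 0)
  n_runs <- length(r$lengths)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  out <- list()
  i <- 1L
  while (i <= n_runs) {
    if (!r$values[i]) { i <- i + 1L; next }          # need a zero run to start
    zero_ep <- r$lengths[i]
    intr_ep <- 0L
    j <- i                                           # last run inside window
    k <- i + 1L
    while (k + 1L <= n_runs) {                       # nonzero run k, zero run k+1
      if (intr_ep + r$lengths[k] > interruption_allow_min * epm) break
      intr_ep <- intr_ep + r$lengths[k]
      zero_ep <- zero_ep + r$lengths[k + 1L]
      j <- k + 1L
      k <- k + 2L
    }
    if (zero_ep * min_per_epoch >= zero_run_min) {
      out[[length(out) + 1L]] <- c(start = run_start[i], end = run_end[j],
                                   zero_ep = zero_ep, intr_ep = intr_ep)
      i <- j + 1L
    } else {
      i <- i + 1L                                    # retry from next zero run
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), minutes = numeric(),
                      zero_minutes = numeric(), interruption_minutes = numeric()))
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, "start"]),
             end = as.integer(m[, "end"]),
             minutes = (m[, "end"] - m[, "start"] + 1) * min_per_epoch,
             zero_minutes = m[, "zero_ep"] * min_per_epoch,
             interruption_minutes = m[, "intr_ep"] * min_per_epoch,
             row.names = NULL)
}

#' Summarise one day of accelerometer wear
#'
#' Computes wear time (day length minus detected nonwear), MVPA minutes
#' (wear-time epochs at or above the MVPA cut point) and the valid-day flag
#' (wear time of at least `valid_day_min` minutes).  Cut points are
#' population specific and must be supplied explicitly; they are expressed
#' in counts per minute and scaled internally to the epoch length.
#'
#' @param series An [epoch_series()] covering (part of) one calendar day.
#' @param cutpoints Named list with at least `mvpa_cpm`, the MVPA threshold
#'   in counts per minute.  No defaults are provided.
#' @param valid_day_min Minimum wear minutes for a valid day (default 500).
#' @param zero_run_min,interruption_allow_min Passed to [detect_nonwear()].
#' @param date,day_type Optional overrides; by default derived from the
#'   first timestamp (weekend = Saturday/Sunday).
#' @return A one-row data.frame (`day_summary`): `child_id`, `date`,
#'   `day_type`, `wear_minutes`, `mvpa_minutes`, `valid`.
#' @export
summarize_day <- function(series, cutpoints, valid_day_min = 500,
                          zero_run_min = 60, interruption_allow_min = 2,
                          date = NULL, day_type = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (missing(cutpoints) || is.null(cutpoints) || is.null(cutpoints$mvpa_cpm))
    stop("cutpoints must be supplied as a list with an 'mvpa_cpm' element ",
         "(counts per minute); no default cut points are assumed")
  epm <- .epochs_per_minute(series$epoch_length_s)
  min_per_epoch <- 1 / epm
  if (is.null(date))
    date <- if (length(series$timestamps)) as.Date(series$timestamps[1]) else NA
  if (is.null(day_type)) {
    wd <- if (!is.na(date)) format(as.Date(date), "%u") else NA
    day_type <- if (!is.na(wd) && wd %in% c("6", "7")) "weekend" else "weekday"
  }

  n <- length(series$counts)
  day_minutes <- n * min_per_epoch
  nw <- detect_nonwear(series, zero_run_min, interruption_allow_min)
  nonwear_idx <- if (nrow(nw)) unlist(mapply(seq.int, nw$start, nw$end,
                                             SIMPLIFY = FALSE)) else integer()
  wear_minutes <- day_minutes - length(nonwear_idx) * min_per_epoch

  thr_per_epoch <- cutpoints$mvpa_cpm * min_per_epoch  # cpm -> counts/epoch
  wear_mask <- rep(TRUE, n)
  wear_mask[nonwear_idx] <- FALSE
  mvpa_minutes <- sum(series$counts[wear_mask] >= thr_per_epoch) * min_per_epoch

  structure(data.frame(child_id = series$child_id,
                       date = date,
                       day_type = day_type,
                       wear_minutes = wear_minutes,
                       mvpa_minutes = mvpa_minutes,
                       valid = wear_minutes >= valid_day_min,
                       stringsAsFactors = FALSE),
            class = c("day_summary", "data.frame"))
}

#' Per-child weekday and weekend MVPA means with inclusion rules
#'
#' Averages MVPA over valid days, separately for weekdays and weekend days,
#' and applies the inclusion rule: at least `min_weekdays` valid weekdays
#' and `min_weekend_days` valid weekend days.  Children failing inclusion
#' are flagged `excluded`, never silently dropped.
#'
#' @param days A data.frame of day summaries (rows from [summarize_day()],
#'   possibly for several children).
#' @param min_weekdays Minimum valid weekdays required (default 2).
#' @param min_weekend_days Minimum valid weekend days required (default 1).
#' @return A data.frame, one row per child: `child_id`, `n_valid_weekdays`,
#'   `n_valid_weekend_days`, `weekday_mvpa`, `weekend_mvpa`, `excluded`.
#'   MVPA means are `NA` for excluded children.
#' @export
child_mvpa_means <- function(days, min_weekdays = 2, min_weekend_days = 1) {
  stopifnot(is.data.frame(days),
            all(c("child_id", "day_type", "mvpa_minutes", "valid") %in% names(days)))
  res <- lapply(split(days, days$child_id), function(d) {
    wk <- d[d$valid & d$day_type == "weekday", "mvpa_minutes"]
    we <- d[d$valid & d$day_type == "weekend", "mvpa_minutes"]
    ok <- length(wk) >= min_weekdays && length(we) >= min_weekend_days
    data.frame(child_id = d$child_id[1],
               n_valid_weekdays = length(wk),
               n_valid_weekend_days = length(we),
               weekday_mvpa = if (ok) mean(wk) else NA_real_,
               weekend_mvpa = if (ok) mean(we) else NA_real_,
               excluded = !ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
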