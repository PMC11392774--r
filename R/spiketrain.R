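#' Spike train objects
#'
#' A `spike_train` holds the spike timestamps of one unit within a
#' fixed-duration recording window, together with condition and cell-type
#' labels.  Timestamps are in seconds, strictly increasing, and lie in
#' `[0, duration]`.
#'
#' @param timestamps numeric vector of spike times in seconds.
#' @param duration record length in seconds (default 60, a 1-min record).
#' @param condition `"baseline"` or `"stimulation"`.
#' @param cell_type `"pyramidal"`, `"interneuron"` or `"unspecified"`.
#' @param unit_id identifier string for the unit.
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 1.2), duration = 2)
#' n_spikes(st)
#' @export
spike_train <- function(timestamps, duration = 60,
                        condition = c("baseline", "stimulation"),
                        cell_type = c("unspecified", "pyramidal", "interneuron"),
                        unit_id = "unit") {
  condition <- match.arg(condition)
  cell_type <- match.arg(cell_type)
  timestamps <- as.numeric(timestamps)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number (seconds)")
  }
  if (anyNA(timestamps)) stop("`timestamps` must not contain NA")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing")
  }
  if (length(timestamps) > 0L &&
      (timestamps[1L] < 0 || timestamps[length(timestamps)] > duration)) {
    stop("`timestamps` must lie within [0, duration]")
  }
  structure(
    list(timestamps = timestamps, duration = duration,
         condition = condition, cell_type = cell_type,
         unit_id = as.character(unit_id)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s' (%s, %s): %d spikes in %.3g s (%.2f spikes/s)\n",
              x$unit_id, x$cell_type, x$condition,
              length(x$timestamps), x$duration, firing_rate(x)))
  invisible(x)
}

#' Number of spikes in a train
#' @param train a `spike_train`.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$timestamps)
}

#' Mean firing rate of a spike train
#'
#' Spike count divided by the record duration.  An empty train has rate 0.
#'
#' @param train a `spike_train`.
#' @return rate in spikes per second.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$timestamps) / train$duration
}

#' Inter-spike interval sequence of a spike train
#'
#' Consecutive differences of the spike timestamps, order preserved, with
#' first-order summary moments.  The coefficient of variation uses the
#' sample standard deviation (n - 1 denominator) throughout the package.
#'
#' @param train a `spike_train` with at least two spikes.
#' @return An `isi_sequence`: list with `intervals` (seconds), `n`,
#'   `mean_isi`, `sd_isi` and `cv`.
#' @examples
#' to_isi(spike_train(c(0, 0.02, 0.06), duration = 1))$intervals
#' @export
to_isi <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$timestamps) < 2L) {
    stop("at least 2 spikes are required to form an ISI sequence")
  }
  new_isi_sequence(diff(train$timestamps))
}

#' Construct an ISI sequence from raw intervals
#'
#' @param intervals numeric vector of inter-spike intervals in seconds,
#'   each strictly positive.
#' @return An `isi_sequence`.
#' @export
new_isi_sequence <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L) stop("`intervals` must be non-empty")
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("all intervals must be positive and non-missing")
  }
  m <- mean(intervals)
  s <- if (length(intervals) >= 2L) stats::sd(intervals) else NA_real_
  structure(
    list(intervals = intervals, n = length(intervals),
         mean_isi = m, sd_isi = s, cv = s / m),
    class = "isi_sequence"
  )
}

#' @export
print.isi_sequence <- function(x, ...) {
  cat(sprintf("<isi_sequence> %d intervals; mean %.4g s, SD %.4g s, CV %.3f\n",
              x$n, x$mean_isi, x$sd_isi, x$cv))
  invisible(x)
}

# Coerce a metric input to a bare interval vector.  Accepts an isi_sequence,
# a spike_train (converted), or a numeric vector of intervals.
as_intervals <- function(x) {
  if (inherits(x, "isi_sequence")) return(x$intervals)
  if (inherits(x, "spike_train")) return(to_isi(x)$intervals)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an isi_sequence, spike_train, or numeric interval vector")
}

#' Write spike trains to a spike-times CSV
#'
#' One row per spike with header `unit_id,condition,cell_type,time_s`;
#' times are written with microsecond precision or better.
#'
#' @param trains a `spike_train` or a list of them.
#' @param path output file path.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- do.call(rbind, lapply(trains, function(tr) {
    stopifnot(inherits(tr, "spike_train"))
    if (length(tr$timestamps) == 0L) return(NULL)
    data.frame(unit_id = tr$unit_id, condition = tr$condition,
               cell_type = tr$cell_type,
               time_s = sprintf("%.9f", tr$timestamps),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains from a spike-times CSV
#'
#' Inverse of [write_spike_csv()].  Spikes are grouped by
#' `(unit_id, condition)`; the record duration is not stored in the CSV and
#' must be supplied.
#'
#' @param path input file path.
#' @param duration record length in seconds applied to every train.
#' @return A list of `spike_train` objects.
#' @export
read_spike_csv <- function(path, duration = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "condition", "cell_type", "time_s")
  if (!all(need %in% names(df))) {
    stop("spike CSV must have columns ", paste(need, collapse = ", "))
  }
  keys <- interaction(df$unit_id, df$condition, drop = TRUE)
  lapply(split(df, keys), function(g) {
    g <- g[order(g$time_s), ]
    spike_train(g$time_s, duration = duration,
                condition = g$condition[1L], cell_type = g$cell_type[1L],
                unit_id = g$unit_id[1L])
  })
}
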