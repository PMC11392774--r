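#' Per-unit metric record for one spike train
#'
#' Computes the full metric family for a single train: firing rate, CV,
#' ApEn, ISI fractions in the 0-8 ms (burst) and 19-21 ms (first
#' entrainment peak) ranges, the Fano scaling exponent alpha, and the R/S
#' Hurst exponent.  Metrics whose preconditions fail (e.g. too few spikes)
#' are returned as `NA` with the reason recorded in the `"failures"`
#' attribute.
#'
#' @param train a `spike_train`.
#' @param fano_fit_lo,fano_fit_hi Fano fit range in seconds.
#' @param t_min,t_max Fano window-size range in seconds.
#' @return a one-row `data.frame` with columns `unit_id`, `cell_type`,
#'   `condition`, `n_spikes`, `rate`, `cv`, `apen`, `frac_0_8ms`,
#'   `frac_19_21ms`, `alpha`, `H`.
#' @export
unit_metrics <- function(train, fano_fit_lo = 10^-0.5, fano_fit_hi = 10,
                         t_min = 0.1, t_max = 10) {
  stopifnot(inherits(train, "spike_train"))
  failures <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[length(failures) + 1L]] <<- paste0(name, ": ", conditionMessage(e))
      NA_real_
    })
  }
  isis <- tryCatch(to_isi(train), error = function(e) NULL)
  rec <- data.frame(
    unit_id = train$unit_id, cell_type = train$cell_type,
    condition = train$condition, n_spikes = length(train$timestamps),
    rate = firing_rate(train),
    cv = if (is.null(isis)) NA_real_ else grab("cv", isi_cv(isis)),
    apen = if (is.null(isis)) NA_real_ else grab("apen", apen(isis)),
    frac_0_8ms = if (is.null(isis)) NA_real_ else grab("frac_0_8ms", isi_fraction(isis, 0, 8)),
    frac_19_21ms = if (is.null(isis)) NA_real_ else grab("frac_19_21ms", isi_fraction(isis, 19, 21)),
    alpha = grab("alpha", fano_curve(train, t_min = t_min, t_max = t_max,
                                     fit_lo = fano_fit_lo,
                                     fit_hi = fano_fit_hi)$alpha),
    H = if (is.null(isis)) NA_real_ else grab("H", hurst_exponent(isis)),
    stringsAsFactors = FALSE
  )
  if (is.null(isis)) failures <- c(failures, "isi: fewer than 2 spikes")
  attr(rec, "failures") <- failures
  rec
}

#' Paired baseline-versus-stimulation comparison of one metric
#'
#' Shapiro-Wilk normality p-values per condition, a paired t-test on the
#' per-unit differences, and mean +/- SD per condition — the group-statistics
#' battery applied to every metric of a cohort.
#'
#' @param baseline,stim per-unit metric values, equal length >= 3, matched by
#'   position (unit i in both vectors is the same unit).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (alternatives refer to `stim - baseline`).
#' @return a list with `n`, `mean_baseline`, `sd_baseline`, `mean_stim`,
#'   `sd_stim`, `mean_diff`, `shapiro_p_baseline`, `shapiro_p_stim`,
#'   `paired_t_stat`, `paired_t_p`.
#' @examples
#' paired_comparison(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 7))
#' @export
paired_comparison <- function(baseline, stim,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  baseline <- as.numeric(baseline)
  stim <- as.numeric(stim)
  if (length(baseline) != length(stim)) {
    stop("`baseline` and `stim` must have equal length (paired design)")
  }
  ok <- stats::complete.cases(baseline, stim)
  baseline <- baseline[ok]
  stim <- stim[ok]
  n <- length(baseline)
  if (n < 3L) stop("paired comparison requires at least 3 complete pairs")
  d <- stim - baseline
  if (stats::sd(d) == 0) {
    stop("degenerate paired test: all per-unit differences are identical (zero variance)")
  }
  sw <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  tt <- stats::t.test(stim, baseline, paired = TRUE, alternative = alternative)
  list(n = n,
       mean_baseline = mean(baseline), sd_baseline = stats::sd(baseline),
       mean_stim = mean(stim), sd_stim = stats::sd(stim),
       mean_diff = mean(d),
       shapiro_p_baseline = sw(baseline), shapiro_p_stim = sw(stim),
       paired_t_stat = unname(tt$statistic), paired_t_p = tt$p.value)
}

#' Unpaired comparison between two groups of units
#'
#' Two-sample t-test between independent groups (e.g. interneurons versus
#' pyramidal cells within one condition).  Welch's unequal-variance test is
#' the default; the pooled-variance test is available.
#'
#' @param x,y metric values for the two groups.
#' @param var_equal use the pooled-variance t-test (default FALSE = Welch).
#' @param alternative passed to [stats::t.test()].
#' @return a list with `t_stat`, `p`, `df`, group means and SDs.
#' @export
unpaired_comparison <- function(x, y, var_equal = FALSE,
                                alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  tt <- stats::t.test(x, y, var.equal = var_equal, alternative = alternative)
  list(t_stat = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_x = mean(x), sd_x = stats::sd(x),
       mean_y = mean(y), sd_y = stats::sd(y))
}

#' Experiment configuration for a synthetic cohort
#'
#' Describes a cohort of units recorded for `duration` seconds in each of two
#' conditions.  Baseline trains come from [generate_baseline_train()];
#' stimulation trains from [generate_entrained_train()] with a per-cell-type
#' coupling ratio.  The defaults mirror a hippocampal CA1 cohort under 50 Hz
#' sinusoidal stimulation: 25 pyramidal cells (coupling ~10%) and 14
#' interneurons (coupling ~65%), strongly correlated cycle skipping under
#' stimulation (`failure_H = 0.8`) and weakly correlated baseline firing.
#'
#' @param n_pyramidal,n_interneuron unit counts per cell type.
#' @param duration record length in seconds per condition.
#' @param stim_frequency stimulation frequency in Hz.
#' @param p_cycle_pyramidal,p_cycle_interneuron per-cycle spike probabilities
#'   under stimulation.
#' @param failure_H Hurst exponent of the cycle-success process under
#'   stimulation.
#' @param phase_jitter_sd spike-time jitter SD (seconds) under stimulation.
#' @param baseline_rate_pyramidal,baseline_rate_interneuron baseline firing
#'   rates (spikes/s).
#' @param baseline_H Hurst exponent of baseline firing fluctuations.
#' @param burst_fraction baseline pyramidal burst-continuation probability.
#' @param stimulation_model `"entrained"` (default) draws stimulation-period
#'   trains from the entrainment model; `"baseline"` draws them from the
#'   baseline generator with an independent seed, giving a null experiment in
#'   which both conditions are identically distributed (type-I calibration).
#' @param seed master seed; per-unit seeds are derived deterministically.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_pyramidal = 25, n_interneuron = 14,
                              duration = 60, stim_frequency = 50,
                              p_cycle_pyramidal = 0.10,
                              p_cycle_interneuron = 0.65,
                              failure_H = 0.8, phase_jitter_sd = 0.001,
                              baseline_rate_pyramidal = 2.5,
                              baseline_rate_interneuron = 9,
                              baseline_H = 0.55, burst_fraction = 0.35,
                              stimulation_model = c("entrained", "baseline"),
                              seed = 1) {
  stimulation_model <- match.arg(stimulation_model)
  stopifnot(n_pyramidal >= 0, n_interneuron >= 0,
            n_pyramidal + n_interneuron >= 3, duration > 0)
  structure(list(n_pyramidal = as.integer(n_pyramidal),
                 n_interneuron = as.integer(n_interneuron),
                 duration = duration, stim_frequency = stim_frequency,
                 p_cycle_pyramidal = p_cycle_pyramidal,
                 p_cycle_interneuron = p_cycle_interneuron,
                 failure_H = failure_H, phase_jitter_sd = phase_jitter_sd,
                 baseline_rate_pyramidal = baseline_rate_pyramidal,
                 baseline_rate_interneuron = baseline_rate_interneuron,
                 baseline_H = baseline_H, burst_fraction = burst_fraction,
                 stimulation_model = stimulation_model,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Deterministic per-unit sub-seed, kept below 2^31.
unit_seed <- function(master, i, k) {
  (as.numeric(master) * 7919 + i * 131 + k) %% 2147483647
}

#' Run a full synthetic cohort experiment
#'
#' For every unit, generates a baseline and a stimulation train, computes the
#' complete metric family with [unit_metrics()], and assembles group
#' summaries and paired statistics per (cell type, metric).  Units failing a
#' metric are excluded pairwise for that metric; the per-test `n` reflects
#' the retained pairs.  Fully reproducible from `(config, seed)`.
#'
#' @param config an [experiment_config()].
#' @param alternative alternative hypothesis for the paired tests
#'   (`"two.sided"` default; `"greater"` tests stimulation > baseline).
#' @return a `cohort_result`: list with `per_unit` (data.frame),
#'   `group_summaries` (data.frame of mean/SD per cell type, condition and
#'   metric), `tests` (data.frame of paired statistics), `failures`
#'   (character log), and `config`.
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_config(n_pyramidal = 6, n_interneuron = 4,
#'                                         duration = 30, seed = 1))
#' res$tests
#' }
#' @export
run_experiment <- function(config = experiment_config(),
                           alternative = "two.sided") {
  stopifnot(inherits(config, "experiment_config"))
  units <- rbind(
    if (config$n_pyramidal > 0)
      data.frame(i = seq_len(config$n_pyramidal), cell_type = "pyramidal"),
    if (config$n_interneuron > 0)
      data.frame(i = seq_len(config$n_interneuron), cell_type = "interneuron")
  )
  units$unit_id <- sprintf("%s_%02d", substr(units$cell_type, 1, 3), units$i)
  per_unit <- list()
  failures <- character(0)
  for (j in seq_len(nrow(units))) {
    ct <- units$cell_type[j]
    uid <- units$unit_id[j]
    base_rate <- if (ct == "pyramidal") config$baseline_rate_pyramidal
                 else config$baseline_rate_interneuron
    p_cycle <- if (ct == "pyramidal") config$p_cycle_pyramidal
               else config$p_cycle_interneuron
    tr_base <- generate_baseline_train(
      cell_type = ct, rate = base_rate, duration = config$duration,
      correlation_H = config$baseline_H,
      burst_fraction = config$burst_fraction,
      seed = unit_seed(config$seed, j, 1L), unit_id = uid)
    tr_stim <- if (config$stimulation_model == "entrained") {
      generate_entrained_train(
        entrainment_config(stim_frequency = config$stim_frequency,
                           per_cycle_probability = p_cycle,
                           failure_H = config$failure_H,
                           phase_jitter_sd = config$phase_jitter_sd,
                           duration = config$duration,
                           seed = unit_seed(config$seed, j, 2L)),
        cell_type = ct, unit_id = uid)
    } else {
      # null experiment: the "stimulation" train is a fresh baseline draw
      tr <- generate_baseline_train(
        cell_type = ct, rate = base_rate, duration = config$duration,
        correlation_H = config$baseline_H,
        burst_fraction = config$burst_fraction,
        seed = unit_seed(config$seed, j, 2L), unit_id = uid)
      tr$condition <- "stimulation"
      tr
    }
    for (tr in list(tr_base, tr_stim)) {
      rec <- unit_metrics(tr)
      fl <- attr(rec, "failures")
      if (length(fl)) {
        failures <- c(failures, paste0(uid, " [", tr$condition, "] ", fl))
      }
      per_unit[[length(per_unit) + 1L]] <- rec
    }
  }
  per_unit <- do.call(rbind, per_unit)
  rownames(per_unit) <- NULL
  metrics <- c("rate", "cv", "apen", "frac_0_8ms", "frac_19_21ms", "alpha", "H")

  summ <- do.call(rbind, lapply(split(per_unit,
                                      list(per_unit$cell_type,
                                           per_unit$condition), drop = TRUE),
    function(g) {
      do.call(rbind, lapply(metrics, function(m) {
        v <- g[[m]][!is.na(g[[m]])]
        data.frame(cell_type = g$cell_type[1L], condition = g$condition[1L],
                   metric = m, n = length(v), mean = mean(v),
                   sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(summ) <- NULL

  tests <- list()
  n_paired_total <- 0L
  for (ct in unique(per_unit$cell_type)) {
    sub <- per_unit[per_unit$cell_type == ct, ]
    wide_b <- sub[sub$condition == "baseline", ]
    wide_s <- sub[sub$condition == "stimulation", ]
    common <- intersect(wide_b$unit_id, wide_s$unit_id)
    n_paired_total <- max(n_paired_total, length(common))
    for (m in metrics) {
      b <- wide_b[[m]][match(common, wide_b$unit_id)]
      s <- wide_s[[m]][match(common, wide_s$unit_id)]
      res <- tryCatch(paired_comparison(b, s, alternative = alternative),
                      error = function(e) {
                        failures <<- c(failures,
                                       paste0("paired test ", ct, "/", m, ": ",
                                              conditionMessage(e)))
                        NULL
                      })
      if (!is.null(res)) {
        tests[[length(tests) + 1L]] <-
          data.frame(cell_type = ct, metric = m, n = res$n,
                     mean_baseline = res$mean_baseline,
                     sd_baseline = res$sd_baseline,
                     mean_stim = res$mean_stim, sd_stim = res$sd_stim,
                     shapiro_p_baseline = res$shapiro_p_baseline,
                     shapiro_p_stim = res$shapiro_p_stim,
                     paired_t_stat = res$paired_t_stat,
                     paired_t_p = res$paired_t_p,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (n_paired_total < 3L) stop("fewer than 3 paired units; experiment failed")
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  rownames(tests) <- NULL
  structure(list(per_unit = per_unit, group_summaries = summ, tests = tests,
                 failures = failures, config = config),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  n_units <- length(unique(x$per_unit$unit_id))
  cat(sprintf("<cohort_result> %d units x 2 conditions\n", n_units))
  if (!is.null(x$tests)) {
    df <- x$tests
    cat(sprintf("  %-12s %-12s baseline %9.3f +/- %.3f  stim %9.3f +/- %.3f  p = %.3g\n",
                df$cell_type, df$metric, df$mean_baseline, df$sd_baseline,
                df$mean_stim, df$sd_stim, df$paired_t_p), sep = "")
  }
  if (length(x$failures)) {
    cat("  ", length(x$failures), "per-unit metric failures (see $failures)\n")
  }
  invisible(x)
}

#' Write cohort results to a directory
#'
#' Emits `per_unit.csv`, `summary.csv` and `tests.json` under `dir`.
#'
#' @param result a `cohort_result`.
#' @param dir output directory (created if missing).
#' @export
write_cohort_result <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$per_unit, file.path(dir, "per_unit.csv"),
                   row.names = FALSE)
  utils::write.csv(result$group_summaries, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$tests, file.path(dir, "tests.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
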