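#' Run the full pressure-flow regulation analysis on a recording
#'
#' Detects beats, then dispatches every annotated event to its analysis
#' stage: each `bolus_*` event yields a hyperemia result (baseline flow,
#' hyperemic flow and pressure, CFR, HMR, classification), and a
#' `ramp_start`/`ramp_end` pair yields the binned autoregulation curve with
#' its two-segment breakpoint fit. Replicate bolus results are reported
#' individually and as per-drug means of the per-replicate indices. Events
#' that cannot be processed are never dropped silently: each failure becomes
#' a warning naming its stage.
#'
#' @param recording A `"coro_recording"` with at least one bolus or ramp
#'   annotation.
#' @param expected_rate Approximate heart rate for beat detection, beats/min.
#' @param bin_width Pressure bin width for the autoregulation curve, mmHg.
#' @param min_segment Minimum bins per regression segment.
#' @param weighted Weight the segment regressions by bin counts?
#' @param search_window Post-bolus search window length, s.
#' @param seed Optional seed recorded in the report metadata.
#' @return A list of class `"analysis_report"` with `metadata`, `hyperemia`
#'   (data frame of per-replicate indices), `hyperemia_means` (per-drug
#'   means), `autoregulation` (a `"breakpoint_fit"` or `NULL`), and
#'   `warnings`.
#' @export
#' @examples
#' rec <- generate_experiment(coro_config(seed = 3))
#' rep <- run_pipeline(rec)
#' rep$hyperemia_means
run_pipeline <- function(recording, expected_rate = 85, bin_width = 5,
                         min_segment = 3, weighted = FALSE,
                         search_window = 60, seed = NULL) {
  stopifnot(inherits(recording, "coro_recording"))
  ann <- recording$annotations
  is_event <- ann$kind %in% c("bolus_adenosine", "bolus_bradykinin",
                              "ramp_start")
  if (!any(is_event)) stop("recording carries no bolus or ramp annotation")

  series <- detect_beats(recording, expected_rate = expected_rate)
  warnings <- character(0)
  note <- function(stage, msg) {
    warnings <<- c(warnings, sprintf("%s: %s", stage, msg))
  }

  ann <- ann[order(ann$onset_s), ]
  boluses <- ann[grepl("^bolus_", ann$kind), , drop = FALSE]
  rows <- list()
  rep_counter <- c(adenosine = 0L, bradykinin = 0L)
  for (i in seq_len(nrow(boluses))) {
    ev <- boluses[i, ]
    drug <- sub("^bolus_", "", ev$kind)
    rep_counter[drug] <- rep_counter[drug] + 1L
    later <- ann$onset_s[ann$onset_s > ev$onset_s + 1e-9]
    nxt <- if (length(later)) min(later) else Inf
    res <- tryCatch(
      analyze_bolus(series, ev$onset_s, drug = drug,
                    search_window = search_window, next_event_onset = nxt),
      error = function(e) {
        note("hyperemia", sprintf("%s replicate %d at %.1f s failed: %s",
                                  drug, rep_counter[drug], ev$onset_s,
                                  conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <- data.frame(
        drug = drug, replicate = rep_counter[[drug]],
        baseline_flow = res$baseline_flow,
        hyperemic_flow = res$hyperemic_flow,
        hyperemic_pressure = res$hyperemic_pressure,
        cfr = res$cfr, hmr = res$hmr,
        classification = res$classification,
        stringsAsFactors = FALSE)
    }
  }
  hyper <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(0), replicate = integer(0),
               baseline_flow = numeric(0), hyperemic_flow = numeric(0),
               hyperemic_pressure = numeric(0), cfr = numeric(0),
               hmr = numeric(0), classification = character(0))

  means <- NULL
  if (nrow(hyper)) {
    num_cols <- c("baseline_flow", "hyperemic_flow", "hyperemic_pressure",
                  "cfr", "hmr")
    means <- do.call(rbind, lapply(split(hyper, hyper$drug), function(d) {
      cbind(data.frame(drug = d$drug[1], n_replicates = nrow(d)),
            as.data.frame(as.list(colMeans(d[num_cols]))))
    }))
    rownames(means) <- NULL
  }

  auto <- NULL
  rs <- ann[ann$kind == "ramp_start", , drop = FALSE]
  re <- ann[ann$kind == "ramp_end", , drop = FALSE]
  if (nrow(rs)) {
    if (nrow(re) == 0) {
      note("autoregulation", "ramp_start without ramp_end annotation")
    } else {
      auto <- withCallingHandlers(
        tryCatch(
          analyze_ramp(series, rs$onset_s[1], re$onset_s[1],
                       bin_width = bin_width, min_segment = min_segment,
                       weighted = weighted),
          error = function(e) {
            note("autoregulation", conditionMessage(e))
            NULL
          }),
        warning = function(w) {
          note("autoregulation", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  }

  structure(list(
    metadata = list(
      package_version = as.character(utils::packageVersion("cororeg")),
      seed = seed,
      n_beats = nrow(series),
      expected_rate = expected_rate,
      bin_width = bin_width,
      min_segment = min_segment,
      weighted = weighted,
      search_window = search_window
    ),
    hyperemia = hyper,
    hyperemia_means = means,
    autoregulation = auto,
    warnings = warnings
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  %d beat(s) analyzed; %d hyperemia result(s)\n",
              x$metadata$n_beats, nrow(x$hyperemia)))
  if (!is.null(x$hyperemia_means)) {
    print(x$hyperemia_means, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$autoregulation)) print(x$autoregulation)
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes the report with `hyperemia` as a record array and
#' `autoregulation` as `{bins, ischemic, plateau, breakpoint_pressure,
#' breakpoint_flow, score, in_range}`.
#'
#' @param report An `"analysis_report"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  auto <- report$autoregulation
  auto_json <- if (is.null(auto)) NULL else list(
    bins = as.data.frame(auto$bins),
    ischemic = auto$ischemic[c("slope", "intercept", "r_squared", "n_points")],
    plateau = auto$plateau[c("slope", "intercept", "r_squared", "n_points")],
    breakpoint_pressure = auto$breakpoint_pressure,
    breakpoint_flow = auto$breakpoint_flow,
    score = auto$score,
    in_range = auto$in_range
  )
  jsonlite::write_json(list(
    metadata = report$metadata,
    hyperemia = report$hyperemia,
    hyperemia_means = report$hyperemia_means,
    autoregulation = auto_json,
    warnings = report$warnings
  ), path, auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}

#' Monte-Carlo recovery of the autoregulatory breakpoint
#'
#' Draws true breakpoints uniformly over the observed physiological range
#' (42-55 mmHg), simulates a balloon ramp with default per-beat noise for
#' each, runs beat detection and the two-segment fit, and reports estimated
#' against true breakpoints.
#'
#' @param n Number of simulations.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param config Base configuration (breakpoint is overridden per run).
#' @param bp_range Range of true breakpoints, mmHg.
#' @return Data frame: `true_bp`, `estimated_bp`, `abs_error`, `in_range`.
#' @export
breakpoint_recovery_study <- function(n = 100, seed = 1,
                                      config = coro_config(),
                                      bp_range = c(42, 55)) {
  truths <- withr::with_seed(seed, stats::runif(n, bp_range[1], bp_range[2]))
  est <- numeric(n)
  inr <- logical(n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$breakpoint_pressure <- truths[i]
    cfg$seed <- as.integer((seed * 1009 + i * 7919) %% 2147483629)
    rec <- simulate_ramp(cfg, seed = cfg$seed)
    beats <- detect_beats(rec, expected_rate = cfg$heart_rate)
    fit <- suppressWarnings(
      analyze_ramp(beats, 0, cfg$ramp_duration + 1))
    est[i] <- fit$breakpoint_pressure
    inr[i] <- fit$in_range
  }
  data.frame(true_bp = truths, estimated_bp = est,
             abs_error = abs(est - truths), in_range = inr)
}

#' Monte-Carlo recovery of coronary flow reserve
#'
#' For each hyperemic gain, simulates seeded adenosine boluses with default
#' per-beat noise, runs beat detection and the bolus analysis, and reports
#' the estimated CFR against the configured gain (the true CFR of the
#' generative model).
#'
#' @param gains True hyperemic gains to test.
#' @param n_per_gain Simulations per gain.
#' @param seed Master seed.
#' @param config Base configuration (gain is overridden per run).
#' @return Data frame: `gain`, `run`, `cfr_hat`.
#' @export
cfr_recovery_study <- function(gains = c(2.0, 2.5, 3.0), n_per_gain = 34,
                               seed = 1, config = coro_config()) {
  out <- vector("list", length(gains))
  for (g in seq_along(gains)) {
    cfr_hat <- numeric(n_per_gain)
    for (i in seq_len(n_per_gain)) {
      cfg <- config
      cfg$hyperemic_gain <- gains[g]
      cfg$seed <- as.integer((seed * 104729 + g * 9973 + i * 211) %% 2147483629)
      rec <- simulate_bolus(cfg, duration = 80, onset = 15, seed = cfg$seed)
      beats <- detect_beats(rec, expected_rate = cfg$heart_rate)
      res <- analyze_bolus(beats, 15, drug = "adenosine",
                           search_window = 60)
      cfr_hat[i] <- res$cfr
    }
    out[[g]] <- data.frame(gain = gains[g], run = seq_len(n_per_gain),
                           cfr_hat = cfr_hat)
  }
  do.call(rbind, out)
}
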