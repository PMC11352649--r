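#' Pipeline orchestration and file I/O
#'
#' `run_simulate()` writes a synthetic cohort to disk as plain-text CSV
#' (events, taps, ground truth, EEG) with a hash manifest; `run_analyze()`
#' executes the full analysis chain — behavior, SDT, ER-DBA, ERP,
#' statistics — on an in-memory cohort or a simulated directory and
#' returns (optionally writes) a result bundle.
#'
#' @name cli_io
NULL

maybe_reject <- function(ep, k) {
  if (nrow(ep$epochs) >= 3) reject_artifact_epochs(ep, k = k) else ep
}

#' Concatenate epoch sets (same time axis)
#'
#' @param sets list of `epoch_set` objects with identical time axes
#' @return a single pooled `epoch_set`
#' @export
bind_epoch_sets <- function(sets) {
  sets <- Filter(function(s) !is.null(s) && nrow(s$epochs) > 0, sets)
  if (length(sets) == 0) stop("no epochs to bind")
  ref <- sets[[1]]
  for (s in sets[-1]) stopifnot(isTRUE(all.equal(s$time_ms, ref$time_ms)))
  structure(list(
    epochs = do.call(rbind, lapply(sets, `[[`, "epochs")),
    time_ms = ref$time_ms,
    category = unlist(lapply(sets, `[[`, "category")),
    rejected = unlist(lapply(sets, `[[`, "rejected")),
    fs = ref$fs,
    n_dropped = sum(vapply(sets, `[[`, numeric(1), "n_dropped"))
  ), class = "epoch_set")
}

#' Write a synthetic cohort to disk
#'
#' Layout: `events_task{1,2}.csv`, and per participant
#' `task{1,2}/P##_taps.csv`, `task{1,2}/P##_truth.csv`,
#' `task{1,2}/P##_eeg.csv` (time_ms, O1, O2, Cz). Event-channel tap times
#' are quantized to the 512-Hz marker resolution on export. A
#' `manifest.csv` of md5 hashes is written last.
#'
#' @param config configuration list (see [default_config()])
#' @param seed integer seed
#' @param outdir output directory (created)
#' @param eeg write EEG files too (default TRUE)
#' @return the cohort (invisibly), with the manifest as attribute
#' @export
run_simulate <- function(config = default_config(), seed = 1, outdir,
                         eeg = TRUE) {
  validate_config(config)
  cohort <- generate_cohort(config, seed = seed, eeg = eeg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (task in c("task1", "task2")) {
    tk <- cohort[[task]]
    if (is.null(tk)) next
    f <- file.path(outdir, paste0("events_", task, ".csv"))
    write_events_csv(tk$seq, f); files <- c(files, f)
    tdir <- file.path(outdir, task)
    dir.create(tdir, showWarnings = FALSE)
    for (p in tk$participants) {
      f <- file.path(tdir, paste0(p$id, "_taps.csv"))
      utils::write.csv(
        data.frame(tap_ms = round(p$taps_ms * 512 / 1000) * 1000 / 512),
        f, row.names = FALSE)
      files <- c(files, f)
      f <- file.path(tdir, paste0(p$id, "_truth.csv"))
      utils::write.csv(p$truth, f, row.names = FALSE, na = "")
      files <- c(files, f)
      if (eeg && !is.null(p$rec)) {
        f <- file.path(tdir, paste0(p$id, "_eeg.csv"))
        write_recording_csv(p$rec, f)
        files <- c(files, f)
      }
    }
  }
  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  attr(cohort, "manifest") <- manifest
  invisible(cohort)
}

#' Load a simulated cohort directory
#'
#' @param datadir directory written by [run_simulate()]
#' @return a `synthetic_cohort`-like list (without profiles)
#' @export
read_cohort <- function(datadir) {
  out <- list(config = NULL, seed = NA)
  for (task in c("task1", "task2")) {
    f <- file.path(datadir, paste0("events_", task, ".csv"))
    if (!file.exists(f)) next
    sq <- annotate_lags(read_events_csv(f))
    tdir <- file.path(datadir, task)
    ids <- unique(sub("_.*$", "", basename(list.files(tdir, pattern = "_taps\\.csv$"))))
    participants <- lapply(sort(ids), function(id) {
      p <- list(id = id,
                taps_ms = utils::read.csv(file.path(tdir, paste0(id, "_taps.csv")))$tap_ms)
      tf <- file.path(tdir, paste0(id, "_truth.csv"))
      if (file.exists(tf)) p$truth <- utils::read.csv(tf, stringsAsFactors = FALSE)
      ef <- file.path(tdir, paste0(id, "_eeg.csv"))
      if (file.exists(ef)) {
        p$rec <- read_recording_csv(ef)
        p$markers <- list(onsets_ms = sq$onset_ms, taps_ms = p$taps_ms)
      }
      p
    })
    out[[task]] <- list(seq = sq, participants = participants)
  }
  class(out) <- "synthetic_cohort"
  out
}

#' Read an analysis configuration from JSON or YAML
#'
#' The file may specify any subset of the configuration tree; missing
#' entries fall back to [default_config()] values.
#'
#' @param path a .json, .yaml or .yml file
#' @return a validated configuration list
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: ", ext)
  }
  validate_config(utils::modifyList(default_config(), user))
}

classify_participant <- function(sq, taps_ms, pid, rt_window = c(-500, 500)) {
  matched <- match_taps_to_pulses(sq, taps_ms, window = rt_window)
  real_rt <- matched$rt_ms[matched$slot_index %in% sq$slot_index[sq$kind == "real"]]
  boundary <- 100
  dec <- NULL
  if (length(real_rt) >= 10) {
    dec <- decompose_dual_lobe(kde_density(real_rt))
    if (isTRUE(dec$bimodal)) boundary <- dec$antimode
  }
  rec <- classify_trials(sq, matched, mode_boundary = boundary,
                         participant = pid)
  list(records = rec, decomposition = dec, boundary = boundary)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: tap matching and trial classification per participant
#' (FH/CH boundary from the per-participant KDE antimode, fallback
#' +100 ms); pooled and lag-locked RT profiles with dual-lobe
#' decomposition; per-participant rates and the error-rate-versus-RT
#' regression; SDT lag profiles and FAR correlations; pooled ER-DBA traces
#' per behavioral category with ERD/ERS testing and envelope features;
#' pooled Cz ERP traces with component detection and omission-reversal
#' scoring; summary statistics (RT-by-lag ANOVA with Holm-Sidak, between-
#' task DBA t-test with power). Stages lacking their inputs (e.g. no EEG)
#' are skipped with a note.
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()])
#' @param config pipeline configuration (defaults from the cohort, else
#'   [default_config()])
#' @param outdir if given, metrics JSON and trace CSVs are written there
#' @return a result bundle list
#' @export
run_analyze <- function(cohort, config = NULL, outdir = NULL) {
  if (is.null(config)) config <- cohort$config
  if (is.null(config)) config <- default_config()
  pp <- config$pipeline
  notes <- character(0)
  res <- list(provenance = list(seed = cohort$seed,
                                n_participants = length(cohort$task2$participants),
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  ## ---- behavior (Task 2) ----
  sq2 <- cohort$task2$seq
  cls <- lapply(cohort$task2$participants, function(p) {
    classify_participant(sq2, p$taps_ms, p$id, rt_window = pp$rt_window)
  })
  names(cls) <- vapply(cohort$task2$participants, `[[`, character(1), "id")
  records <- do.call(rbind, lapply(cls, `[[`, "records"))
  pooled_real_rt <- records$rt_ms[records$kind == "real" & !is.na(records$rt_ms)]
  pooled_miss_rt <- records$rt_ms[records$kind == "missing" & !is.na(records$rt_ms)]
  kde_real <- kde_density(pooled_real_rt)
  decomp_pooled <- decompose_dual_lobe(kde_real)
  kde_missing <- if (length(pooled_miss_rt) >= 2) kde_density(pooled_miss_rt) else NULL
  rates <- lapply(names(cls), function(pid) {
    c(list(participant = pid),
      participant_rates(cls[[pid]]$records, cls[[pid]]$decomposition))
  })
  rates_df <- do.call(rbind, lapply(rates, function(r) as.data.frame(r)))
  # error rate vs mean RT of erroneous taps, across participants
  fa_rt <- vapply(names(cls), function(pid) {
    r <- cls[[pid]]$records
    m <- r$rt_ms[r$category == "FA"]
    if (length(m)) mean(m) else NA_real_
  }, numeric(1))
  err_vs_rt <- try_regression(fa_rt, rates_df$FAR)
  res$behavior <- list(records = records,
                       kde_real = kde_real, kde_missing = kde_missing,
                       decomposition = decomp_pooled,
                       lag_profile = lag_locked_profile(records),
                       rates = rates_df,
                       error_rate_vs_fa_rt = err_vs_rt)

  ## ---- SDT ----
  res$sdt <- sdt_lag_profile(records)

  ## ---- lag ANOVA on per-participant mean RTs ----
  lag_set <- -2:8
  per_part_lag <- lapply(names(cls), function(pid) {
    lag_locked_profile(cls[[pid]]$records, lags = lag_set)$mean_rt
  })
  lag_mat <- do.call(rbind, per_part_lag)
  groups <- lapply(seq_along(lag_set), function(j) lag_mat[, j])
  names(groups) <- lag_set
  groups <- Filter(function(g) sum(!is.na(g)) >= 2, groups)
  rt_anova <- if (length(groups) >= 2) one_way_anova(groups) else NULL
  pairwise_p <- NULL
  if (!is.null(rt_anova) && "0" %in% names(groups)) {
    others <- setdiff(names(groups), "0")
    pvals <- vapply(others, function(L) {
      two_sample_ttest_with_power(groups[["0"]], groups[[L]], alpha = pp$alpha)$p
    }, numeric(1))
    hs <- holm_sidak(pvals, alpha = pp$alpha)
    pairwise_p <- data.frame(lag = others, p = pvals, reject = hs$reject)
  }
  res$stats <- list(rt_by_lag_anova = rt_anova, rt_vs_lag0 = pairwise_p)

  ## ---- ER-DBA ----
  has_eeg <- !is.null(cohort$task2$participants[[1]]$rec)
  if (has_eeg) {
    dba_pool <- pool_dba_epochs(cohort$task2, cls, window = pp$epoch_window)
    traces <- list()
    for (cat in names(dba_pool)) {
      ep <- maybe_reject(dba_pool[[cat]], k = pp$reject_k)
      traces[[cat]] <- grand_average(ep, baseline_window = pp$dba_baseline)
      attr(traces[[cat]], "uncorrected") <- grand_average(ep, baseline_window = NULL)
    }
    # condition contrasts as in the RT-sign and tap-vs-avoid comparisons
    erd_ers <- list()
    pairs <- list(hit_neg = "hit_pos", hit_pos = "hit_neg",
                  FA = "CR", CR = "FA")
    for (cat in intersect(names(pairs), names(dba_pool))) {
      ep <- maybe_reject(dba_pool[[cat]], k = pp$reject_k)
      other <- pairs[[cat]]
      ref <- if (other %in% names(dba_pool)) {
        maybe_reject(dba_pool[[other]], k = pp$reject_k)
      } else NULL
      erd_ers[[cat]] <- classify_erd_ers(ep, test_window = c(-200, 400),
                                         baseline_window = c(-900, -500),
                                         alpha = pp$alpha, ref = ref)
    }
    env <- if ("hit_neg" %in% names(traces)) {
      envelope_normalize(attr(traces$hit_neg, "uncorrected"))
    } else NULL
    features <- lapply(traces, function(tr) {
      detect_extrema_features(tr, window = c(-1000, 1000))
    })
    # between-task mean DBA comparison on per-participant index means
    dba_ttest <- NULL
    if (!is.null(cohort$task1)) {
      m1 <- vapply(cohort$task1$participants, function(p)
        mean(dba_index_series(p$rec)$data), numeric(1))
      m2 <- vapply(cohort$task2$participants, function(p)
        mean(dba_index_series(p$rec)$data), numeric(1))
      dba_ttest <- two_sample_ttest_with_power(m1, m2, alpha = pp$alpha)
    }
    res$dba <- list(traces = traces, erd_ers = erd_ers, envelope = env,
                    features = features, task_ttest = dba_ttest)
  } else {
    notes <- c(notes, "EEG absent: ER-DBA stage skipped")
  }

  ## ---- ERP ----
  if (has_eeg && "Cz" %in% cohort$task2$participants[[1]]$rec$channels) {
    erp_pool <- pool_erp_epochs(cohort$task2, cls, window = pp$epoch_window)
    erp_tr <- list()
    for (cat in names(erp_pool)) {
      ep <- maybe_reject(erp_pool[[cat]], k = pp$reject_k)
      erp_tr[[cat]] <- grand_average(ep, baseline_window = pp$erp_baseline)
    }
    comps <- if ("real" %in% names(erp_tr)) detect_components(erp_tr$real) else NULL
    omission_comps <- lapply(erp_tr[intersect(c("FA", "CR"), names(erp_tr))],
      detect_components,
      windows = list(oN1 = c(150, 250), oP2 = c(300, 480)))
    reversal <- if (all(c("FA", "real") %in% names(erp_tr))) {
      omission_reversal_score(erp_tr$FA, erp_tr$real, window = c(100, 500))
    } else NULL
    res$erp <- list(traces = erp_tr, components = comps,
                    omission_components = omission_comps,
                    reversal_score = reversal)
  } else if (has_eeg) {
    notes <- c(notes, "Cz absent: ERP stage skipped")
  }

  res$notes <- notes
  if (!is.null(outdir)) write_result_bundle(res, outdir)
  res
}

pool_dba_epochs <- function(task, cls, window = c(-1000, 8000)) {
  sets <- list(hit = list(), hit_neg = list(), hit_pos = list(),
               miss = list(), CR = list(), FA = list())
  for (i in seq_along(task$participants)) {
    p <- task$participants[[i]]
    rec <- cls[[p$id]]$records
    dba <- dba_index_series(p$rec)
    onset <- task$seq$onset_ms
    cats <- list(
      hit = onset[rec$category %in% c("CH", "FH")],
      hit_neg = onset[rec$category %in% c("CH", "FH") & rec$rt_ms < 0],
      hit_pos = onset[rec$category %in% c("CH", "FH") & rec$rt_ms >= 0],
      miss = onset[rec$category == "miss"],
      CR = onset[rec$category == "CR"],
      FA = onset[rec$category == "FA"]
    )
    for (cat in names(cats)) {
      if (length(cats[[cat]]) == 0) next
      sets[[cat]] <- c(sets[[cat]],
                       list(epoch_stream(dba, cats[[cat]],
                                         t_min = window[1], t_max = window[2])))
    }
  }
  sets <- Filter(function(s) length(s) > 0, sets)
  lapply(sets, bind_epoch_sets)
}

pool_erp_epochs <- function(task, cls, window = c(-1000, 8000)) {
  sets <- list(real = list(), CR = list(), FA = list())
  for (i in seq_along(task$participants)) {
    p <- task$participants[[i]]
    rec <- cls[[p$id]]$records
    cz <- eeg_recording(p$rec$data[, "Cz", drop = FALSE], "Cz",
                        p$rec$fs, p$rec$start_ms)
    filt <- bandpass_filter(cz, 0.01, 45, order = 3)
    onset <- task$seq$onset_ms
    cats <- list(
      real = onset[rec$category %in% c("CH", "FH")],   # responded real pulses
      CR = onset[rec$category == "CR"],
      FA = onset[rec$category == "FA"]
    )
    for (cat in names(cats)) {
      if (length(cats[[cat]]) == 0) next
      sets[[cat]] <- c(sets[[cat]],
                       list(epoch_stream(filt, cats[[cat]],
                                         t_min = window[1], t_max = window[2])))
    }
  }
  sets <- Filter(function(s) length(s) > 0, sets)
  lapply(sets, bind_epoch_sets)
}

write_result_bundle <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  metrics <- list(
    provenance = res$provenance,
    decomposition = res$behavior$decomposition[
      c("peak_rt_pro", "peak_rt_rea", "antimode", "P_F", "P_C",
        "weight_pro", "bimodal")],
    rates = res$behavior$rates,
    lag_profile = res$behavior$lag_profile,
    sdt_per_lag = res$sdt$per_lag,
    rt_by_lag_anova = res$stats$rt_by_lag_anova,
    erp_reversal_score = res$erp$reversal_score,
    notes = res$notes
  )
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  dump_traces <- function(traces, prefix) {
    for (cat in names(traces)) {
      tr <- traces[[cat]]
      utils::write.csv(data.frame(time_ms = tr$time_ms, mean = tr$mean,
                                  sem = tr$sem, n = tr$n),
                       file.path(outdir, sprintf("%s_%s.csv", prefix, cat)),
                       row.names = FALSE)
    }
  }
  if (!is.null(res$dba)) dump_traces(res$dba$traces, "erdba_trace")
  if (!is.null(res$erp)) dump_traces(res$erp$traces, "erp_trace")
  invisible(outdir)
}
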