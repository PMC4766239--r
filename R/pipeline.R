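# End-to-end pipeline: simulate -> preprocess -> markers -> severity/factors.

#' Pipeline configuration
#'
#' Aggregates every tunable of the analysis with defaults equal to the study
#' parameters: FIR order 340 with 2/12/15 Hz border frequencies, 4-s
#' segments with 2-s overlap, Parzen truncation c = 255 on a 1024-point
#' grid, delta/theta/alpha/beta0 bands, 10 x 10 cMI histogram, Bonferroni
#' family of 8 markers, MMSE regime boundary 21 and 2 common factors. All
#' values are validated at construction.
#'
#' @param cohort a [cohort_spec()].
#' @param artifacts an [artifact_spec()].
#' @param phase `"resting"` or `"active"`.
#' @param duration_s optional recording-duration override (seconds).
#' @param markers marker subset to compute.
#' @param bands frequency bands for the frequency-domain markers.
#' @param spectral a [spectral_config()].
#' @param rate sampling rate (samples/s).
#' @param fir_order,highpass,eog_lowpass,lowpass preprocessing filters.
#' @param length_s,overlap_s segmentation windows (s).
#' @param ar_max_order maximum AR order for Granger fits.
#' @param cmi_normalization `"maes"` or `"max"`.
#' @param regime_cut MMSE regime boundary.
#' @param bonferroni_m marker-family size for the Bonferroni threshold.
#' @param n_factors common-factor count.
#' @param factor_pair cluster pair (e.g. `"Anterior-TemporalLeft"`) whose
#'   marker set feeds the factor analysis.
#' @param stages subset of `c("simulate", "preprocess", "markers",
#'   "severity", "factors")` to run.
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            artifacts = artifact_spec(),
                            phase = c("resting", "active"),
                            duration_s = NULL,
                            markers = MARKER_NAMES,
                            bands = names(frequency_bands()),
                            spectral = spectral_config(),
                            rate = 256,
                            fir_order = 340, highpass = 2,
                            eog_lowpass = 12, lowpass = 15,
                            length_s = 4, overlap_s = 2,
                            ar_max_order = 10,
                            cmi_normalization = c("maes", "max"),
                            regime_cut = 21,
                            bonferroni_m = 8,
                            n_factors = 2,
                            factor_pair = "Anterior-TemporalLeft",
                            stages = c("simulate", "preprocess", "markers",
                                       "severity", "factors"),
                            out_dir = NULL) {
  phase <- match.arg(phase)
  cmi_normalization <- match.arg(cmi_normalization)
  markers <- match.arg(markers, MARKER_NAMES, several.ok = TRUE)
  stages <- match.arg(stages, c("simulate", "preprocess", "markers",
                                "severity", "factors"), several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(artifacts, "artifact_spec"),
            inherits(spectral, "spectral_config"))
  if (highpass >= eog_lowpass || eog_lowpass > 15 || lowpass >= rate / 2)
    stop("filter borders must satisfy highpass < eog_lowpass <= 15 and lowpass < Nyquist")
  if (overlap_s >= length_s) stop("`overlap_s` must be below `length_s`")
  if (fir_order %% 2 != 0) stop("`fir_order` must be even")
  structure(list(cohort = cohort, artifacts = artifacts, phase = phase,
                 duration_s = duration_s, markers = markers, bands = bands,
                 spectral = spectral, rate = rate, fir_order = fir_order,
                 highpass = highpass, eog_lowpass = eog_lowpass,
                 lowpass = lowpass, length_s = length_s,
                 overlap_s = overlap_s, ar_max_order = ar_max_order,
                 cmi_normalization = cmi_normalization,
                 regime_cut = regime_cut, bonferroni_m = bonferroni_m,
                 n_factors = n_factors, factor_pair = factor_pair,
                 stages = stages, out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-subject seed below 2^31
subject_seed <- function(base, i) (as.numeric(base) * 10007 + i) %% 2147483647

#' Preprocess one subject and compute the marker table
#'
#' Convenience driver for a single subject: simulate (or accept) a recording,
#' run [preprocess_pipeline()] and [subject_markers()].
#'
#' @param subject cohort row.
#' @param config a [pipeline_config()].
#' @param rec optional pre-existing [eeg_recording()]; simulated when NULL.
#' @param seed simulation seed.
#' @return Marker data.frame (see [subject_markers()]).
#' @export
process_subject <- function(subject, config = pipeline_config(), rec = NULL,
                            seed = 1L) {
  if (is.null(rec))
    rec <- generate_recording(subject, config$phase, config$artifacts,
                              seed = seed, spec = config$cohort,
                              duration_s = config$duration_s,
                              rate = config$rate)
  segs <- preprocess_pipeline(rec, highpass = config$highpass,
                              lowpass = config$lowpass,
                              eog_lowpass = config$eog_lowpass,
                              fir_order = config$fir_order,
                              length_s = config$length_s,
                              overlap_s = config$overlap_s)
  subject_markers(segs, markers = config$markers, bands = config$bands,
                  config = config$spectral,
                  ar_max_order = config$ar_max_order,
                  cmi_normalization = config$cmi_normalization)
}

# subjects x keys value matrix for one set of selected (marker, pair, band,
# direction, combo) rows
marker_matrix <- function(tbl, selection, cohort) {
  cols <- lapply(seq_len(nrow(selection)), function(i) {
    k <- selection[i, c("marker", "pair", "band", "direction", "combo")]
    s <- merge(tbl, k)
    s$value[match(cohort$id, s$subject)]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste(selection$marker, selection$band, selection$direction,
                       sep = ".")
  rownames(m) <- cohort$id
  m
}

#' Run the full analysis
#'
#' Executes the configured stages: cohort simulation, per-subject recording
#' generation and preprocessing, marker computation, cohort-level best-combo
#' selection with quadratic severity regression and Bonferroni flags,
#' Mann-Whitney regime tests, and common-factor analysis of one cluster
#' pair's markers. When `config$out_dir` is set, writes `cohort.csv`,
#' `markers.tsv` (all candidate rows), `selection.tsv`, `results.json` and
#' `log.txt` (configuration echo with seeds, stage timings and counts).
#'
#' @param config a [pipeline_config()].
#' @return List with `cohort`, `markers` (long table over subjects),
#'   `selection` (best-combo table with R^2), `severity` (per-key regression
#'   summaries), `regime` (Mann-Whitney results), `factors`
#'   (factor model and per-factor regressions), `reports` (per-subject
#'   preprocessing diagnostics), invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  t_all <- proc.time()[3]
  log_lines <- c(
    "eegsynch run_all",
    sprintf("seed: %d  subjects: %d  phase: %s", config$cohort$seed,
            config$cohort$n_subjects, config$phase),
    sprintf("truncation c = %d, n_freq = %d", config$spectral$truncation,
            config$spectral$n_freq),
    sprintf("band edges (Hz): %s; bands used: %s",
            paste(unique(unlist(frequency_bands())), collapse = "/"),
            paste(config$bands, collapse = ",")),
    sprintf("FIR order %d; borders %g/%g/%g Hz; segments %g s / %g s overlap",
            config$fir_order, config$highpass, config$eog_lowpass,
            config$lowpass, config$length_s, config$overlap_s),
    sprintf("bonferroni threshold: %g", 0.05 / config$bonferroni_m),
    sprintf("markers: %s", paste(config$markers, collapse = ",")))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines,
                    sprintf("stage %s: %.1f s", name, proc.time()[3] - t0))
    res
  }
  out <- list()

  cohort <- stage("simulate", generate_cohort(config$cohort))
  out$cohort <- cohort

  if (any(c("preprocess", "markers") %in% config$stages)) {
    res <- stage("markers", {
      tabs <- vector("list", nrow(cohort))
      reports <- vector("list", nrow(cohort))
      for (i in seq_len(nrow(cohort))) {
        rec <- generate_recording(cohort[i, ], config$phase, config$artifacts,
                                  seed = subject_seed(config$cohort$seed, i),
                                  spec = config$cohort,
                                  duration_s = config$duration_s,
                                  rate = config$rate)
        segs <- preprocess_pipeline(rec, highpass = config$highpass,
                                    lowpass = config$lowpass,
                                    eog_lowpass = config$eog_lowpass,
                                    fir_order = config$fir_order,
                                    length_s = config$length_s,
                                    overlap_s = config$overlap_s)
        reports[[i]] <- segs$report
        tb <- subject_markers(segs, markers = config$markers,
                              bands = config$bands,
                              config = config$spectral,
                              ar_max_order = config$ar_max_order,
                              cmi_normalization = config$cmi_normalization)
        tabs[[i]] <- cbind(subject = cohort$id[i], tb)
      }
      list(tbl = do.call(rbind, tabs), reports = reports)
    })
    out$markers <- res$tbl
    out$reports <- res$reports
    log_lines <- c(log_lines,
                   sprintf("segments kept (median): %d",
                           as.integer(stats::median(vapply(res$reports,
                             function(r) r$n_kept, numeric(1))))))
  }

  if ("severity" %in% config$stages && !is.null(out$markers)) {
    sev <- stage("severity", {
      sel <- select_best_combo(out$markers, cohort)
      fits <- lapply(seq_len(nrow(sel)), function(i) {
        k <- sel[i, c("marker", "pair", "band", "direction", "combo")]
        s <- merge(out$markers, k)
        y <- s$value[match(cohort$id, s$subject)]
        fit <- quadratic_regression(y, cohort)
        reg <- mmse_regime_test(y, cohort, cut = config$regime_cut)
        list(key = k, fit = fit, regime = reg)
      })
      p <- vapply(fits, function(f) f$fit$f_pvalue, numeric(1))
      flags <- bonferroni_flags(p, m = config$bonferroni_m)
      list(selection = sel, fits = fits, bonferroni = flags)
    })
    out$selection <- sev$selection
    out$severity <- sev$fits
    out$bonferroni <- sev$bonferroni
    out$regime <- lapply(sev$fits, function(f) f$regime)
  }

  if ("factors" %in% config$stages && !is.null(out$selection)) {
    out$factors <- stage("factors", {
      sel <- out$selection[out$selection$pair == config$factor_pair, ]
      m <- marker_matrix(out$markers, sel, cohort)
      keep <- apply(m, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
      m <- m[, keep, drop = FALSE]
      if (nrow(m) < ncol(m)) {
        message("factor analysis skipped: fewer subjects (", nrow(m),
                ") than markers (", ncol(m), ")")
        NULL
      } else {
        fm <- factor_analysis(m, n_factors = config$n_factors)
        list(model = fm, regressions = factor_regression(fm, cohort))
      }
    })
  }

  log_lines <- c(log_lines,
                 sprintf("total: %.1f s", proc.time()[3] - t_all))
  out$log <- log_lines

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    if (!is.null(out$markers))
      utils::write.table(out$markers, file.path(config$out_dir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$selection))
      utils::write.table(out$selection,
                         file.path(config$out_dir, "selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$severity)) {
      res_json <- lapply(out$severity, function(f)
        list(key = as.list(f$key), r_squared = f$fit$r_squared,
             f_pvalue = f$fit$f_pvalue, vertex = f$fit$vertex,
             regime_p = f$regime$p_value))
      jsonlite::write_json(res_json,
                           file.path(config$out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  }
  invisible(out)
}
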