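# End-to-end synthetic study orchestration: generate every modality's
# raw data with planted effects, run the three analysis branches
# (ECG digitise -> features, NLP scoring, CAM ratios), assemble the
# patient-level record table and produce the association report.

#' Pipeline run configuration
#'
#' @param seed master RNG seed; every stage derives its own seed from it.
#' @param n cohort size.
#' @param ecg_n size of the ECG sub-cohort (paper-ECG availability).
#' @param event_rate target mortality rate.
#' @param or_per_sd planted per-SD odds ratios for the three latent
#'   modality signals (total compromise ratio, severity score, heart
#'   rate).
#' @param px_per_mm render resolution for synthetic ECG pages.
#' @param ecg_duration rhythm-strip length, s.
#' @param lung_shape synthetic CXR mask shape.
#' @param threshold CAM activation threshold.
#' @param n_perm permutations for the pointwise template test.
#' @param fdr_level FDR level used in reporting.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n = 121, ecg_n = 27,
                       event_rate = 0.157,
                       or_per_sd = c(tcr = 2.0, severity = 1.5,
                                     mean_hr = 1.5),
                       px_per_mm = 5, ecg_duration = 10,
                       lung_shape = c(64, 64), threshold = 0.20,
                       n_perm = 500, fdr_level = 0.05, out_dir = NULL) {
  stopifnot_scalar(fdr_level, "fdr_level", 0, 1, strict = TRUE)
  stopifnot(ecg_n <= n)
  structure(list(seed = seed, n = n, ecg_n = ecg_n,
                 event_rate = event_rate, or_per_sd = or_per_sd,
                 px_per_mm = px_per_mm, ecg_duration = ecg_duration,
                 lung_shape = lung_shape, threshold = threshold,
                 n_perm = n_perm, fdr_level = fdr_level,
                 out_dir = out_dir), class = "run_config")
}

# note text for one patient from planted gold criterion flags
build_note <- function(flags, age, dictionary, seed) {
  with_seed(seed, {
    sent <- c(sprintf("paciente de %d años valorado en piso.", age),
              sample(distractor_sentences(), 2))
    for (cr in names(flags)[flags]) {
      phrase <- sample(unlist(dictionary$criteria[[cr]]$plant), 1)
      sent <- c(sent, paste0(phrase, "."))
    }
    paste(sample(sent), collapse = " ")
  })
}

run_ecg_branch <- function(z_hr, ids, cfg) {
  spec <- page_render_spec(px_per_mm = cfg$px_per_mm)
  feats <- list(); templates <- list(); beat_tabs <- list()
  for (k in seq_along(ids)) {
    hr <- max(45, min(150, 85 + 12 * z_hr[k]))
    par <- ecg_sim_params(mean_hr = hr, rmssd_target = 20,
                          duration = cfg$ecg_duration,
                          seed = cfg$seed + 1000L + ids[k])
    truth <- gen_ecg_signal(par)
    page <- render_ecg_page(truth, spec)
    sigs <- digitise_page(page$image, page$manifest)
    sig <- sigs[[1]]
    peaks <- detect_r_peaks(sig)
    if (length(peaks) < 3) next
    beats <- filter_rr(peaks)
    if (!nrow(beats)) next
    bl <- estimate_baseline(sig, beats$peak_time)
    bs <- segment_beats(sig, beats, baseline = bl)
    if (!nrow(bs$segments)) next
    bf <- beat_features(bs)
    hrv <- tryCatch(hrv_metrics(beats$rr_prev),
                    error = function(e) NULL)
    feats[[k]] <- data.frame(
      patient_id = ids[k],
      mean_hr = if (is.null(hrv)) NA else hrv$mean_hr,
      rmssd = if (is.null(hrv)) NA else hrv$rmssd,
      sd1 = if (is.null(hrv)) NA else hrv$sd1,
      sd2 = if (is.null(hrv)) NA else hrv$sd2,
      sdnn = if (is.null(hrv)) NA else hrv$sdnn,
      st_level = stats::median(bf$st_level, na.rm = TRUE),
      t_amp = stats::median(bf$t_amp, na.rm = TRUE),
      r_amp = stats::median(bf$r_amp, na.rm = TRUE),
      n_beats = nrow(bf))
    templates[[k]] <- colMeans(bs$segments)
    bf$patient_id <- ids[k]
    beat_tabs[[k]] <- bf
  }
  list(patient = do.call(rbind, feats),
       templates = do.call(rbind, templates),
       template_ids = ids[!vapply(templates, is.null, TRUE)],
       beats = do.call(rbind, beat_tabs))
}

#' Run the full synthetic multimodal study
#'
#' Generates a cohort with planted effects, synthesises raw inputs for
#' each modality (ECG pages, Spanish notes, lung activation maps), runs
#' each analysis branch on the raw data, and assembles the association
#' report. Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return list (`pipeline_report`): `records` patient table,
#'   `association` table, `firth` fit, `permutation` result,
#'   `agreement` report, `missingness`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dict <- load_dictionary()
  cohort <- gen_cohort(cohort_sim_params(
    n = cfg$n, event_rate = cfg$event_rate,
    or_per_sd = cfg$or_per_sd, seed = cfg$seed))

  # --- CXR branch: plant a consolidation fraction from the latent signal
  frac <- stats::pnorm(cohort$tcr) * 0.6
  cxr_rows <- lapply(seq_len(cfg$n), function(i) {
    lug <- gen_lung_activation(cfg$lung_shape,
                               true_fraction_left = frac[i],
                               true_fraction_right = frac[i],
                               threshold = cfg$threshold,
                               seed = cfg$seed + 2000L + i)
    cr <- compromise_ratios(lug$activation, split_lungs(lug$mask),
                            cfg$threshold)
    data.frame(patient_id = i, cr_left = cr$cr_left,
               cr_right = cr$cr_right, tcr_measured = cr$tcr)
  })
  cxr_tab <- do.call(rbind, cxr_rows)

  # --- NLP branch: plant criteria proportional to the latent severity
  ages <- with_seed(cfg$seed + 3000L, sample(35:95, cfg$n, replace = TRUE))
  crits <- idsa_criteria()
  k_crit <- pmin(length(crits),
                 pmax(0, round(stats::pnorm(cohort$severity) * 6)))
  gold_flags <- matrix(FALSE, cfg$n, length(crits),
                       dimnames = list(NULL, crits))
  notes <- character(cfg$n)
  for (i in seq_len(cfg$n)) {
    picked <- with_seed(cfg$seed + 4000L + i,
                        sample(crits, k_crit[i]))
    gold_flags[i, picked] <- TRUE
    notes[i] <- build_note(gold_flags[i, ], ages[i], dict,
                           cfg$seed + 5000L + i)
  }
  nlp_tab <- score_notes(notes, ages, dict, version = "V2")
  agreement <- agreement_stats(nlp_tab, as.data.frame(gold_flags))

  # --- ECG branch on the sub-cohort (include events when available)
  deaths <- which(cohort$death == 1)
  ecg_ids <- with_seed(cfg$seed + 6000L, {
    need_dead <- min(length(deaths), max(2L, round(cfg$ecg_n * 0.15)))
    dd <- if (need_dead > 0) sample(deaths, need_dead) else integer(0)
    ss <- sample(setdiff(seq_len(cfg$n), dd), cfg$ecg_n - length(dd))
    sort(c(dd, ss))
  })
  ecg <- run_ecg_branch(cohort$mean_hr[ecg_ids], ecg_ids, cfg)

  # --- patient record table (ECG block nullable outside the subset)
  records <- data.frame(patient_id = cohort$patient_id,
                        age = ages,
                        death = cohort$death)
  records <- merge(records, cxr_tab, by = "patient_id")
  records$severity_score <- nlp_tab$severity_score
  records <- merge(records, ecg$patient, by = "patient_id", all.x = TRUE)

  # --- association layer
  assoc <- association_table(
    data.frame(tcr = records$tcr_measured,
               severity_score = records$severity_score,
               age = records$age),
    outcome = records$death)
  ecg_sub <- records[!is.na(records$mean_hr), ]
  if (length(unique(ecg_sub$death)) == 2) {
    assoc <- rbind(assoc, within(
      logistic_or_per_sd(ecg_sub$mean_hr, ecg_sub$death, name = "mean_hr"),
      q <- NA_real_))
  }
  firth <- firth_logistic(
    cbind(tcr = as.numeric(scale(records$tcr_measured)),
          severity = as.numeric(scale(records$severity_score)),
          age = as.numeric(scale(records$age))),
    records$death)
  perm <- NULL
  tmpl_labels <- cohort$death[ecg$template_ids]
  if (!is.null(ecg$templates) && length(unique(tmpl_labels)) == 2) {
    perm <- pointwise_permutation(ecg$templates, tmpl_labels,
                                  n_perm = cfg$n_perm,
                                  seed = cfg$seed + 7000L)
  }
  miss <- missingness_report(records[, setdiff(names(records),
                                               "patient_id")])
  report <- list(
    records = records, association = assoc, firth = firth,
    permutation = perm, agreement = agreement, missingness = miss,
    manifest = list(seed = cfg$seed, n = cfg$n, ecg_n = cfg$ecg_n,
                    threshold = cfg$threshold, n_perm = cfg$n_perm,
                    package_version = as.character(
                      utils::packageVersion("pneumabio")))
  )
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Per-variable missingness report
#'
#' Fraction of missing values per column; variables strictly above the
#' 20% threshold are flagged (a common exclusion rule for key
#' variables).
#'
#' @param records data.frame.
#' @param threshold flagging threshold (strict `>`).
#' @return data.frame: variable, n_missing, frac_missing, flagged.
#' @export
missingness_report <- function(records, threshold = 0.20) {
  if (!nrow(records)) pb_stop("empty table", "pb_input_error")
  fr <- vapply(records, function(col) mean(is.na(col)), 0)
  data.frame(variable = names(fr),
             n_missing = vapply(records, function(col) sum(is.na(col)), 0L),
             frac_missing = unname(fr),
             flagged = unname(fr > threshold),
             row.names = NULL)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records,
                   file.path(out_dir, "patient_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$association,
                   file.path(out_dir, "association_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$missingness,
                   file.path(out_dir, "missingness.csv"),
                   row.names = FALSE)
  utils::write.csv(report$agreement$per_criterion,
                   file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)
  if (!is.null(report$permutation)) {
    utils::write.csv(
      data.frame(delta_obs = report$permutation$delta_obs,
                 p = report$permutation$p, q = report$permutation$q),
      file.path(out_dir, "permutation.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
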