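# End-to-end orchestration: generate -> preprocess -> spectra -> BCI ->
# statistics, with a YAML-serializable configuration, derived seeds, a run
# manifest and an output validator.

#' Build a pipeline run configuration
#'
#' All knobs of a reproducible run. The defaults reproduce the study
#' conditions (12 + 19 subjects, 5-min rest at 500 Hz, 15-trial sessions
#' at 250 Hz); tests and examples pass smaller sizes through the same
#' interface.
#'
#' @param n_uws,n_mcs group sizes.
#' @param seed master seed; every stage derives its own stream from it.
#' @param outdir output directory.
#' @param plan a [session_plan()].
#' @param null_effects generate a null cohort (no group differences).
#' @param artifact_rate spike events per minute in the synthesis.
#' @param ica run the ICA stage during preprocessing.
#' @param threshold BCI feedback threshold.
#' @param write_edf also export each recording as EDF.
#' @return a `run_config` list.
#' @export
run_config <- function(n_uws = 12, n_mcs = 19, seed = 1,
                       outdir = tempfile("docbci_run_"),
                       plan = session_plan(), null_effects = FALSE,
                       artifact_rate = 2, ica = TRUE, threshold = 50,
                       write_edf = FALSE) {
  structure(list(n_uws = n_uws, n_mcs = n_mcs, seed = seed, outdir = outdir,
                 plan = unclass(plan), null_effects = null_effects,
                 artifact_rate = artifact_rate, ica = ica,
                 threshold = threshold, write_edf = write_edf),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$outdir <- NULL # location must not change the hash
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE)
}

read_table <- function(path) read.csv(path, comment.char = "#")

#' Execute the full analysis pipeline
#'
#' Runs every stage on a synthetic cohort: profile generation, rest and
#' task synthesis, preprocessing with QC, Welch relative band power by
#' region, closed-loop session scoring, and the statistical tables.
#' All tables are written as CSV (UTF-8, comma, '.' decimal) with the
#' configuration hash in a header comment, plus a JSON run manifest.
#' Identical configurations yield byte-identical CSV outputs.
#'
#' @param config a [run_config()].
#' @return list with `manifest`, `tables` (in-memory copies), `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  plan <- do.call(session_plan, config$plan)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed

  ec <- default_effect_config(null_effects = config$null_effects)
  cohort <- make_cohort(config$n_uws, config$n_mcs, ec,
                        seed = derive_seed(seed, "cohort_stage"))
  meta <- cohort_metadata(cohort)

  rpt <- NULL
  qc <- NULL
  topo_acc <- list(rest = NULL, task = NULL)
  for (p in cohort) {
    for (cond in c("rest", "task")) {
      rec <- synthesize_recording(p, plan, cond,
                                  artifact_rate = config$artifact_rate,
                                  seed = derive_seed(seed, p$subject_id, cond))
      if (config$write_edf)
        write_edf(rec, file.path(outdir, paste0(p$subject_id, "_",
                                                cond, ".edf")))
      pp <- preprocess_recording(rec, ica = config$ica,
                                 ica_seed = derive_seed(seed, p$subject_id,
                                                        cond, "ica"))
      if (pp$qc$all_rejected) {
        qc <- rbind(qc, data.frame(subject_id = p$subject_id,
                                   condition = cond, failed = TRUE,
                                   bad_channels = NA, ica_removed = NA,
                                   epochs_kept = 0,
                                   epochs_rejected = pp$qc$epochs_rejected,
                                   snr_pre_db = NA, snr_post_db = NA))
        next
      }
      psd <- welch_psd(pp$epochs)
      rp <- relative_power(psd)
      rp$subject_id <- p$subject_id
      rp$group <- p$group
      rp$condition <- cond
      rpt <- rbind(rpt, rp[, c("subject_id", "group", "condition",
                               "region", "band", "rel_power")])
      topo <- export_topography(psd)
      topo_acc[[cond]] <- if (is.null(topo_acc[[cond]]))
        topo else {
          t2 <- topo_acc[[cond]]
          t2[, -(1:3)] <- t2[, -(1:3)] + topo[, -(1:3)]
          t2
        }
      qc <- rbind(qc, data.frame(subject_id = p$subject_id,
                                 condition = cond, failed = FALSE,
                                 bad_channels = length(pp$qc$bad_channels),
                                 ica_removed = pp$qc$ica_removed,
                                 epochs_kept = pp$qc$epochs_kept,
                                 epochs_rejected = pp$qc$epochs_rejected,
                                 snr_pre_db = pp$qc$snr_pre_db,
                                 snr_post_db = pp$qc$snr_post_db))
    }
  }

  bci <- run_cohort_sessions(cohort, plan,
                             seed = derive_seed(seed, "bci_stage"),
                             threshold = config$threshold,
                             artifact_rate = config$artifact_rate)
  tabs <- build_contrast_tables(rpt, bci$sessions, meta)

  tables <- list(cohort_metadata = meta, relative_power = rpt, qc = qc,
                 sessions = bci$sessions, trial_outcomes = bci$outcomes,
                 table1 = tabs$table1, table2_within = tabs$table2_within,
                 table2_between = tabs$table2_between,
                 accuracy_contrast = tabs$accuracy,
                 attention_crsr_correlation = tabs$correlation)
  for (nm in names(tables))
    if (!is.null(tables[[nm]]))
      write_table(tables[[nm]], file.path(outdir, paste0(nm, ".csv")), hash)
  for (cond in c("rest", "task"))
    if (!is.null(topo_acc[[cond]])) {
      tp <- topo_acc[[cond]]
      tp[, -(1:3)] <- tp[, -(1:3)] / length(cohort)
      write_table(tp, file.path(outdir, paste0("topography_", cond, ".csv")),
                  hash)
    }
  cfg_path <- file.path(outdir, "config.yaml")
  cfg <- unclass(config)
  writeLines(yaml::as.yaml(cfg), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("docbci")),
    config_hash = hash, seed = seed,
    n_subjects = length(cohort),
    row_counts = lapply(tables, function(t) if (is.null(t)) 0L else nrow(t)),
    bci_failures = bci$failures,
    stage_order = c("cohort", "synthesize", "preprocess", "spectra",
                    "bci", "stats"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(manifest = manifest, tables = tables, outdir = outdir)
}

#' Validate the outputs of a pipeline run
#'
#' Re-reads the run's CSV outputs and asserts the invariant suite: tables
#' present, relative-power band sums equal to one within 1e-6, relative
#' powers inside \[0, 1\], accuracies inside \[0, 100\], all p values in
#' (0, 1\], and session row counts matching the manifest.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @return list with `pass` (logical) and `checks` (data.frame of
#'   check/status/detail rows).
#' @export
validate_run <- function(outdir) {
  checks <- NULL
  add <- function(name, ok, detail = "")
    checks <<- rbind(checks, data.frame(check = name, pass = ok,
                                        detail = detail, row.names = NULL))
  need <- c("cohort_metadata", "relative_power", "sessions",
            "table2_within", "table2_between", "manifest")
  paths <- file.path(outdir, paste0(need, c(rep(".csv", 5), ".json")))
  missing <- need[!file.exists(paths)]
  add("outputs_present", !length(missing), paste(missing, collapse = ", "))
  if (length(missing)) return(list(pass = FALSE, checks = checks))

  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  rpt <- read_table(file.path(outdir, "relative_power.csv"))
  sums <- aggregate(rel_power ~ subject_id + condition + region, rpt, sum)
  add("band_sums_unity", all(abs(sums$rel_power - 1) < 1e-6),
      sprintf("max dev %.2g", max(abs(sums$rel_power - 1))))
  add("rel_power_range", all(rpt$rel_power >= 0 & rpt$rel_power <= 1))

  sess <- read_table(file.path(outdir, "sessions.csv"))
  add("accuracy_bounds",
      all(sess$accuracy_pct >= 0 & sess$accuracy_pct <= 100))
  add("session_rows",
      nrow(sess) == manifest$row_counts$sessions,
      sprintf("%d vs manifest %d", nrow(sess),
              manifest$row_counts$sessions))

  pv <- c(read_table(file.path(outdir, "table2_within.csv"))$p,
          unlist(read_table(file.path(outdir,
                                      "table2_between.csv"))[, c("p_rest",
                                                                 "p_task",
                                                                 "p_delta")]))
  add("p_value_range", all(pv > 0 & pv <= 1))
  list(pass = all(checks$pass), checks = checks)
}
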