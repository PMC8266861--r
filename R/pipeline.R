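# End-to-end orchestration: simulate -> segment -> roi -> extract -> select
# -> evaluate -> report, with plain-file handoff between stages so every
# intermediate artifact is inspectable and replayable.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic analysis. The cohort
#' defaults mirror the study design the package implements: a 108-patient
#' fine-tuning cohort (30 pCR, 78 non-pCR) used for feature selection and
#' LOO evaluation, and a 26-patient independent test (7 pCR, 19 non-pCR)
#' never touched by the selection.
#'
#' @param outdir output directory for stage artifacts.
#' @param seed master seed governing every random draw of the run.
#' @param n_pcr_train,n_nonpcr_train fine-tuning cohort sizes.
#' @param n_pcr_test,n_nonpcr_test independent-test cohort sizes.
#' @param phantom a [synthetic_phantom_config()] template; per-patient seeds
#'   and mild per-patient radius variation are derived from `seed`.
#' @param t2_shrink_pcr in-plane tumor radius factor at the early-treatment
#'   exam for responders (shrinkage after the first chemotherapy cycle).
#' @param t2_gain_damp_pcr fraction by which responder enhancement gains
#'   relax toward 1 at the early-treatment exam.
#' @param backend extractor backend (see [make_extractor()]).
#' @param extractor_seed seed of the filter-bank weights.
#' @param selection a [selection_config()]; its seed defaults to `seed`.
#' @param pe_threshold,ser_range segmentation thresholds
#'   (see [segment_tumor()]).
#' @param n_select_features number of evenly-spaced pool2 features per
#'   timepoint entering the selection (desk-scale default 500, i.e. 1,000
#'   for T1+T2 combined).
#' @param assoc_strength class association of the synthetic clinical table.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1,
                            n_pcr_train = 30, n_nonpcr_train = 78,
                            n_pcr_test = 7, n_nonpcr_test = 19,
                            phantom = synthetic_phantom_config(),
                            t2_shrink_pcr = 0.75,
                            t2_gain_damp_pcr = 0.85,
                            backend = "filterbank",
                            extractor_seed = 909,
                            selection = NULL,
                            pe_threshold = 0.7,
                            ser_range = c(0.9, Inf),
                            n_select_features = 500,
                            assoc_strength = 1) {
  if (is.null(selection)) selection <- selection_config(seed = seed)
  structure(
    list(outdir = outdir, seed = as.integer(seed),
         n_pcr_train = n_pcr_train, n_nonpcr_train = n_nonpcr_train,
         n_pcr_test = n_pcr_test, n_nonpcr_test = n_nonpcr_test,
         phantom = phantom,
         t2_shrink_pcr = t2_shrink_pcr,
         t2_gain_damp_pcr = t2_gain_damp_pcr,
         backend = backend, extractor_seed = as.integer(extractor_seed),
         selection = selection,
         pe_threshold = pe_threshold, ser_range = ser_range,
         n_select_features = as.integer(n_select_features),
         assoc_strength = assoc_strength),
    class = "pipeline_config")
}

stage_path <- function(config, ...) file.path(config$outdir, ...)

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run stage '", produced_by,
         "' first", call. = FALSE)
  }
  path
}

write_manifest <- function(config, stage, inputs = character(),
                           extra = list(), elapsed = NA_real_) {
  dir.create(stage_path(config, stage), recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- c(list(
    stage = stage,
    seed = config$seed,
    config = list(
      n_train = c(pcr = config$n_pcr_train, nonpcr = config$n_nonpcr_train),
      n_test = c(pcr = config$n_pcr_test, nonpcr = config$n_nonpcr_test),
      backend = config$backend, extractor_seed = config$extractor_seed,
      selection = unclass(config$selection),
      pe_threshold = config$pe_threshold, ser_range = config$ser_range,
      n_select_features = config$n_select_features),
    input_md5 = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("earlypcr")),
    r_version = R.version.string,
    elapsed_s = round(elapsed, 2),
    written_at = format(Sys.time(), tz = "UTC")
  ), extra)
  jsonlite::write_json(manifest,
                       stage_path(config, stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# per-patient phantom configs for both timepoints; responders shrink and
# enhance less at the early-treatment exam
patient_phantoms <- function(config, k, label) {
  tpl <- config$phantom
  jitter <- with_seed(mix_seed(config$seed, 31L, k),
                      stats::runif(2, 0.8, 1.2))
  radii <- pmax(c(tpl$tumor_radii[1],
                  round_half_up(tpl$tumor_radii[2:3] * jitter)), 2)
  make_cfg <- function(radii, gains_scale) {
    gp <- 1 + (tpl$enhancement_pcr - 1) * gains_scale
    gn <- tpl$enhancement_nonpcr
    synthetic_phantom_config(
      volume_shape = tpl$volume_shape, pixel_spacing = tpl$pixel_spacing,
      tumor_center = tpl$tumor_center, tumor_radii = radii,
      enhancement_pcr = gp, enhancement_nonpcr = gn,
      texture_sd = tpl$texture_sd, base_intensity = tpl$base_intensity,
      seed = mix_seed(config$seed, 32L, k))
  }
  cfg_t1 <- make_cfg(radii, 1)
  radii_t2 <- radii
  if (label == "pCR") {
    radii_t2 <- pmax(c(radii[1], round_half_up(radii[2:3] * config$t2_shrink_pcr)), 2)
  }
  cfg_t2 <- make_cfg(radii_t2, if (label == "pCR") config$t2_gain_damp_pcr else 1)
  cfg_t2$seed <- mix_seed(config$seed, 33L, k)
  list(T1 = cfg_t1, T2 = cfg_t2)
}

run_simulate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(stage_path(config, "simulate"), recursive = TRUE,
             showWarnings = FALSE)
  n_all <- config$n_pcr_train + config$n_nonpcr_train +
    config$n_pcr_test + config$n_nonpcr_test
  labels <- c(rep("pCR", config$n_pcr_train),
              rep("non-pCR", config$n_nonpcr_train),
              rep("pCR", config$n_pcr_test),
              rep("non-pCR", config$n_nonpcr_test))
  cohort <- c(rep("fine-tuning", config$n_pcr_train + config$n_nonpcr_train),
              rep("independent-test", config$n_pcr_test + config$n_nonpcr_test))
  patients <- lapply(seq_len(n_all), function(k) {
    cfgs <- patient_phantoms(config, k, labels[k])
    tp <- lapply(c(T1 = "T1", T2 = "T2"), function(t) {
      gen_dce_patient(cfgs[[t]], labels[k])
    })
    list(id = sprintf("P%03d", k), label = labels[k], cohort = cohort[k],
         T1 = tp$T1, T2 = tp$T2)
  })
  names(patients) <- vapply(patients, `[[`, "", "id")
  saveRDS(patients, stage_path(config, "simulate", "patients.rds"))
  clin_train <- gen_clinical_table(config$n_pcr_train, config$n_nonpcr_train,
                                   config$assoc_strength,
                                   seed = mix_seed(config$seed, 41L))
  clin_test <- gen_clinical_table(config$n_pcr_test, config$n_nonpcr_test,
                                  config$assoc_strength,
                                  seed = mix_seed(config$seed, 42L))
  # clinical rows follow cohort order: pCR-first within each cohort
  reorder_clin <- function(clin, ids) {
    clin <- clin[order(clin$pcr == "pCR", decreasing = TRUE), ]
    clin$patient_id <- ids
    rownames(clin) <- ids
    clin
  }
  ids <- names(patients)
  train_ids <- ids[cohort == "fine-tuning"]
  test_ids <- ids[cohort == "independent-test"]
  clinical <- rbind(
    cbind(reorder_clin(clin_train, train_ids), cohort = "fine-tuning"),
    cbind(reorder_clin(clin_test, test_ids), cohort = "independent-test"))
  clinical$pcr <- factor(labels, levels = c("non-pCR", "pCR"))
  utils::write.csv(clinical, stage_path(config, "simulate", "clinical.csv"),
                   row.names = FALSE)
  truth <- list(labels = stats::setNames(labels, ids),
                cohort = stats::setNames(cohort, ids),
                ld_mm = stats::setNames(
                  vapply(patients, function(p) p$T1$ld_mm, numeric(1)), ids))
  jsonlite::write_json(truth, stage_path(config, "simulate", "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "simulate",
                 extra = list(n_patients = n_all),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

# bounding box of the true mask, padded; the radiologist-style seed region
mask_seed_box <- function(mask, pad = 3L) {
  pos <- which(mask, arr.ind = TRUE)
  list(lo = pmax(apply(pos, 2, min) - pad, 1L),
       hi = pmin(apply(pos, 2, max) + pad, dim(mask)))
}

run_segment <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  patients <- readRDS(require_artifact(
    stage_path(config, "simulate", "patients.rds"), "simulate"))
  dir.create(stage_path(config, "segment"), showWarnings = FALSE,
             recursive = TRUE)
  masks <- lapply(patients, function(p) {
    lapply(c(T1 = "T1", T2 = "T2"), function(t) {
      segment_tumor(p[[t]]$series, mask_seed_box(p[[t]]$mask),
                    config$pe_threshold, config$ser_range)
    })
  })
  dice <- vapply(names(patients), function(id) {
    mean(c(dice_coefficient(masks[[id]]$T1, patients[[id]]$T1$mask),
           dice_coefficient(masks[[id]]$T2, patients[[id]]$T2$mask)))
  }, numeric(1))
  saveRDS(masks, stage_path(config, "segment", "masks.rds"))
  write_manifest(config, "segment",
                 inputs = stage_path(config, "simulate", "patients.rds"),
                 extra = list(mean_dice = mean(dice), min_dice = min(dice)),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

run_roi <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  patients <- readRDS(require_artifact(
    stage_path(config, "simulate", "patients.rds"), "simulate"))
  masks <- readRDS(require_artifact(
    stage_path(config, "segment", "masks.rds"), "segment"))
  dir.create(stage_path(config, "roi"), showWarnings = FALSE, recursive = TRUE)
  patches <- lapply(names(patients), function(id) {
    p <- patients[[id]]
    lapply(c(T1 = "T1", T2 = "T2"), function(t) {
      extract_roi(p[[t]]$series, masks[[id]][[t]], p[[t]]$ld_mm, timepoint = t)
    })
  })
  names(patches) <- names(patients)
  saveRDS(patches, stage_path(config, "roi", "patches.rds"))
  prov <- lapply(patches, function(pp) {
    lapply(pp, function(x) {
      list(slice = x$source_slice, center = x$center, ld_mm = x$ld_mm,
           ld_px = x$ld_px)
    })
  })
  jsonlite::write_json(prov, stage_path(config, "roi", "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "roi",
                 inputs = c(stage_path(config, "simulate", "patients.rds"),
                            stage_path(config, "segment", "masks.rds")),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

run_extract <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  patches <- readRDS(require_artifact(
    stage_path(config, "roi", "patches.rds"), "roi"))
  dir.create(stage_path(config, "extract"), showWarnings = FALSE,
             recursive = TRUE)
  extractor <- make_extractor(config$backend, seed = config$extractor_seed)
  feats <- t(vapply(names(patches), function(id) {
    v1 <- extract_features(patches[[id]]$T1, extractor, patient_id = id)
    v2 <- extract_features(patches[[id]]$T2, extractor, patient_id = id)
    concat_timepoints(v1, v2)$values
  }, numeric(86528L)))
  saveRDS(feats, stage_path(config, "extract", "features.rds"))
  cap <- select_feature_columns(config)
  write_feature_csv(feats[, cap, drop = FALSE],
                    stage_path(config, "extract", "features_capped.csv"))
  jsonlite::write_json(
    list(extractor = extractor$name, flatten_order = extractor$flatten_order,
         normalization = "per-patch min-max to [0,1], 3 replicated channels",
         capped_columns = cap),
    stage_path(config, "extract", "extractor.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "extract",
                 inputs = stage_path(config, "roi", "patches.rds"),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

# evenly spaced zero-based feature ids, n per timepoint block
select_feature_columns <- function(config) {
  n <- config$n_select_features
  base <- unique(round_half_up(seq(0, 43263, length.out = n)))
  paste0("f", c(base, base + 43264L))
}

#' Write/read a feature matrix as CSV with zero-based feature-id header
#'
#' @param X numeric matrix with feature-name columns and patient rownames.
#' @param path CSV path.
#' @return `path` (write) / the matrix (read).
#' @export
write_feature_csv <- function(X, path) {
  df <- data.frame(patient_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$patient_id
  X
}

read_cohort_data <- function(config) {
  feats <- readRDS(require_artifact(
    stage_path(config, "extract", "features.rds"), "extract"))
  clinical <- utils::read.csv(require_artifact(
    stage_path(config, "simulate", "clinical.csv"), "simulate"),
    stringsAsFactors = TRUE)
  clinical$pcr <- factor(clinical$pcr, levels = c("non-pCR", "pCR"))
  rownames(clinical) <- clinical$patient_id
  list(features = feats, clinical = clinical,
       train = clinical$patient_id[clinical$cohort == "fine-tuning"],
       test = clinical$patient_id[clinical$cohort == "independent-test"])
}

run_select <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  dat <- read_cohort_data(config)
  dir.create(stage_path(config, "select"), showWarnings = FALSE,
             recursive = TRUE)
  cap <- select_feature_columns(config)
  X <- dat$features[dat$train, cap, drop = FALSE]
  y <- dat$clinical[dat$train, "pcr"]
  names(y) <- dat$train
  res <- loo_dynamic_select(X, y, config$selection)
  saveRDS(res, stage_path(config, "select", "selection.rds"))
  write_selection_json(res, stage_path(config, "select", "selection.json"))
  writeLines(res$osf, stage_path(config, "select", "osf.txt"))
  write_manifest(config, "select",
                 inputs = stage_path(config, "extract", "features.rds"),
                 extra = list(osf_size = length(res$osf),
                              draw_log_digest = sum(res$draw_log$redraws)),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

run_evaluate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  dat <- read_cohort_data(config)
  sel <- readRDS(require_artifact(
    stage_path(config, "select", "selection.rds"), "select"))
  dir.create(stage_path(config, "evaluate"), showWarnings = FALSE,
             recursive = TRUE)
  osf <- sel$osf
  tr <- dat$train; te <- dat$test
  ytr <- stats::setNames(dat$clinical[tr, "pcr"], tr)
  yte <- stats::setNames(dat$clinical[te, "pcr"], te)
  ctr <- dat$clinical[tr, , drop = FALSE]
  cte <- dat$clinical[te, , drop = FALSE]
  clin_vars <- select_associated(associate(ctr, ytr))
  clin_vars <- intersect(clin_vars, c("er", "pgr", "her2", "subtype"))
  if (length(clin_vars) == 0) clin_vars <- c("er", "pgr", "her2", "subtype")
  Xtr <- dat$features[tr, osf, drop = FALSE]
  Xte <- dat$features[te, osf, drop = FALSE]
  reports <- list()
  if (length(osf)) {
    reports$loo_osf <- evaluate_loo(loo_scores(Xtr, ytr), ytr)
    reports$loo_osf_clinical <-
      evaluate_loo(loo_scores(Xtr, ytr, clinical = ctr,
                              clinical_vars = clin_vars), ytr)
    reports$test_osf <- independent_eval(Xtr, ytr, Xte, yte, osf = osf)
    reports$test_osf_clinical <- independent_eval(
      Xtr, ytr, Xte, yte, osf = osf,
      train_clinical = ctr, test_clinical = cte, clinical_vars = clin_vars)
    reports$subtype_stratified <- subtype_stratified_eval(
      reports$loo_osf$scores, ytr, ctr$subtype,
      reports$loo_osf$youden_threshold)
  }
  reports$loo_clinical <- evaluate_loo(
    loo_scores(matrix(0, length(tr), 0, dimnames = list(tr, NULL)), ytr,
               clinical = ctr, clinical_vars = clin_vars), ytr)
  reports$clinical_variables <- clin_vars
  reports$osf <- osf
  saveRDS(reports, stage_path(config, "evaluate", "reports.rds"))
  summary_json <- lapply(
    reports[vapply(reports, inherits, TRUE, "eval_report")],
    function(r) list(auc = r$auc, accuracy = r$accuracy,
                     sensitivity = r$sensitivity,
                     specificity = r$specificity,
                     youden_threshold = r$youden_threshold))
  jsonlite::write_json(summary_json,
                       stage_path(config, "evaluate", "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "evaluate",
                 inputs = c(stage_path(config, "extract", "features.rds"),
                            stage_path(config, "select", "selection.rds")),
                 extra = list(clinical_variables = clin_vars),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

run_report <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  reports <- readRDS(require_artifact(
    stage_path(config, "evaluate", "reports.rds"), "evaluate"))
  dir.create(stage_path(config, "report"), showWarnings = FALSE,
             recursive = TRUE)
  n_osf <- length(reports$osf)
  n_clin <- length(reports$clinical_variables)
  row_of <- function(set, model, nfeat, r) {
    if (is.null(r)) return(NULL)
    data.frame(set = set, model = model, n_features = nfeat,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity, auc = round(r$auc, 2),
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, list(
    row_of("fine-tuning", "OSF", n_osf, reports$loo_osf),
    row_of("fine-tuning", "clinical", n_clin, reports$loo_clinical),
    row_of("fine-tuning", "OSF + clinical", n_osf + n_clin,
           reports$loo_osf_clinical),
    row_of("independent-test", "OSF", n_osf, reports$test_osf),
    row_of("independent-test", "OSF + clinical", n_osf + n_clin,
           reports$test_osf_clinical)))
  utils::write.csv(tab, stage_path(config, "report", "summary.csv"),
                   row.names = FALSE)
  md <- c("| Set | Model | N. features | Accuracy (%) | Sensitivity (%) | Specificity (%) | AUC |",
          "|---|---|---|---|---|---|---|",
          apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  writeLines(md, stage_path(config, "report", "summary.md"))
  for (nm in names(reports)[vapply(reports, inherits, TRUE, "eval_report")]) {
    utils::write.csv(reports[[nm]]$roc,
                     stage_path(config, "report", paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(reports$subtype_stratified)) {
    utils::write.csv(reports$subtype_stratified$per_subtype,
                     stage_path(config, "report", "subtype_metrics.csv"),
                     row.names = FALSE)
  }
  write_manifest(config, "report",
                 inputs = stage_path(config, "evaluate", "reports.rds"),
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(TRUE)
}

#' Run one stage (or all) of the synthetic end-to-end pipeline
#'
#' Stages hand artifacts to each other through plain files under
#' `config$outdir` (`<outdir>/<stage>/...`), each with a JSON manifest
#' (config echo, seed, input checksums, versions, wall-clock). Rerunning a
#' stage with unchanged inputs and config reproduces its primary outputs
#' byte for byte. A stage whose prerequisite artifact is missing stops with
#' the name of the stage to run first.
#'
#' @param stage one of `"simulate"`, `"segment"`, `"roi"`, `"extract"`,
#'   `"select"`, `"evaluate"`, `"report"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return `TRUE`, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "segment", "roi",
                                   "extract", "select", "evaluate", "report"),
                         config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "segment", "roi", "extract", "select", "evaluate",
              "report")
  todo <- if (stage == "all") stages else stage
  runners <- list(simulate = run_simulate, segment = run_segment,
                  roi = run_roi, extract = run_extract, select = run_select,
                  evaluate = run_evaluate, report = run_report)
  for (s in todo) runners[[s]](config)
  invisible(TRUE)
}
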