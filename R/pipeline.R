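#' Study configuration
#'
#' Collects every parameter of a full in-silico method-development study
#' into one serializable list. All randomness downstream flows from the
#' single `seed`.
#'
#' @param seed integer seed driving the whole study.
#' @param grid a [wavenumber_grid].
#' @param noise a [noise_model] for calibration/validation-set spectra.
#' @param levels calibration levels (percent of label).
#' @param total_mg calibration blend mass; `val_total_mg` validation blend
#'   mass.
#' @param val_total_mg validation blend total mass (mg).
#' @param cal_replicates,val_replicates vials per level per role.
#' @param repacks spectra averaged per sample.
#' @param plan a [preprocess_plan].
#' @param max_factors,cv_folds PLS factor search range and fold count.
#' @param n_components,score_quantile,resid_sd_mult PCA specificity
#'   settings.
#' @param study_levels,study_series,study_replicates intermediate-precision
#'   validation-study layout.
#' @param series_gain_sd between-series gain SD applied in the validation
#'   study (day-to-day effect).
#' @param beta,lambda accuracy-profile expectation proportion and
#'   acceptance limit (%).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 17,
                       grid = wavenumber_grid(),
                       noise = noise_model(),
                       levels = seq(80, 120, by = 5),
                       total_mg = 2053.64,
                       val_total_mg = 1026.82,
                       cal_replicates = 6, val_replicates = 3,
                       repacks = 3,
                       plan = dual_region_plan(),
                       max_factors = 8, cv_folds = 6,
                       n_components = 4, score_quantile = 0.999,
                       resid_sd_mult = 5,
                       study_levels = c(80, 100, 120),
                       study_series = 3, study_replicates = 3,
                       series_gain_sd = 0.003,
                       beta = 0.95, lambda = 5) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the complete in-silico QC study
#'
#' The full method-development and validation sequence for both APIs of
#' the capsule formulation:
#' \enumerate{
#'   \item generate the one-API-varied blend designs (calibration +
#'     external validation sets) and simulate their spectra;
#'   \item pre-process with the dual-region plan and calibrate one PLS1
#'     model per API, the factor count chosen by stratified
#'     venetian-blinds cross-validation;
#'   \item compute the merit table (factors, r, residual-error interval,
#'     RMSEC, RMSEP) from the calibration and external validation sets;
#'   \item fit one shared PCA identification model on all calibration
#'     spectra and challenge it with the specificity proof-set (placebo,
#'     10% DHA spike, pure APIs) plus genuine-composition spectra;
#'   \item simulate the multi-series validation study, predict contents
#'     and build the beta-expectation accuracy profile per API.
#' }
#' Deterministic given the config (the seed is set once on entry).
#'
#' @param config a [run_config].
#' @return A `study_report` list: `config`, `merit` (data.frame),
#'   `models`, `cv`, `pca`, `specificity` (verdict data.frame),
#'   `profiles` (per API), `summary` (flat list of headline numbers).
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  form <- hgc_formulation()
  lib <- default_library()
  apis <- c("AZ", "AS")

  cal_sets <- list(); val_sets <- list(); models <- list(); cvs <- list()
  merit <- list(); profiles <- list(); preprocs <- list()

  for (api in apis) {
    design <- blend_design(form, api, levels = config$levels,
                           total_mg = config$total_mg,
                           cal_replicates = config$cal_replicates,
                           val_replicates = config$val_replicates)
    cal <- simulate_set(design_table(design, "calibration"), form, lib,
                        config$grid, config$noise, config$repacks)
    val <- simulate_set(design_table(design, "validation"), form, lib,
                        config$grid, config$noise, config$repacks)
    pp <- apply_plan(cal, config$plan)
    ycol <- paste0("true_", api, "_pct")
    y_cal <- cal$meta[[ycol]]
    cv <- cross_validate(pp$features, y_cal, config$max_factors,
                         folds = config$cv_folds,
                         strata = cal$meta$level_percent)
    model <- fit_pls1(pp$features, y_cal, cv$selected)
    Xval <- apply_plan(val, pp)
    y_val <- val$meta[[ycol]]
    pred_val <- predict(model, Xval)
    ei <- error_interval(y_val, pred_val)
    merit[[api]] <- data.frame(
      api = api, n_factors = model$n_factors, r = model$r,
      error_min = ei[1], error_max = ei[2],
      rmsec = model$rmsec, rmsep = rmsep(y_val, pred_val))

    vt <- validation_table(design, levels = config$study_levels,
                           series = config$study_series,
                           replicates = config$study_replicates,
                           total_mg = config$val_total_mg)
    study_noise <- config$noise
    study_noise$series_gain_sd <- config$series_gain_sd
    vset <- simulate_set(vt, form, lib, config$grid, study_noise,
                         config$repacks)
    pred <- predict(model, apply_plan(vset, pp))
    vdata <- data.frame(level_percent = vset$meta$level_percent,
                        true_percent = vset$meta[[ycol]],
                        series_id = vset$meta$series_id,
                        replicate_id = vset$meta$replicate_id,
                        recovered_percent = pred)
    profiles[[api]] <- accuracy_profile(vdata, beta = config$beta,
                                        lambda = config$lambda)
    cal_sets[[api]] <- cal; val_sets[[api]] <- val
    models[[api]] <- model; cvs[[api]] <- cv; preprocs[[api]] <- pp
  }

  # one shared identification model on all calibration spectra
  all_cal <- bind_spectra(cal_sets[["AZ"]], cal_sets[["AS"]])
  pp_id <- apply_plan(all_cal, config$plan)
  pca <- fit_pca(pp_id$features, n_components = config$n_components,
                 score_quantile = config$score_quantile,
                 resid_sd_mult = config$resid_sd_mult)
  chal <- simulate_challenges(lib, config$grid, config$noise,
                              config$repacks, repeats = 3)
  verdict_chal <- classify(pca, apply_plan(chal, pp_id))
  verdict_chal <- cbind(label = chal$meta$label, verdict_chal)
  genuine <- bind_spectra(val_sets[["AZ"]], val_sets[["AS"]])
  verdict_gen <- classify(pca, apply_plan(genuine, pp_id))

  merit <- do.call(rbind, merit)
  rownames(merit) <- NULL
  summary <- list(
    seed = config$seed,
    r_min = min(merit$r),
    rmsec_max = max(merit$rmsec),
    rmsep_max = max(merit$rmsep),
    challenge_rejection_rate = mean(!verdict_chal$accept),
    genuine_acceptance_rate = mean(verdict_gen$accept),
    pc12_explained = pca$cum_explained[2],
    max_abs_tolerance_limit = max(vapply(profiles, function(p)
      max(abs(c(p$table$lower, p$table$upper))), numeric(1))),
    profiles_pass = all(vapply(profiles, `[[`, logical(1), "pass")))

  structure(list(config = config, merit = merit, models = models,
                 cv = cvs, preprocessors = preprocs,
                 id_preprocessor = pp_id, pca = pca,
                 specificity = list(challenges = verdict_chal,
                                    genuine = verdict_gen),
                 profiles = profiles, summary = summary),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("NIR QC study report (seed ", x$config$seed, ")\n\n", sep = "")
  cat("Merit table:\n")
  m <- x$merit
  m$r <- round(m$r, 4)
  m[c("error_min", "error_max", "rmsec", "rmsep")] <-
    round(m[c("error_min", "error_max", "rmsec", "rmsep")], 3)
  print(m, row.names = FALSE)
  cat(sprintf("\nSpecificity: %.0f%% of challenges rejected, %.1f%% of genuine samples accepted\n",
              100 * x$summary$challenge_rejection_rate,
              100 * x$summary$genuine_acceptance_rate))
  cat(sprintf("PC1+PC2 explained variance: %.3f%%\n", x$summary$pc12_explained))
  for (api in names(x$profiles)) {
    cat("\n", api, " ", sep = "")
    print(x$profiles[[api]])
  }
  invisible(x)
}

#' Write/read a spectra set as CSV
#'
#' Wide CSV with `wavenumber_cm1` as first column and one column per
#' sample (12 significant digits), plus a companion metadata CSV keyed by
#' sample label.
#'
#' @param spectra a [spectra_set].
#' @param path spectra CSV path.
#' @param meta_path optional metadata CSV path.
#' @return `read_spectra_csv` returns a [spectra_set].
#' @export
write_spectra_csv <- function(spectra, path, meta_path = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(wavenumber_cm1 = spectra$grid$points,
                   t(spectra$absorbance), check.names = FALSE)
  dfc <- cbind(df[1], lapply(df[-1], function(x) format(x, digits = 12)))
  utils::write.csv(dfc, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path))
    utils::write.csv(spectra$meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm1")
    stop("malformed spectra CSV: first column must be wavenumber_cm1 (line 1)",
         call. = FALSE)
  nu <- df[[1]]
  sp <- diff(nu)
  if (any(abs(sp - sp[1]) > 1e-9))
    stop("malformed spectra CSV: wavenumber grid not uniform", call. = FALSE)
  grid <- wavenumber_grid(nu[1], nu[length(nu)], sp[1])
  A <- t(as.matrix(df[-1]))
  meta <- if (!is.null(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(sample = colnames(df)[-1], stringsAsFactors = FALSE)
  }
  spectra_set(grid, A, meta)
}

#' Write a machine-readable study report
#'
#' JSON summary (config echo, merit figures, specificity rates, profile
#' verdicts) plus CSVs of the merit table and per-API accuracy-profile
#' tables, under one directory.
#'
#' @param report a `study_report` from [run_full_study()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(report$config)
  cfg$grid <- list(start = min(cfg$grid$points), stop = max(cfg$grid$points),
                   spacing = cfg$grid$spacing)
  cfg$noise <- unclass(cfg$noise)
  cfg$plan <- unclass(cfg$plan)
  out <- list(schema_version = "1.0",
              r_version = as.character(getRversion()),
              config = cfg,
              summary = report$summary,
              profiles = lapply(report$profiles, function(p)
                list(pass = p$pass, beta = p$beta, lambda = p$lambda,
                     table = p$table)))
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$merit, file.path(dir, "merit.csv"),
                   row.names = FALSE)
  for (api in names(report$profiles))
    utils::write.csv(report$profiles[[api]]$table,
                     file.path(dir, sprintf("profile_%s.csv", api)),
                     row.names = FALSE)
  invisible(dir)
}
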