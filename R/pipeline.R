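#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], filled with
#' the package defaults: the bundled synthetic reference and BMI tables, a
#' simulated cohort per sex, degree-5 mean curves, and a reduced-cost
#' training schedule (2000 iterations with the learning rate scaled so
#' `learning_rate * iterations` matches the full schedule; see the
#' vignette).
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed; every stochastic stage derives its seed from
#'   this one.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(out_dir = tempfile("staturecast_run_"),
                               seed = 1L) {
  ext <- function(f) system.file("extdata", f, package = "staturecast")
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    reference = list(male = ext("reference_0sd_male_synthetic.csv"),
                     female = ext("reference_0sd_female_synthetic.csv")),
    bmi_path = ext("standard_bmi_synthetic.csv"),
    cohort_path = NULL,              # NULL: simulate
    degree = 5L,
    split_ratio = 0.75,
    thresholds = c(1, 2, 3),
    mlp = list(hidden_units = 100L, iterations = 2000L,
               learning_rate = 5e-5 * 46000 / 2000, band = 0.5),
    sim = list(n_subjects = 200L, n_visits = 2L)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults from
#' [default_run_config()]; nested keys (`mlp`, `sim`, `reference`) are
#' merged element-wise.
#'
#' @param path YAML file path.
#' @param out_dir,seed Defaults passed to [default_run_config()] when the
#'   file does not set them.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, out_dir = tempfile("staturecast_run_"),
                            seed = 1L) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(out_dir = out_dir, seed = seed)
  for (k in names(user)) {
    if (k %in% c("mlp", "sim", "reference") && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full prediction workflow
#'
#' Composes the package end to end, mirroring the method's order of
#' operations: fit the per-sex mean growth curves to the reference tables;
#' obtain a cohort (from CSV, or simulated); train the per-sex adult-height
#' networks on a 3:1 train/validation split; predict adult heights for the
#' validation children; register a personal curve for each using the first
#' visit plus the predicted adult height; predict the stage height at the
#' next visit's age; and evaluate both adult and stage predictions.
#'
#' @param config A `run_config` list (see [default_run_config()]).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a manifest list: artifact paths with MD5 checksums,
#'   the resolved config, and the evaluation summaries (`adult`, `stage`,
#'   per sex).  All artifacts are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  sexes <- c("male", "female")

  curves <- run_stage("fit-reference", {
    out <- lapply(sexes, function(sx) {
      ref <- load_reference_table(config$reference[[sx]], sx)
      cv <- fit_mean_curve(ref, degree = config$degree)
      write_mean_curve(cv, art(paste0("meancurve_", sx, ".json")))
      say("fit-reference: %s degree-%d curve, RMSE %.3f cm", sx,
          cv$degree, cv$fit_rmse)
      cv
    })
    names(out) <- sexes
    out
  })

  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort_path)) {
      df <- load_cohort(config$cohort_path)
      if (!"visit" %in% names(df))
        df$visit <- stats::ave(df$age, df$subject_id,
                               FUN = function(a) rank(a, ties.method = "first"))
      say("cohort: read %d rows from %s", nrow(df), config$cohort_path)
      df
    } else {
      parts <- lapply(seq_along(sexes), function(i) {
        sim <- do.call(simulation_config, c(
          list(sex = sexes[i], seed = config$seed + i), config$sim))
        sc <- simulate_cohort(sim, curves[[sexes[i]]])
        cohort_frame(sc)
      })
      df <- do.call(rbind, parts)
      utils::write.csv(df, art("cohort.csv"), row.names = FALSE)
      say("cohort: simulated %d rows (%d subjects)", nrow(df),
          length(unique(df$subject_id)))
      df
    }
  })

  bmi_tabs <- run_stage("bmi-table", {
    out <- lapply(sexes, function(sx) load_bmi_table(config$bmi_path, sx))
    names(out) <- sexes
    out
  })

  adult_eval <- list(); stage_rows <- list(); curve_rows <- list()
  for (sx in sexes) {
    first <- cohort[cohort$sex == sx & cohort$visit == 1 &
                      !is.na(cohort$adult_height), , drop = FALSE]
    if (nrow(first) < 8L) stopf("pipeline stage 'train': too few %s subjects", sx)
    split <- run_stage("split", split_train_validation(
      first, ratio = config$split_ratio, seed = config$seed + 11L))

    model <- run_stage("train", {
      cfg <- mlp_config(sex = sx,
                        hidden_units = config$mlp$hidden_units,
                        learning_rate = config$mlp$learning_rate,
                        iterations = config$mlp$iterations,
                        band = config$mlp$band,
                        seed = config$seed + 101L)
      X <- build_feature_matrix(split$train, bmi_tabs[[sx]])
      m <- train_adult_height_mlp(X, split$train$adult_height, cfg)
      write_mlp_model(m, art(paste0("model_", sx, ".json")))
      say("train: %s model, %d iterations, final band loss %.3f",
          sx, cfg$iterations, m$final_loss)
      m
    })

    val <- split$validation
    pred_adult <- run_stage("predict-adult", {
      predict_adult_height(model, build_feature_matrix(val, bmi_tabs[[sx]]))
    })
    adult_eval[[sx]] <- summarize_errors(pred_adult, val$adult_height,
                                         config$thresholds)

    run_stage("fit-curve", {
      second <- cohort[cohort$sex == sx & cohort$visit == 2, , drop = FALSE]
      second <- second[match(val$subject_id, second$subject_id), , drop = FALSE]
      keep <- which(!is.na(second$subject_id))
      for (j in keep) {
        pc <- fit_personal_curve(
          data.frame(age = val$age[j], height = val$height[j]),
          pred_adult[j], curves[[sx]])
        curve_rows[[length(curve_rows) + 1L]] <- data.frame(
          subject_id = val$subject_id[j], sex = sx, alpha = pc$alpha,
          beta = pc$beta, gamma = pc$gamma, objective = pc$objective)
        stage_rows[[length(stage_rows) + 1L]] <- data.frame(
          subject_id = val$subject_id[j], sex = sx,
          target_age = second$age[j],
          target_height = second$height[j],
          prediction_height = predict_stage_height(pc, second$age[j]))
      }
    })
  }

  report <- run_stage("evaluate", {
    curves_df <- do.call(rbind, curve_rows)
    utils::write.csv(curves_df, art("curves.csv"), row.names = FALSE)
    preds <- deviation_table(do.call(rbind, stage_rows))
    utils::write.csv(preds, art("predictions.csv"), row.names = FALSE)
    stage_eval <- lapply(sexes, function(sx) {
      p <- preds[preds$sex == sx, ]
      summarize_errors(p$prediction_height, p$target_height,
                       config$thresholds)
    })
    names(stage_eval) <- sexes
    rep <- list(
      seed = config$seed,
      adult = lapply(adult_eval, function(s)
        list(n = s$n, mae = s$mae, rmse = s$rmse, max_abs = s$max_abs,
             within = as.list(s$within))),
      stage = lapply(stage_eval, function(s)
        list(n = s$n, mae = s$mae, rmse = s$rmse, max_abs = s$max_abs,
             within = as.list(s$within))))
    jsonlite::write_json(rep, art("report.json"), auto_unbox = TRUE,
                         digits = NA)
    say("evaluate: stage MAE %.2f (male) / %.2f (female) cm",
        stage_eval$male$mae, stage_eval$female$mae)
    list(adult = adult_eval, stage = stage_eval)
  })

  cfg_out <- config
  cfg_out$reference <- lapply(cfg_out$reference, normalizePath)
  yaml::write_yaml(unclass(cfg_out), art("config.yaml"))
  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- list(out_dir = config$out_dir, seed = config$seed,
                   artifacts = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  invisible(list(manifest = manifest, config = config,
                 adult = report$adult, stage = report$stage,
                 curves = curves))
}
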