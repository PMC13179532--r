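#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the input mode (simulate a
#' cohort or ingest OpenFace-dialect CSVs), the response-model
#' parameters for simulation, the train/validation split rule (80% of
#' the toddler trials train the mixture; the remaining toddler trials
#' and all infant trials are validation -- infant data are never used
#' for training), the feature-extraction delay, the EM protocol template
#' and the base seed.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param n_infants,n_toddlers Cohort sizes in simulate mode (defaults:
#'   28 infants, 30 toddlers, 10 trials each).
#' @param infant_params,toddler_params [response_model_params()]
#'   overrides for simulate mode (defaults: the group defaults).
#' @param features_csv,stimulus_csv Input paths for ingest mode.
#' @param split_unit `"trial"` (default) or `"participant"`.
#' @param split_fraction Fraction of toddler data used for training.
#' @param offset_s Feature-extraction delay after onset (default 2 s).
#' @param tol_s Frame-matching tolerance (default: half a frame
#'   interval).
#' @param flip_yaw Negate horizontal coordinates on ingest (for mirrored
#'   OpenFace output).
#' @param conflict_policy Head/gaze combination conflict policy.
#' @param em An [em_config()] template; the seed is re-derived per
#'   feature set and the sign-opposition criterion is disabled for the
#'   PCA feature set.
#' @param seed Base seed for all randomness.
#' @param out_dir If non-`NULL`, reports and tables are written there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            n_infants = 28L, n_toddlers = 30L,
                            infant_params = NULL, toddler_params = NULL,
                            features_csv = NULL, stimulus_csv = NULL,
                            split_unit = c("trial", "participant"),
                            split_fraction = 0.8,
                            offset_s = 2, tol_s = NULL, flip_yaw = FALSE,
                            conflict_policy = c("gaze", "head", "centre"),
                            em = em_config(), seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  split_unit <- match.arg(split_unit)
  conflict_policy <- match.arg(conflict_policy)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_input("'split_fraction' must be in (0, 1)")
  }
  if (mode == "ingest") {
    if (is.null(features_csv) || is.null(stimulus_csv)) {
      stop_input("ingest mode requires 'features_csv' and 'stimulus_csv'")
    }
    missing <- c(features_csv, stimulus_csv)[!file.exists(c(features_csv, stimulus_csv))]
    if (length(missing)) stop_input("input file(s) not found: ",
                                    paste(missing, collapse = ", "))
  }
  structure(
    list(mode = mode, n_infants = as.integer(n_infants),
         n_toddlers = as.integer(n_toddlers),
         infant_params = infant_params %||% response_model_params("infant"),
         toddler_params = toddler_params %||% response_model_params("toddler"),
         features_csv = features_csv, stimulus_csv = stimulus_csv,
         split_unit = split_unit, split_fraction = split_fraction,
         offset_s = offset_s, tol_s = tol_s, flip_yaw = isTRUE(flip_yaw),
         conflict_policy = conflict_policy, em = em,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# Simulate the whole cohort; returns frames (named list) + schedule.
simulate_cohort <- function(config) {
  ids <- c(sprintf("I%02d", seq_len(config$n_infants)),
           sprintf("T%02d", seq_len(config$n_toddlers)))
  groups <- rep(c("infant", "toddler"), c(config$n_infants, config$n_toddlers))
  frames <- list()
  schedules <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    params <- if (groups[i] == "infant") config$infant_params else config$toddler_params
    s <- simulate_session(ids[i], groups[i], params,
                          seed = derive_seed(config$seed, i * 1000L))
    frames[[ids[i]]] <- s$frames
    schedules[[i]] <- s$schedule
  }
  schedule <- do.call(rbind, schedules)
  class(schedule) <- c("stimulus_schedule", "data.frame")
  list(frames = frames, schedule = schedule)
}

# Seeded train/validation split of the valid toddler trials.
split_training <- function(trial_table, config) {
  valid <- which(trial_table$valid)
  toddler_valid <- valid[trial_table$group[valid] == "toddler"]
  infant_valid <- valid[trial_table$group[valid] == "infant"]
  train <- withr::with_seed(derive_seed(config$seed, 555L), {
    if (config$split_unit == "trial") {
      n_train <- round(config$split_fraction * length(toddler_valid))
      sort(sample(toddler_valid, n_train))
    } else {
      pids <- unique(trial_table$participant_id[toddler_valid])
      train_pids <- sample(pids, round(config$split_fraction * length(pids)))
      sort(toddler_valid[trial_table$participant_id[toddler_valid] %in% train_pids])
    }
  })
  list(training = train,
       validation_toddler = setdiff(toddler_valid, train),
       validation_infant = infant_valid)
}

pipeline_splits <- function() c("training", "validation_toddler", "validation_infant")

#' Run the full detection pipeline
#'
#' End-to-end orchestration: simulate or ingest sessions, extract the
#' single analysis frame per trial, split the toddler trials into
#' training and validation (infant trials are validation only, by
#' construction), fit the PCA and the three-cluster mixture per feature
#' set, label clusters as left/centre/right, predict every split, and
#' assemble contingency tables, correct-decision rates, exact binomial
#' tests, cross-feature-set averages and the head/gaze decision
#' combination. Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `latreact_run`: `report` (plain list, written
#'   as JSON when `out_dir` is set), `tables` (nested
#'   `[[feature_set]][[split]]` of [direction_table()]s), `models`,
#'   `labellings`, `pca`, `split` (row indices), `trial_table`,
#'   `timecourse`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- if (config$mode == "simulate") {
    simulate_cohort(config)
  } else {
    read_session(config$features_csv, config$stimulus_csv)
  }
  trial_table <- build_trial_table(data$frames, data$schedule,
                                   offset_s = config$offset_s,
                                   tol_s = config$tol_s,
                                   flip_yaw = config$flip_yaw)
  timecourse <- mean_abs_yaw_timecourse(data$frames, data$schedule)
  split <- split_training(trial_table, config)
  if (length(split$training) < 3L) {
    stop_input("stage split: fewer than 3 valid toddler training trials")
  }
  train_rows <- trial_table[split$training, ]
  pca <- suppressWarnings(fit_pca(train_rows))

  models <- list(); labellings <- list(); tables <- list()
  predictions <- list(); fs_stats <- list()
  for (fs in feature_sets()) {
    cfg <- config$em
    cfg$seed <- derive_seed(config$seed, 37L * match(fs, feature_sets()))
    if (fs == "pca2") cfg$apply_sign_criterion <- FALSE
    x_train <- select_feature_matrix(train_rows, fs, pca)
    model <- fit_gmm3(x_train, cfg)
    labelling <- label_clusters(model, x_train, train_rows$side)
    models[[fs]] <- model
    labellings[[fs]] <- labelling
    tables[[fs]] <- list(); predictions[[fs]] <- list(); fs_stats[[fs]] <- list()
    for (sp in pipeline_splits()) {
      rows <- trial_table[split[[sp]], ]
      preds <- if (nrow(rows)) {
        predict_direction(model, labelling,
                          select_feature_matrix(rows, fs, pca))
      } else {
        factor(character(0L), levels = direction_levels())
      }
      tab <- direction_table(preds, rows$side, split = sp, feature_set = fs)
      tables[[fs]][[sp]] <- tab
      predictions[[fs]][[sp]] <- preds
      nd <- n_decisions(tab)
      fs_stats[[fs]][[sp]] <- list(
        n_trials = as.integer(sum(tab)),
        n_decisions = nd,
        n_correct = n_correct(tab),
        specificity = correct_decision_rate(tab),
        specificity_pct = if (nd > 0L) round(100 * correct_decision_rate(tab)) else NA,
        p_one_sided = if (nd > 0L) signif(binom_p_one_sided(n_correct(tab), nd), 3L) else NA,
        decision_rate = decision_rate(tab),
        n_restarts_used = model$n_restarts_used,
        criterion_met = model$criterion_met
      )
    }
  }

  averages <- lapply(stats::setNames(nm = pipeline_splits()), function(sp) {
    suppressWarnings(
      average_correct_rate(lapply(tables, function(t) t[[sp]]))
    )
  })

  combination <- lapply(
    stats::setNames(nm = c("validation_toddler", "validation_infant")),
    function(sp) {
      comb <- combine_decisions(predictions$head_rot[[sp]],
                                predictions$gaze_angle[[sp]],
                                conflict = config$conflict_policy)
      rows <- trial_table[split[[sp]], ]
      tab <- direction_table(comb$predictions, rows$side,
                             split = sp, feature_set = "head_plus_gaze")
      c(comb$stats, list(
        n_correct = n_correct(tab),
        specificity = correct_decision_rate(tab)
      ))
    }
  )

  report <- list(
    seed = config$seed,
    mode = config$mode,
    config = config_echo(config),
    n_trials = nrow(trial_table),
    n_valid = sum(trial_table$valid),
    n_invalid = sum(!trial_table$valid),
    n_valid_by_group = as.list(table(trial_table$group[trial_table$valid])),
    split_sizes = lapply(split, length),
    feature_sets = fs_stats,
    average_correct_rate_pct = averages,
    combination = combination
  )

  run <- structure(
    list(report = report, tables = tables, models = models,
         labellings = labellings, predictions = predictions, pca = pca,
         split = split, trial_table = trial_table, timecourse = timecourse,
         config = config),
    class = "latreact_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run)
  invisible(run)
}

# Config echo for the report: plain values only, stable ordering.
config_echo <- function(config) {
  list(
    mode = config$mode,
    n_infants = config$n_infants, n_toddlers = config$n_toddlers,
    split_unit = config$split_unit, split_fraction = config$split_fraction,
    offset_s = config$offset_s, flip_yaw = config$flip_yaw,
    conflict_policy = config$conflict_policy,
    em = unclass(config$em),
    infant_params = unclass(config$infant_params),
    toddler_params = unclass(config$toddler_params)
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_echo(config), tmp)
  unname(tools::md5sum(tmp))
}

# Write trial CSV, model JSONs, direction TSV, report JSON and run log.
write_run_outputs <- function(run) {
  out <- run$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  feat_cols <- openface_feature_columns()
  trial_csv <- run$trial_table[, c("participant_id", "group", "trial_index",
                                   "stimulus", "side", "valid", feat_cols)]
  names(trial_csv)[seq_along(feat_cols) + 6L] <- sprintf("f%02d", seq_along(feat_cols))
  utils::write.csv(trial_csv, file.path(out, "trial_features.csv"),
                   row.names = FALSE)
  for (fs in names(run$models)) {
    write_gmm3_json(run$models[[fs]], file.path(out, paste0("model_", fs, ".json")))
  }
  make_direction_tsv(run, file.path(out, "direction_tables.tsv"))
  utils::write.csv(run$timecourse, file.path(out, "yaw_timecourse.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_lines <- c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config hash: %s", config_hash(run$config)),
    sprintf("seed: %d", run$config$seed),
    if (run$config$mode == "ingest") {
      paste0("input md5: ",
             paste(tools::md5sum(c(run$config$features_csv,
                                   run$config$stimulus_csv)), collapse = " "))
    },
    vapply(names(run$models), function(fs) {
      sprintf("feature set %s: restarts=%d criterion_met=%s loglik=%.4f",
              fs, run$models[[fs]]$n_restarts_used,
              run$models[[fs]]$criterion_met, run$models[[fs]]$loglik)
    }, character(1L))
  )
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(out)
}

#' Write the direction contingency tables as a single TSV
#'
#' Layout mirrors the study's summary table: one row per feature set and
#' predicted class, with left/right-speaker counts for the training,
#' toddler-validation and infant-validation splits side by side.
#'
#' @param run A [run_pipeline()] result, or a nested
#'   `[[feature_set]][[split]]` list of [direction_table()]s.
#' @param path Output TSV path.
#' @return The table written, invisibly (as a `data.frame`).
#' @export
make_direction_tsv <- function(run, path) {
  tables <- if (inherits(run, "latreact_run")) run$tables else run
  if (inherits(run, "latreact_run")) {
    missing <- setdiff(feature_sets(), names(tables))
    if (length(missing)) {
      stop_input("incomplete run: missing feature set(s) ",
                 paste(missing, collapse = ", "))
    }
  }
  rows <- list()
  for (fs in names(tables)) {
    for (cl in direction_levels()) {
      row <- list(feature_set = fs, class = cl)
      for (sp in names(tables[[fs]])) {
        tab <- tables[[fs]][[sp]]
        row[[paste0(sp, "_left")]] <- tab[cl, "left"]
        row[[paste0(sp, "_right")]] <- tab[cl, "right"]
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(feature_set = character(0L), class = character(0L))
  }
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Summarise validation statistics from direction tables
#'
#' Computes, for each feature set of one split, the decision counts,
#' the correct-decision rate ("specificity") and the exact one-sided
#' binomial p-value against guessing at 50%, plus the cross-feature-set
#' average rate. Works on any `[[feature_set]]` list of
#' [direction_table()]s, e.g. one split of [study_direction_tables()].
#'
#' @param tables Named list of [direction_table()]s (one split).
#' @return `data.frame` with one row per feature set plus attributes
#'   `average_pct`.
#' @export
validation_summary <- function(tables) {
  rows <- lapply(names(tables), function(fs) {
    tab <- tables[[fs]]
    nd <- n_decisions(tab)
    data.frame(
      feature_set = fs,
      n_trials = sum(tab),
      n_decisions = nd,
      n_correct = n_correct(tab),
      specificity_pct = if (nd > 0L) round(100 * correct_decision_rate(tab)) else NA,
      p_one_sided = if (nd > 0L) signif(binom_p_one_sided(n_correct(tab), nd), 3L) else NA,
      decision_rate = decision_rate(tab)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "average_pct") <- suppressWarnings(average_correct_rate(tables))
  out
}

#' @export
print.latreact_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("latreact run (seed %d, %s mode)\n", r$seed, r$mode))
  cat(sprintf("  trials: %d (%d valid, %d without an extraction frame)\n",
              r$n_trials, r$n_valid, r$n_invalid))
  cat(sprintf("  split: %d train / %d toddler validation / %d infant validation\n",
              r$split_sizes$training, r$split_sizes$validation_toddler,
              r$split_sizes$validation_infant))
  for (fs in names(r$feature_sets)) {
    s <- r$feature_sets[[fs]]$validation_infant
    cat(sprintf("  %-10s infant validation: %d/%d correct (%s%%), p = %s\n",
                fs, s$n_correct, s$n_decisions,
                format(s$specificity_pct), format(s$p_one_sided)))
  }
  cat(sprintf("  average correct-decision rate: toddler %s%%, infant %s%%\n",
              format(r$average_correct_rate_pct$validation_toddler),
              format(r$average_correct_rate_pct$validation_infant)))
  invisible(x)
}
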