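#' Configure an end-to-end shock-detection study
#'
#' Bundles every choice of the study protocol -- input source, segment
#' durations, patient split, algorithms, bootstrap size, selection method
#' and the master seed -- into a validated config. All randomness flows
#' from `seed` via fixed per-stage substreams, so a config reproduces its
#' results exactly.
#'
#' @param input either a corpus tibble, or a list
#'   `list(type = "synthetic", profile =, n_patients =, records_per_patient =)`,
#'   or `list(type = "csv"|"wfdb", dir =)`.
#' @param durations segment durations to analyze, subset of `c(4, 8)`.
#' @param split_prop fraction of patients for training.
#' @param algorithms classifier names (see [model_spec()]).
#' @param B bootstrap resamples for evaluation (study default 500).
#' @param selection selection methods to run: subset of
#'   `c("BSTsel", "L1LRsel")` (may be empty).
#' @param selection_B resamples for the selection bootstrap.
#' @param tune run hyperparameter tuning (otherwise defaults are used).
#' @param tune_grids optional named list of per-algorithm grid overrides.
#' @param rfe_hyper optional named list of per-method ranking
#'   hyperparameters for the selection bootstrap.
#' @param evaluate_subsets paired-compare each selected subset against all
#'   features for every algorithm.
#' @param single_feature also compute the per-feature threshold-classifier
#'   table.
#' @param seed master seed.
#' @param out_dir optional directory for result tables and the manifest.
#' @return a validated `shock_config`.
#' @export
study_config <- function(input = list(
                           type = "synthetic", profile = "public_like",
                           n_patients = 20, records_per_patient = 2
                         ),
                         durations = c(4, 8), split_prop = 0.8,
                         algorithms = c("L1LR", "BAG", "RF", "BST", "SVM"),
                         B = 500, selection = c("BSTsel", "L1LRsel"),
                         selection_B = 100, tune = FALSE,
                         tune_grids = NULL, rfe_hyper = NULL,
                         evaluate_subsets = TRUE, single_feature = FALSE,
                         seed = 1, out_dir = NULL) {
  known <- c("L1LR", "BAG", "RF", "BST", "SVM")
  if (!all(algorithms %in% known)) {
    abort(
      paste(
        "unknown algorithm(s):",
        paste(setdiff(algorithms, known), collapse = ", ")
      ),
      class = "shockable_config_error"
    )
  }
  if (!all(durations %in% c(4, 8)) || !length(durations)) {
    abort("durations must be a subset of c(4, 8)",
      class = "shockable_config_error"
    )
  }
  if (!all(selection %in% c("BSTsel", "L1LRsel"))) {
    abort("unknown selection method", class = "shockable_config_error")
  }
  if (split_prop <= 0 || split_prop >= 1) {
    abort("split_prop must be in (0, 1)", class = "shockable_config_error")
  }
  if (is.list(input) && !is.data.frame(input)) {
    if (identical(input$type, "synthetic")) {
      rhythm_profile(input$profile) # validates the profile name
    } else if (input$type %in% c("csv", "wfdb")) {
      if (!dir.exists(input$dir)) {
        abort("input directory does not exist",
          class = "shockable_config_error"
        )
      }
    } else {
      abort("unknown input type", class = "shockable_config_error")
    }
  }
  structure(
    list(
      input = input, durations = durations, split_prop = split_prop,
      algorithms = algorithms, B = B, selection = selection,
      selection_B = selection_B, tune = tune, tune_grids = tune_grids,
      rfe_hyper = rfe_hyper, evaluate_subsets = evaluate_subsets,
      single_feature = single_feature, seed = seed, out_dir = out_dir
    ),
    class = "shock_config"
  )
}

# fixed substream offsets: every stage draws from seed + offset (the
# offsets stay far below .Machine$integer.max for small seeds)
stage_seed <- function(seed, stage, k = 0) {
  offs <- c(
    corpus = 101, split = 211, tune = 307, select = 401, fit = 503,
    boot = 601
  )
  as.integer(seed + offs[[stage]] + 1000L * k)
}

#' Run the full study protocol
#'
#' Executes preprocess, segment/label, feature extraction, patient split,
#' standardization, (optional) tuning, feature selection, training,
#' patient-wise bootstrap evaluation and subset-vs-all paired comparisons,
#' for every configured duration and algorithm. Any stage failure aborts
#' with the stage name attached; a partial manifest of completed stages is
#' included in the condition. Training/tuning/selection never see
#' test-patient rows (asserted).
#'
#' @param config a [study_config()].
#' @return a `shock_study` bundle: per-duration results plus the manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "shock_config"))
  done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(
        paste0("stage '", name, "' failed: ", conditionMessage(e)),
        class = "shockable_stage_error",
        stage = name, completed = done
      )
    })
    done <<- c(done, name)
    res
  }

  corpus <- stage("input", load_input(config))
  corpus <- stage("preprocess", preprocess_records(corpus))

  per_duration <- list()
  for (di in seq_along(config$durations)) {
    dur <- config$durations[di]
    labelled <- stage(
      paste0("segment_label_", dur, "s"),
      label_segments(segment_records(corpus, dur))
    )
    feats <- stage(
      paste0("features_", dur, "s"),
      extract_features(filter(labelled, .data$retained))
    )
    split <- stage(
      paste0("split_", dur, "s"),
      patient_split(feats, config$split_prop,
        seed = stage_seed(config$seed, "split")
      )
    )
    stopifnot(
      length(intersect(
        unique(split$train$patient_id),
        unique(split$test$patient_id)
      )) == 0
    )
    std <- standardize_features(split$train, split$test)
    train <- std$train
    test <- std$other

    specs <- list()
    for (ai in seq_along(config$algorithms)) {
      alg <- config$algorithms[ai]
      sp <- model_spec(alg)
      if (config$tune) {
        sp <- stage(
          paste0("tune_", alg, "_", dur, "s"),
          tune_model(sp, train,
            seed = stage_seed(config$seed, "tune", ai),
            grid = config$tune_grids[[alg]]
          )
        )
      }
      specs[[alg]] <- sp
    }

    selections <- list()
    for (si in seq_along(config$selection)) {
      meth <- config$selection[si]
      rfe <- stage(
        paste0("rfe_", meth, "_", dur, "s"),
        rfe_bootstrap(train, meth,
          B = config$selection_B,
          seed = stage_seed(config$seed, "select", si),
          hyper = config$rfe_hyper[[meth]] %||% list()
        )
      )
      selections[[meth]] <- one_se_subset(rfe)
      selections[[meth]]$rfe <- rfe
    }

    models <- list()
    boots <- list()
    preds <- list()
    for (ai in seq_along(config$algorithms)) {
      alg <- config$algorithms[ai]
      m <- stage(
        paste0("fit_", alg, "_", dur, "s"),
        fit_model(specs[[alg]], train,
          seed = stage_seed(config$seed, "fit", ai)
        )
      )
      pr <- bind_cols(
        test[c("patient_id", "label")],
        predict(m, test)
      )
      models[[alg]] <- m
      preds[[alg]] <- pr
      boots[[alg]] <- stage(
        paste0("bootstrap_", alg, "_", dur, "s"),
        bootstrap_metrics(pr,
          B = config$B,
          seed = stage_seed(config$seed, "boot")
        )
      )
    }

    subset_evals <- list()
    if (config$evaluate_subsets && length(selections)) {
      for (meth in names(selections)) {
        for (ai in seq_along(config$algorithms)) {
          alg <- config$algorithms[ai]
          key <- paste(meth, alg, sep = ".")
          subset_evals[[key]] <- stage(
            paste0("subset_", key, "_", dur, "s"),
            evaluate_subset(
              train, test, selections[[meth]]$subset, specs[[alg]],
              B = config$B,
              seed = stage_seed(config$seed, "boot")
            )
          )
        }
      }
    }

    sft <- NULL
    if (config$single_feature) {
      sft <- stage(
        paste0("single_feature_", dur, "s"),
        single_feature_performance(train, test)
      )
    }

    per_duration[[as.character(dur)]] <- list(
      duration = dur, audit = segment_audit(labelled),
      n_segments = nrow(feats),
      train_patients = unique(split$train$patient_id),
      test_patients = unique(split$test$patient_id),
      specs = specs, models = models, boots = boots,
      predictions = preds, selections = selections,
      subset_evals = subset_evals, single_feature = sft
    )
  }

  bundle <- structure(
    list(
      config = config, results = per_duration,
      manifest = list(
        seed = config$seed, stages = done,
        package_version = as.character(utils::packageVersion("shockable")),
        timestamp = NULL # kept out of the manifest: reruns must be identical
      )
    ),
    class = "shock_study"
  )
  if (!is.null(config$out_dir)) write_study(bundle, config$out_dir)
  bundle
}

load_input <- function(config) {
  input <- config$input
  if (is.data.frame(input)) return(input)
  switch(input$type,
    synthetic = gen_corpus(
      input$profile %||% "public_like",
      n_patients = input$n_patients %||% 20,
      records_per_patient = input$records_per_patient %||% 2,
      seed = stage_seed(config$seed, "corpus")
    ),
    csv = {
      files <- list.files(input$dir, pattern = "\\.csv$", full.names = TRUE)
      files <- files[!grepl("\\.ann\\.csv$", files)]
      bind_rows(lapply(files, function(f) {
        read_record_csv(f, patient_id = sub("\\.csv$", "", basename(f)))
      }))
    },
    wfdb = {
      names <- sub(
        "\\.hea$", "",
        list.files(input$dir, pattern = "\\.hea$")
      )
      bind_rows(lapply(names, function(nm) read_record_wfdb(input$dir, nm)))
    }
  )
}

write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  perf <- report_study(bundle)$performance
  readr::write_csv(perf, file.path(dir, "performance.csv"))
  for (dur in names(bundle$results)) {
    res <- bundle$results[[dur]]
    for (alg in names(res$boots)) {
      readr::write_csv(
        res$boots[[alg]]$metrics,
        file.path(dir, sprintf("bootstrap_%s_%ss.csv", alg, dur))
      )
    }
    for (meth in names(res$selections)) {
      readr::write_csv(
        res$selections[[meth]]$curve,
        file.path(dir, sprintf("selection_curve_%s_%ss.csv", meth, dur))
      )
    }
  }
  cfg <- bundle$config
  cfg$out_dir <- NULL
  manifest <- list(
    config = cfg[!vapply(cfg, is.function, logical(1))],
    manifest = bundle$manifest
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"
  )
  invisible(dir)
}

#' Summarise a study bundle into report tables
#'
#' Produces the standard report layouts: per-algorithm bootstrap
#' performance (Se/Sp printed to one decimal; the BER identity
#' `BER = 100 - (Se + Sp)/2` is re-verified on every row at print time),
#' selected subsets per method in decreasing selection-count order, the
#' BER-versus-subset-size curves, and the single-feature table when
#' computed. Incomplete bundles list their missing stages instead.
#'
#' @param bundle a `shock_study`.
#' @return list of tibbles: `performance`, `subsets`, `ber_curves`,
#'   `single_feature`, `comparisons`.
#' @export
report_study <- function(bundle) {
  stopifnot(inherits(bundle, "shock_study"))
  perf <- purrr::map_dfr(bundle$results, function(res) {
    purrr::map_dfr(names(res$boots), function(alg) {
      # means over complete resamples only, so the BER identity carries
      # over from the per-resample level to the reported row
      m <- res$boots[[alg]]$metrics
      m <- m[stats::complete.cases(m[, c("se", "sp", "ber")]), ]
      row <- tibble(
        duration = res$duration, algorithm = alg,
        se = mean(m$se), sp = mean(m$sp), ber = mean(m$ber),
        ber_sd = sd(m$ber)
      )
      stopifnot(abs(row$ber - (100 - (row$se + row$sp) / 2)) < 1e-6)
      row
    })
  })
  subsets <- purrr::map_dfr(bundle$results, function(res) {
    purrr::map_dfr(names(res$selections), function(meth) {
      sel <- res$selections[[meth]]
      tibble(
        duration = res$duration, method = meth, K_s = sel$K_s,
        subset = paste(sel$subset, collapse = ", ")
      )
    })
  })
  curves <- purrr::map_dfr(bundle$results, function(res) {
    purrr::map_dfr(names(res$selections), function(meth) {
      mutate(res$selections[[meth]]$curve,
        duration = res$duration,
        method = meth, .before = 1
      )
    })
  })
  comparisons <- purrr::map_dfr(bundle$results, function(res) {
    purrr::map_dfr(names(res$subset_evals), function(key) {
      ev <- res$subset_evals[[key]]
      tibble(
        duration = res$duration, comparison = key,
        delta_ber = ev$comparison$mean,
        ci_lo = ev$comparison$ci[1], ci_hi = ev$comparison$ci[2],
        significant = ev$comparison$significant
      )
    })
  })
  single <- purrr::map_dfr(bundle$results, function(res) {
    if (is.null(res$single_feature)) return(tibble())
    mutate(res$single_feature, duration = res$duration, .before = 1)
  })
  list(
    performance = mutate(perf,
      se = round(.data$se, 1), sp = round(.data$sp, 1),
      ber = round(.data$ber, 1)
    ),
    subsets = subsets, ber_curves = curves, comparisons = comparisons,
    single_feature = single
  )
}

#' @export
print.shock_study <- function(x, ...) {
  cat(
    "<shock_study> durations:",
    paste(names(x$results), collapse = "/"),
    "s | algorithms:",
    paste(x$config$algorithms, collapse = ", "), "\n"
  )
  print(report_study(x)$performance)
  invisible(x)
}
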