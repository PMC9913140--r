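#' Run configuration for the end-to-end experiment
#'
#' Assembles and validates every stage's parameters.  Desk-scale defaults: a
#' synthetic 100x-like dataset at one-tenth scale, median window 3, CLAHE,
#' 32x32 extractor input, a small hyperparameter-search budget, and shortened
#' DBN epochs; `splits` follows the standard 80:20 and 70:30 protocol.
#'
#' @param data Either `list(dir = "path")` for a directory with PNGs and
#'   `labels.csv`, or a synthetic spec:
#'   `list(magnification, scale, difficulty, size, impulse_rate,
#'   contrast_scale)` (all optional).
#' @param preprocess `list(median_window, contrast, clip_limit, tile)`.
#' @param extractor An [extractor_config()].
#' @param tune `list(enabled, n_pop, max_iter, space)`; `space = NULL` uses
#'   the default space (head learning rate, head epochs, squeeze ratio, head
#'   dropout).
#' @param dbn A [train_config()].
#' @param splits Character vector of ratios, default `c("80:20", "70:30")`.
#' @param seed Root seed; every stage draws from a named substream of it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(data = list(), preprocess = list(),
                       extractor = extractor_config(),
                       tune = list(), dbn = NULL,
                       splits = c("80:20", "70:30"), seed = 0) {
  data <- utils::modifyList(
    list(dir = NULL, magnification = "100x", scale = 0.1,
         difficulty = "easy", size = 64, impulse_rate = 0.05,
         contrast_scale = 0.6),
    data)
  preprocess <- utils::modifyList(
    list(median_window = 3, contrast = "clahe", clip_limit = 0.01, tile = 8),
    preprocess)
  tune <- utils::modifyList(
    list(enabled = TRUE, n_pop = 6, max_iter = 5, space = NULL), tune)
  dbn <- dbn %||% train_config(epochs = 10, finetune_epochs = 15,
                               batch_size = 5, learning_rate = 0.01,
                               dropout = 0.5)
  stopifnot(inherits(extractor, "extractor_config"),
            inherits(dbn, "train_config"))
  if (!all(grepl("^\\d+:\\d+$", splits))) {
    abort("`splits` must look like \"80:20\".", class = "histodbn_parameter_error")
  }
  structure(list(data = data, preprocess = preprocess, extractor = extractor,
                 tune = tune, dbn = dbn, splits = splits,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `extractor` and
#' `dbn` blocks are passed to [extractor_config()] / [train_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ex <- if (!is.null(y$extractor)) do.call(extractor_config, y$extractor)
        else extractor_config()
  db <- if (!is.null(y$dbn)) do.call(train_config, y$dbn) else NULL
  run_config(data = y$data %||% list(), preprocess = y$preprocess %||% list(),
             extractor = ex, tune = y$tune %||% list(), dbn = db,
             splits = y$splits %||% c("80:20", "70:30"), seed = y$seed %||% 0)
}

# default hyperparameter space for the extractor-plus-head objective
default_search_space <- function() {
  search_space(
    space_dim("learning_rate", "log", -3, -1),
    space_dim("head_epochs", "int", 3, 12),
    space_dim("squeeze_ratio", "real", 0.15, 0.6),
    space_dim("head_dropout", "real", 0, 0.6)
  )
}

# rebuild an extractor config with squeeze widths = ratio * expand_total
apply_squeeze_ratio <- function(config, ratio) {
  fires <- purrr::map(config$fire_configs, function(fc) {
    s <- clamp(round_half_up(ratio * fc$expand_total), 1, fc$expand_total - 1L)
    fire_config(s, fc$expand_1x1, fc$expand_3x3)
  })
  extractor_config(input_size = config$input_size,
                   stem_channels = config$stem_channels,
                   fire_configs = fires,
                   pool_positions = config$pool_positions, seed = config$seed)
}

# train a softmax head on features with Adamax; returns val error rate
head_fitness <- function(tr_X, tr_y, va_X, va_y, classes, learning_rate,
                         epochs, dropout, seed) {
  withr::with_seed(seed, {
    scaler <- fit_scaler(tr_X)
    Xtr <- apply_scaler(tr_X, scaler); Xva <- apply_scaler(va_X, scaler)
    W <- matrix(0, ncol(Xtr), length(classes)); b <- numeric(length(classes))
    Y <- one_hot(tr_y, classes)
    opt <- adamax_state(learning_rate = learning_rate)
    keep <- 1 - dropout
    n <- nrow(Xtr)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = 8)) {
        rows <- idx[start:min(start + 7L, n)]
        Xb <- Xtr[rows, , drop = FALSE]
        if (keep < 1) {
          Xb <- Xb * (matrix(runif(length(Xb)) < keep,
                             nrow(Xb), ncol(Xb)) / keep)
        }
        P <- softmax_rows(Xb %*% W + rep(b, each = nrow(Xb)))
        Yb <- Y[rows, , drop = FALSE]
        g <- list(W = t(Xb) %*% (P - Yb) / nrow(Xb), b = colMeans(P - Yb))
        st <- adamax_step_list(opt, list(W = W, b = b), g)
        opt <- st$state; W <- st$params$W; b <- st$params$b
      }
    }
    P <- softmax_rows(Xva %*% W + rep(b, each = nrow(Xva)))
    pred <- classes[max.col(P, ties.method = "first")]
    fitness_error_rate(pred, va_y)
  })
}

#' Run the full classification experiment
#'
#' Orchestrates the pipeline end to end: synthesize (or read) the image set,
#' preprocess (median filter + contrast enhancement), optionally tune the
#' feature extractor's hyperparameters with the population optimizer against
#' a held-out error-rate objective, extract fire-module features, train the
#' DBN classifier with Adamax for each split ratio, and assemble per-class
#' evaluation reports for the training and testing phases.
#'
#' Every random draw descends from `config$seed` through named substreams
#' (data, tuning, splits, DBN), so results are exactly reproducible and the
#' stages do not perturb one another.
#'
#' @param config A [run_config()].
#' @return A `histo_experiment`: list with `reports` (tibble: split, phase,
#'   class, metrics), `confusions`, `traces` (per-epoch error/loss),
#'   `scores` (raw class scores for ROC/PR export), `tuning` (log or NULL),
#'   `models`, `features`, `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(data = list(scale = 0.02),
#'                   tune = list(enabled = FALSE),
#'                   dbn = train_config(epochs = 2, finetune_epochs = 3))
#' ex <- run_experiment(cfg)
#' glance(ex)
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "data"
  result <- tryCatch({
    dataset <- if (!is.null(config$data$dir)) {
      read_labeled_images(config$data$dir)
    } else {
      make_breakhis_like(config$data$magnification, config$data$scale,
                         seed = substream_seed(config$seed, "data"),
                         difficulty = config$data$difficulty,
                         size = config$data$size,
                         impulse_rate = config$data$impulse_rate,
                         contrast_scale = config$data$contrast_scale)
    }
    labels <- dataset$labels$label
    stage <- "preprocess"
    imgs <- preprocess_images(dataset$images,
                              median_window = config$preprocess$median_window,
                              contrast = config$preprocess$contrast,
                              clip_limit = config$preprocess$clip_limit,
                              tile = config$preprocess$tile)
    stage <- "tune"
    extractor <- config$extractor
    tuning <- NULL
    head_lr <- config$dbn$learning_rate
    if (isTRUE(config$tune$enabled)) {
      space <- config$tune$space %||% default_search_space()
      tune_seed <- substream_seed(config$seed, "tune")
      # the objective scores candidates on a fixed validation fifth of the
      # data; feature extraction is memoized per decoded topology
      pool <- split_dataset(labels, ratio = 0.8, seed = tune_seed)
      cache <- new.env()
      classes <- levels(labels)
      objective <- function(hp) {
        ratio <- hp$squeeze_ratio %||% 0.25
        key <- paste0("r", paste(purrr::map_int(
          apply_squeeze_ratio(extractor, ratio)$fire_configs,
          "squeeze_1x1"), collapse = "-"))
        if (is.null(cache[[key]])) {
          cfg_i <- apply_squeeze_ratio(extractor, ratio)
          cache[[key]] <- extract_features(imgs, cfg_i)
        }
        feats <- cache[[key]]
        head_fitness(feats[pool$train, , drop = FALSE], labels[pool$train],
                     feats[pool$test, , drop = FALSE], labels[pool$test],
                     classes,
                     learning_rate = hp$learning_rate %||% 0.01,
                     epochs = hp$head_epochs %||% 5,
                     dropout = hp$head_dropout %||% 0.5,
                     seed = substream_seed(tune_seed, "head"))
      }
      tuned <- tune_hyperparameters(
        space, objective,
        aoa_config(n_pop = config$tune$n_pop, max_iter = config$tune$max_iter,
                   seed = tune_seed))
      tuning <- tuned
      if (!is.null(tuned$best$squeeze_ratio)) {
        extractor <- apply_squeeze_ratio(extractor, tuned$best$squeeze_ratio)
      }
      if (!is.null(tuned$best$learning_rate)) head_lr <- tuned$best$learning_rate
    }
    stage <- "extract"
    features <- extract_features(imgs, extractor)
    stage <- "classify"
    reports <- list(); confusions <- list(); traces <- list()
    scores <- list(); models <- list()
    for (ratio in config$splits) {
      sp <- split_dataset(labels, ratio = ratio,
                          seed = substream_seed(config$seed, paste0("split-", ratio)))
      dbn_cfg <- config$dbn
      dbn_cfg$seed <- substream_seed(config$seed, paste0("dbn-", ratio))
      tr_X <- features[sp$train, , drop = FALSE]
      te_X <- features[sp$test, , drop = FALSE]
      classes <- levels(labels)
      model <- dbn_model(c(ncol(tr_X), 64, 32), n_classes = length(classes),
                         classes = classes, seed = dbn_cfg$seed)
      model$scaler <- fit_scaler(tr_X)
      Xs <- apply_scaler(tr_X, model$scaler)
      model <- greedy_pretrain(model, Xs, dbn_cfg)
      model <- up_down_finetune(model, Xs, labels[sp$train], dbn_cfg,
                                val_data = apply_scaler(te_X, model$scaler),
                                val_labels = labels[sp$test])
      for (phase in c("training", "testing")) {
        X <- if (phase == "training") tr_X else te_X
        truth <- labels[if (phase == "training") sp$train else sp$test]
        prob <- predict(model, X, type = "prob")
        pred <- predict(model, X, type = "class")
        cm <- confusion_matrix(truth, pred, classes = classes)
        rep_tbl <- compute_report(cm)
        rep_tbl <- dplyr::bind_cols(
          tibble::tibble(split = ratio, phase = phase,
                         .rows = nrow(rep_tbl)), rep_tbl)
        key <- paste(ratio, phase)
        reports[[key]] <- rep_tbl
        confusions[[key]] <- cm
        scores[[key]] <- dplyr::bind_cols(
          tibble::tibble(split = ratio, phase = phase,
                         truth = as.character(truth)),
          tibble::as_tibble(prob))
      }
      traces[[ratio]] <- dplyr::bind_cols(
        tibble::tibble(split = ratio, .rows = nrow(model$finetune_log)),
        model$finetune_log)
      models[[ratio]] <- model
    }
    structure(list(reports = dplyr::bind_rows(reports),
                   confusions = confusions,
                   traces = dplyr::bind_rows(traces),
                   scores = dplyr::bind_rows(scores),
                   tuning = tuning, models = models, features = features,
                   labels = labels, config = config),
              class = "histo_experiment")
  }, histodbn_parameter_error = function(e) {
    abort(paste0("Stage `", stage, "` failed (config seed ", config$seed,
                 "): ", conditionMessage(e)),
          class = "histodbn_pipeline_error", parent = e)
  }, histodbn_structural_error = function(e) {
    abort(paste0("Stage `", stage, "` failed (config seed ", config$seed,
                 "): ", conditionMessage(e)),
          class = "histodbn_pipeline_error", parent = e)
  })
  result
}

#' @export
print.histo_experiment <- function(x, ...) {
  cat("<histo_experiment> seed ", x$config$seed, ", ",
      length(x$labels), " images\n", sep = "")
  avg <- dplyr::filter(x$reports, .data$class == "Average")
  print(dplyr::select(avg, "split", "phase", "accuracy", "sensitivity",
                      "specificity", "f_score", "mcc"))
  invisible(x)
}

#' Write experiment artifacts to disk
#'
#' Reports as CSV and Markdown, confusion matrices, per-epoch traces, raw
#' scores (for ROC/PR curves) and the tuning log.
#'
#' @param experiment A `histo_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_artifacts <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(experiment$reports, file.path(dir, "reports.csv"), row.names = FALSE)
  writeLines(report_markdown(experiment$reports), file.path(dir, "reports.md"))
  write.csv(experiment$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(experiment$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  for (key in names(experiment$confusions)) {
    write.csv(as.data.frame(unclass(experiment$confusions[[key]])),
              file.path(dir, paste0("confusion_", gsub("[ :]", "_", key), ".csv")))
  }
  if (!is.null(experiment$tuning)) {
    write.csv(experiment$tuning$result$trace,
              file.path(dir, "tuning_trace.csv"), row.names = FALSE)
  }
  invisible(dir)
}
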