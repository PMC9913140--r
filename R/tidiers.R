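#' Tidiers and plots for fitted objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a fit
#' (optimizer trace, training log, per-class report rows), `glance()` a
#' one-row (or one-row-per-split) summary, and `autoplot()` a ggplot2
#' figure.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy aoa_result
#' @export
tidy.aoa_result <- function(x, ...) x$trace

#' @rdname tidiers
#' @method glance aoa_result
#' @export
glance.aoa_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best$fitness,
                 iteration_found = x$best$iteration,
                 n_pop = x$config$n_pop, max_iter = x$config$max_iter,
                 dim = x$config$dim, seed = x$config$seed)
}

#' @rdname tidiers
#' @method autoplot aoa_result
#' @export
autoplot.aoa_result <- function(x, ...) {
  df <- tidyr::pivot_longer(x$trace, c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "fitness (error rate)",
                  colour = NULL, title = "Optimizer trace") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy dbn_model
#' @export
tidy.dbn_model <- function(x, ...) {
  out <- list()
  if (!is.null(x$pretrain_log)) {
    out$pretrain <- dplyr::mutate(x$pretrain_log, stage = "pretrain")
  }
  if (!is.null(x$finetune_log)) {
    out$finetune <- dplyr::mutate(x$finetune_log, stage = "finetune")
  }
  if (length(out) == 0) return(tibble::tibble())
  dplyr::bind_rows(out)
}

#' @rdname tidiers
#' @method glance dbn_model
#' @export
glance.dbn_model <- function(x, ...) {
  tibble::tibble(
    layers = paste(x$layer_sizes, collapse = "-"),
    pretrained = !is.null(x$pretrain_log),
    finetuned = !is.null(x$finetune_log),
    final_train_error = if (!is.null(x$finetune_log))
      dplyr::last(x$finetune_log$train_error_rate) else NA_real_
  )
}

#' @rdname tidiers
#' @method autoplot dbn_model
#' @export
autoplot.dbn_model <- function(x, ...) {
  if (is.null(x$finetune_log)) {
    abort("Model has no fine-tuning log to plot.", class = "histodbn_parameter_error")
  }
  cols <- intersect(c("train_error_rate", "val_error_rate"),
                    names(x$finetune_log))
  df <- tidyr::pivot_longer(x$finetune_log, dplyr::all_of(cols),
                            names_to = "series", values_to = "error_rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$error_rate,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "error rate (%)", colour = NULL,
                  title = "DBN fine-tuning") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy histo_experiment
#' @export
tidy.histo_experiment <- function(x, ...) x$reports

#' @rdname tidiers
#' @method glance histo_experiment
#' @export
glance.histo_experiment <- function(x, ...) {
  avg <- dplyr::filter(x$reports, .data$class == "Average")
  dplyr::select(avg, "split", "phase", "accuracy", "sensitivity",
                "specificity", "f_score", "mcc")
}

#' @rdname tidiers
#' @method autoplot histo_experiment
#' @export
autoplot.histo_experiment <- function(x, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(x$reports, .data$class != "Average"),
    c("accuracy", "sensitivity", "specificity", "f_score", "mcc"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(ggplot2::vars(.data$phase), ggplot2::vars(.data$split)) +
    ggplot2::coord_cartesian(ylim = c(50, 100)) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL,
                  title = "Per-class evaluation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
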