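#' Two-class confusion matrix
#'
#' Rows are truth (benign, malignant), columns are predictions.
#'
#' @param truth,predicted Label vectors with values in `classes`.
#' @param classes Class order; first class is the row/column 1 label.
#' @return A 2x2 (or k x k) integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = c("benign", "malignant")) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (anyNA(truth) || anyNA(predicted)) {
    abort("Labels outside the declared classes.", class = "histodbn_parameter_error")
  }
  m <- table(truth = truth, predicted = predicted)
  structure(unclass(m), class = "confusion_matrix")
}

#' Per-class and averaged evaluation report
#'
#' For each class taken as positive (one-vs-rest): accuracy, sensitivity
#' (true-positive rate), specificity (true-negative rate), F-score and
#' Matthews correlation coefficient, all on the percent scale (MCC x 100),
#' rounded half-up.  The `Average` row is the arithmetic mean of the class
#' rows.  In a binary problem the report inherits the characteristic
#' symmetries: accuracy is shared, each class's sensitivity equals the other
#' class's specificity, and MCC is identical for both classes.
#'
#' Degenerate denominators (an empty truth row or prediction column) yield 0
#' for the affected metric and set the `degenerate` attribute instead of
#' raising a division error.
#'
#' @param cm A [confusion_matrix()] (or plain square matrix, truth in rows).
#' @param round_decimals Decimals for round-half-up (default 2).
#' @return A tibble with columns `class`, `accuracy`, `sensitivity`,
#'   `specificity`, `f_score`, `mcc`.
#' @examples
#' cm <- matrix(c(9, 2, 1, 8), 2, dimnames = list(c("benign", "malignant"),
#'                                                c("benign", "malignant")))
#' compute_report(cm)
#' @export
compute_report <- function(cm, round_decimals = 2) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) == 0) {
    abort("`cm` must be a square non-negative matrix with positive total.",
          class = "histodbn_parameter_error")
  }
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  total <- sum(cm)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  rows <- purrr::map(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    tibble::tibble(
      class = classes[i],
      accuracy = 100 * (tp + tn) / total,
      sensitivity = 100 * safe_div(tp, tp + fn),
      specificity = 100 * safe_div(tn, tn + fp),
      f_score = 100 * safe_div(2 * tp, 2 * tp + fp + fn),
      mcc = 100 * safe_div(tp * tn - fp * fn, mcc_den)
    )
  })
  tab <- dplyr::bind_rows(rows)
  avg <- dplyr::summarise(tab, class = "Average",
                          dplyr::across(dplyr::where(is.numeric), mean))
  out <- dplyr::bind_rows(tab, avg)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          ~ round_half_up(.x, round_decimals)))
  attr(out, "degenerate") <- degenerate
  out
}

#' Average a set of per-class metric rows
#'
#' Arithmetic mean of the class rows at the stated rounding — the rule that
#' produces the `Average` rows of a standard per-class report.
#'
#' @param rows Tibble/data frame of per-class rows with numeric metric
#'   columns.
#' @param round_decimals Decimals for round-half-up (default 2).
#' @return One-row tibble with `class = "Average"`.
#' @export
average_report_rows <- function(rows, round_decimals = 2) {
  avg <- dplyr::summarise(dplyr::as_tibble(rows),
                          dplyr::across(dplyr::where(is.numeric), mean))
  avg <- dplyr::mutate(avg, dplyr::across(dplyr::where(is.numeric),
                                          ~ round_half_up(.x, round_decimals)))
  dplyr::bind_cols(tibble::tibble(class = "Average"), avg)
}

#' Stratified train/test split
#'
#' Per class, `floor(test_fraction * n_class)` samples go to the test set and
#' the remainder to training; the index sets are disjoint, exhaustive and
#' seeded.
#'
#' @param labels Label vector.
#' @param ratio `"80:20"`, `"70:30"`, or a numeric training fraction.
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @examples
#' split_dataset(rep(c("a", "b"), each = 50), "80:20", seed = 1)$test |> length()
#' @export
split_dataset <- function(labels, ratio = "80:20", stratified = TRUE, seed = 1) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(ratio, ":")[[1]]))
    if (length(parts) != 2 || any(is.na(parts))) {
      abort("`ratio` must look like \"80:20\".", class = "histodbn_parameter_error")
    }
    test_frac <- parts[2] / sum(parts)
  } else {
    test_frac <- 1 - ratio
  }
  labels <- as.character(labels)
  n <- length(labels)
  if (stratified && any(table(labels) < 2)) {
    abort("Every class needs at least 2 samples for a stratified split.",
          class = "histodbn_parameter_error")
  }
  test <- withr::with_seed(substream_seed(seed, "split"), {
    if (stratified) {
      unlist(purrr::map(unique(labels), function(cl) {
        idx <- which(labels == cl)
        sample(idx, floor(test_frac * length(idx)))
      }), use.names = FALSE)
    } else {
      sample.int(n, floor(test_frac * n))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Render a report as a Markdown table
#'
#' @param report Tibble from [compute_report()] (or several bound together).
#' @return Character scalar of Markdown.
#' @export
report_markdown <- function(report) {
  cols <- names(report)
  fmt <- function(x) ifelse(is.na(suppressWarnings(as.numeric(x))),
                            as.character(x), sprintf("%.2f", as.numeric(x)))
  header <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
  body <- apply(report, 1, function(r) {
    vals <- purrr::map2_chr(r, cols, function(v, nm) {
      if (nm %in% c("accuracy", "sensitivity", "specificity", "f_score", "mcc"))
        fmt(v) else as.character(v)
    })
    paste0("| ", paste(vals, collapse = " | "), " |")
  })
  paste(c(header, sep, body), collapse = "\n")
}

#' Reference per-class results on the two-magnification benchmark
#'
#' Per-class accuracy/sensitivity/specificity/F-score/MCC rows reported for
#' this architecture on the 100x and 200x histopathology benchmark, bundled
#' as package data.  Used for internal-consistency checks: averaging the
#' per-class rows with [average_report_rows()] must reproduce the reported
#' `Average` rows.
#'
#' @return Tibble with columns `magnification`, `split`, `phase`, `class` and
#'   the five metric columns (percent scale).
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_results.csv", package = "histodbn",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(rep("character", 4),
                                            rep("numeric", 5))))
}
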