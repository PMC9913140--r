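test_that("a perfect classifier scores 100 everywhere", {
  cm <- confusion_matrix(rep(c("benign", "malignant"), each = 50),
                         rep(c("benign", "malignant"), each = 50))
  rep_tbl <- compute_report(cm)
  for (col in c("accuracy", "sensitivity", "specificity", "f_score", "mcc")) {
    expect_true(all(rep_tbl[[col]] == 100))
  }
})

test_that("the report reproduces hand-evaluated metrics", {
  cm <- matrix(c(9, 2, 1, 8), 2, 2,
               dimnames = list(c("benign", "malignant"),
                               c("benign", "malignant")))
  rep_tbl <- compute_report(cm)
  benign <- dplyr::filter(rep_tbl, class == "benign")
  expect_equal(benign$sensitivity, 90.00)
  expect_equal(benign$specificity, 80.00)
  expect_equal(benign$accuracy, 85.00)
  expect_equal(benign$f_score, 85.71)
  expect_equal(benign$mcc, 70.35)
})

test_that("averaging printed per-class sensitivities matches the published average rows", {
  # published tie-breaking is inconsistent on exact half-cases, so columns
  # are checked to within half an ULP of the printed two-decimal precision
  ref <- reference_results()
  groups <- dplyr::group_split(dplyr::filter(ref, class != "Average"),
                               magnification, split, phase)
  for (g in groups) {
    avg_ref <- dplyr::filter(ref, class == "Average",
                             magnification == g$magnification[1],
                             split == g$split[1], phase == g$phase[1])
    got <- average_report_rows(dplyr::select(g, sensitivity:mcc),
                               round_decimals = 8)
    for (col in c("sensitivity", "specificity", "f_score", "mcc")) {
      expect_lte(abs(got[[col]] - avg_ref[[col]]), 0.005 + 1e-9)
    }
  }
  # the worked pair: benign 94.66 / malignant 97.20 average to 95.93
  expect_equal(average_report_rows(tibble::tibble(sensitivity = c(94.66, 97.20)))$sensitivity,
               95.93)
})

test_that("binary reports carry the class-symmetry structure", {
  withr::with_seed(61, {
    for (rep in 1:200) {
      cm <- matrix(sample(0:60, 4, replace = TRUE), 2, 2,
                   dimnames = list(c("benign", "malignant"),
                                   c("benign", "malignant")))
      if (sum(cm) == 0) next
      rep_tbl <- compute_report(cm, round_decimals = 6)
      b <- dplyr::filter(rep_tbl, class == "benign")
      m <- dplyr::filter(rep_tbl, class == "malignant")
      expect_equal(b$accuracy, m$accuracy)
      expect_equal(b$sensitivity, m$specificity)
      expect_equal(b$specificity, m$sensitivity)
      expect_equal(b$mcc, m$mcc)
      a <- dplyr::filter(rep_tbl, class == "Average")
      expect_equal(a$sensitivity, (b$sensitivity + m$sensitivity) / 2,
                   tolerance = 1e-6)
    }
  })
})

test_that("the report agrees with an independent metric implementation", {
  withr::with_seed(62, {
    for (rep in 1:1000) {
      cells <- sample(1:80, 4, replace = TRUE)  # keep denominators positive
      cm <- matrix(cells, 2, 2,
                   dimnames = list(c("benign", "malignant"),
                                   c("benign", "malignant")))
      got <- dplyr::filter(compute_report(cm, round_decimals = 8),
                           class == "benign")
      want <- oracle_metrics(tp = cm[1, 1], fn = cm[1, 2],
                             fp = cm[2, 1], tn = cm[2, 2])
      expect_equal(got$accuracy, round_half_up(want[["accuracy"]], 8))
      expect_equal(got$sensitivity, round_half_up(want[["sensitivity"]], 8))
      expect_equal(got$specificity, round_half_up(want[["specificity"]], 8))
      expect_equal(got$f_score, round_half_up(want[["f_score"]], 8))
      expect_equal(got$mcc, round_half_up(want[["mcc"]], 8))
    }
  })
})

test_that("degenerate confusion matrices yield zeros with a flag, not errors", {
  cm <- matrix(c(10, 0, 5, 0), 2, 2,
               dimnames = list(c("benign", "malignant"),
                               c("benign", "malignant")))
  rep_tbl <- compute_report(cm)
  expect_true(attr(rep_tbl, "degenerate"))
  expect_true(all(is.finite(as.matrix(rep_tbl[, -1]))))
})

test_that("stratified splits follow the floor rule and are reproducible", {
  labels <- rep(c("benign", "malignant"), each = 50)
  sp <- split_dataset(labels, "80:20", seed = 1)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_equal(sum(labels[sp$test] == "benign"), 10)

  big <- c(rep("benign", 644), rep("malignant", 1437))
  sp2 <- split_dataset(big, "80:20", seed = 1)
  expect_length(sp2$test, floor(0.2 * 644) + floor(0.2 * 1437))  # 128 + 287
  expect_length(sp2$train, 2081 - 415)

  sp3 <- split_dataset(big, "70:30", seed = 1)
  expect_length(sp3$test, floor(0.3 * 644) + floor(0.3 * 1437))

  expect_identical(split_dataset(labels, "80:20", seed = 1), sp)
  expect_false(identical(split_dataset(labels, "80:20", seed = 2)$test, sp$test))

  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))

  expect_error(split_dataset(c("a", "b", "b"), "80:20"),
               class = "histodbn_parameter_error")
  expect_error(split_dataset(labels, "eighty"), class = "histodbn_parameter_error")
})

test_that("rounding is half-up at the requested precision", {
  expect_equal(round_half_up(93.525, 2), 93.53)
  expect_equal(round_half_up(85.714285, 2), 85.71)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), 0)
})

test_that("markdown rendering keeps the report layout", {
  cm <- confusion_matrix(rep(c("benign", "malignant"), each = 10),
                         rep(c("benign", "malignant"), each = 10))
  md <- report_markdown(compute_report(cm))
  lines <- strsplit(md, "\n")[[1]]
  expect_match(lines[1], "class.*accuracy.*sensitivity")
  expect_length(lines, 2 + 3)
})
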