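test_that("compute_metrics matches an independent oracle on 1000 tables", {
  oracle <- function(tp, tn, fp, fn) {
    n <- tp + tn + fp + fn
    acc <- (tp + tn) / n
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    c(acc, prec, sens, spec, mcc)
  }
  set.seed(60)
  for (i in 1:1000) {
    cts <- as.numeric(rmultinom(1, sample(1:200, 1), prob = runif(4)))
    m <- compute_metrics(counts = list(tp = cts[1], tn = cts[2],
                                       fp = cts[3], fn = cts[4]))
    ref <- oracle(cts[1], cts[2], cts[3], cts[4])
    got <- c(m$accuracy, m$precision, m$sensitivity, m$specificity, m$mcc)
    expect_close(got, ref, tol = 1e-10)
  }
})

test_that("the worked example TP=3 TN=2 FP=1 FN=1 gives MCC 5/12", {
  m <- compute_metrics(counts = list(tp = 3, tn = 2, fp = 1, fn = 1))
  expect_equal(m$mcc, 5 / 12)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 2 / 3)
})

test_that("degenerate confusion tables are flagged, not NaN", {
  m <- compute_metrics(counts = list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_equal(m$mcc, 0)
  expect_false(m$mcc_defined)
  expect_equal(m$precision, 0)
  expect_false(m$precision_defined)
  expect_equal(m$accuracy, 1)
  expect_error(compute_metrics(counts = list(tp = 0, tn = 0, fp = 0, fn = 0)),
               class = "aopred_config_error")
  expect_error(compute_metrics(counts = list(tp = -1, tn = 1, fp = 1, fn = 1)),
               class = "aopred_config_error")
})

test_that("accuracy identity holds for metrics from label vectors", {
  set.seed(61)
  truth <- rbinom(60, 1, 0.4)
  est <- rbinom(60, 1, 0.5)
  m <- compute_metrics(truth, est)
  expect_equal(m$accuracy, mean(truth == est))
  expect_equal(m$tp + m$tn + m$fp + m$fn, 60)
  cf <- confusion(truth, est)
  expect_identical(m$tp, as.numeric(cf$tp))
  expect_error(confusion(c(0, 1), c(0, 2)), class = "aopred_config_error")
  expect_error(confusion(c(0, 1), c(0)), class = "aopred_config_error")
})

test_that("paired_t_test matches stats::t.test and handles zero variance", {
  # hand example: differences (1, 2, 3) -> t = mean/ (sd/sqrt(3)) = 2*sqrt(3)
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)
  out <- paired_t_test(x, y)
  expect_equal(out$statistic, 2 * sqrt(3))
  expect_equal(out$df, 2)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(out$p_value, ref$p.value)
  expect_false(out$degenerate)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  shifted <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(shifted$degenerate)
  expect_true(is.na(shifted$p_value))
  expect_equal(shifted$estimate, 1)

  expect_error(paired_t_test(1, 2), class = "aopred_config_error")
})

test_that("cross_validate keeps test folds untouched and returns metrics", {
  man <- generate_peptides(synth_spec(15, 15, length_range = c(3, 10),
                                      seed = 30))
  cv <- cross_validate(
    function(s) tiny_model(view = "sequence", seed = s),
    man, k = 3, seed = 2,
    config = train_config(learning_rate = 1e-3, batch_size = 10,
                          max_epochs = 2, patience = 2)
  )
  expect_s3_class(cv, "aop_cv")
  expect_identical(cv$fold, 1:3)
  expect_equal(sum(cv$tp + cv$tn + cv$fp + cv$fn), nrow(man))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  gl <- glance(cv)
  expect_equal(gl$mean_accuracy, mean(cv$accuracy))
  td <- tidy(cv)
  expect_identical(names(td), c("fold", "accuracy", "precision",
                                "sensitivity", "specificity", "mcc"))
})

test_that("length_stratified_eval partitions and scores strata", {
  man <- generate_peptides(synth_spec(8, 8, length_range = c(3, 30), seed = 31))
  fit <- train_aop(tiny_model(view = "sequence", seed = 8), man,
                   config = train_config(learning_rate = 1e-3, batch_size = 16,
                                         max_epochs = 1, seed = 5))
  out <- length_stratified_eval(fit, man, threshold = 15)
  expect_true(all(out$stratum %in% c("short", "long")))
  expect_equal(sum(out$n), nrow(man))
})

test_that("grid_search ranks by accuracy with MCC and order tie-breaks", {
  man <- generate_peptides(synth_spec(10, 10, length_range = c(3, 8),
                                      seed = 32))
  grid <- tibble::tibble(lr = c(1e-3, 5e-3))
  res <- grid_search(
    grid,
    function(row, s) tiny_model(view = "sequence", seed = s),
    man, k = 2, seed = 3,
    config = train_config(learning_rate = 1e-3, batch_size = 10,
                          max_epochs = 1, patience = 1)
  )
  expect_identical(sort(res$rank), 1:2)
  expect_true(all(c("mean_accuracy", "mean_mcc") %in% names(res)))
  expect_identical(res$rank, order(-res$mean_accuracy, -res$mean_mcc))
  expect_error(grid_search(grid[0, ], identity, man),
               class = "aopred_config_error")
})

test_that("autoplot and plot_training_history return ggplot objects", {
  man <- tiny_manifest(4, 4, seed = 33)
  fit <- train_aop(tiny_model(seed = 9), man, config = train_config(
    learning_rate = 1e-3, batch_size = 8, max_epochs = 2, seed = 6))
  p <- plot_training_history(fit)
  expect_s3_class(p, "ggplot")
  cv <- structure(
    tibble::tibble(fold = 1:2, accuracy = c(0.5, 0.6), precision = c(0.5, 0.6),
                   sensitivity = c(0.5, 0.6), specificity = c(0.5, 0.6),
                   mcc = c(0, 0.2)),
    class = c("aop_cv", class(tibble::tibble())), k = 2, seed = 1
  )
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})
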