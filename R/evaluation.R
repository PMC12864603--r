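# Evaluation: confusion counts, the five classification metrics, stratified
# cross-validation, paired comparison, length-stratified evaluation and a
# small grid search.

#' Confusion counts
#'
#' @param truth Integer vector of 0/1 reference labels.
#' @param estimate Integer vector of 0/1 predicted labels.
#' @return A tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop_aopred("`truth` and `estimate` must have equal length.",
                "aopred_config_error")
  }
  if (anyNA(truth) || anyNA(estimate) ||
      !all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    stop_aopred("Labels must be 0/1 with no missing values.",
                "aopred_config_error")
  }
  tibble::tibble(
    tp = sum(truth == 1 & estimate == 1),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0)
  )
}

#' Classification metrics from labels or confusion counts
#'
#' Computes accuracy, precision, sensitivity (recall), specificity and the
#' Matthews correlation coefficient. Degenerate cases are handled explicitly:
#' when any MCC denominator factor is zero the MCC is reported as 0, and when
#' no positive predictions exist precision is reported as 0 and flagged via
#' `precision_defined = FALSE` (likewise for sensitivity/specificity when
#' their denominators vanish).
#'
#' @param truth,estimate 0/1 label vectors (omit when `counts` is given).
#' @param counts Optionally, a one-row data frame or named list/vector with
#'   entries `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble with the counts, the five metrics and
#'   definedness flags.
#' @export
compute_metrics <- function(truth = NULL, estimate = NULL, counts = NULL) {
  if (is.null(counts)) {
    counts <- confusion(truth, estimate)
  }
  counts <- as.list(counts)
  need <- c("tp", "tn", "fp", "fn")
  if (!all(need %in% names(counts))) {
    stop_aopred("`counts` must provide tp, tn, fp and fn.",
                "aopred_config_error")
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) {
    stop_aopred("Confusion counts must be non-negative.",
                "aopred_config_error")
  }
  n <- tp + tn + fp + fn
  if (n == 0) {
    stop_aopred("Empty confusion table.", "aopred_config_error")
  }
  acc <- (tp + tn) / n
  prec_def <- (tp + fp) > 0
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  prec <- if (prec_def) tp / (tp + fp) else 0
  sens <- if (sens_def) tp / (tp + fn) else 0
  spec <- if (spec_def) tn / (tn + fp) else 0
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = acc, precision = prec, sensitivity = sens,
    specificity = spec, mcc = mcc,
    precision_defined = prec_def, sensitivity_defined = sens_def,
    specificity_defined = spec_def, mcc_defined = denom2 > 0
  )
}

#' Stratified k-fold cross-validation
#'
#' For each fold, the held-out fold is the test set; 10% of the remaining
#' records (one inner stratified fold) become an early-stopping validation
#' set and the rest are trained on.
#'
#' @param model_factory A function `function(seed)` returning a fresh
#'   [aop_model()].
#' @param manifest A labeled manifest tibble.
#' @param k Number of folds.
#' @param seed Integer seed driving fold assignment and per-fold training.
#' @param config A [train_config()]; its `seed` is replaced per fold.
#' @return An object of class `aop_cv`: a tibble with one row per fold
#'   holding the test metrics, plus attributes `k` and `seed`.
#' @export
cross_validate <- function(model_factory, manifest, k = 5, seed = 1,
                           config = train_config()) {
  folds <- make_folds(manifest, k = k, seed = seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    test <- manifest[folds == i, ]
    rest <- manifest[folds != i, ]
    inner <- make_folds(rest, k = 10, seed = derive_seed(seed, paste0("inner-", i)))
    valid <- rest[inner == 1, ]
    train <- rest[inner != 1, ]
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("fold-", i))
    fit <- train_aop(model_factory(cfg$seed), train, valid = valid,
                     config = cfg)
    pred <- predict(fit, test)
    truth <- test$label[match(pred$id, test$id)]
    m <- compute_metrics(truth, pred$label)
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(fold = i), m)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("aop_cv", class(out))
  out
}

#' @export
tidy.aop_cv <- function(x, ...) {
  tibble::as_tibble(x)[, c("fold", "accuracy", "precision", "sensitivity",
                           "specificity", "mcc")]
}

#' @export
glance.aop_cv <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"),
    mean_accuracy = mean(x$accuracy), sd_accuracy = stats::sd(x$accuracy),
    mean_mcc = mean(x$mcc), sd_mcc = stats::sd(x$mcc)
  )
}

#' Paired t-test between two per-fold metric vectors
#'
#' Wraps [stats::t.test()] with explicit handling of the zero-variance case:
#' when all paired differences are identical the test statistic is undefined,
#' so the result reports `p_value = 1` for a zero mean difference and flags
#' the comparison as degenerate otherwise.
#'
#' @param x,y Equal-length numeric vectors (e.g. per-fold accuracies).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_aopred("Paired test needs two equal-length vectors (n >= 2).",
                "aopred_config_error")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      estimate = mean(d), statistic = NA_real_, df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else NA_real_,
      degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE
  )
}

#' Length-stratified evaluation
#'
#' Evaluates a fitted model separately on short (< `threshold` residues) and
#' long (>= `threshold`) peptides.
#'
#' @param fit An `aop_fit`.
#' @param manifest A labeled manifest tibble.
#' @param threshold Length cutoff.
#' @return A tibble with a `stratum` column (`"short"`/`"long"`), an `n`
#'   column and the metric columns; empty strata are omitted.
#' @export
length_stratified_eval <- function(fit, manifest, threshold = 15) {
  strata <- split_by_length(manifest, threshold = threshold)
  rows <- list()
  for (s in names(strata)) {
    part <- strata[[s]]
    if (nrow(part) == 0) next
    pred <- predict(fit, part)
    truth <- part$label[match(pred$id, part$id)]
    rows[[s]] <- dplyr::bind_cols(
      tibble::tibble(stratum = s, n = nrow(pred)),
      compute_metrics(truth, pred$label)
    )
  }
  dplyr::bind_rows(rows)
}

#' Cross-validated grid search
#'
#' Runs [cross_validate()] for every row of `grid` and ranks configurations
#' by mean accuracy, breaking ties by mean MCC and then by grid order.
#'
#' @param grid A data frame; each row is one configuration.
#' @param model_factory A function `function(row, seed)` returning a fresh
#'   [aop_model()] for that configuration row (a one-row tibble).
#' @param manifest A labeled manifest tibble.
#' @param k,seed,config As in [cross_validate()].
#' @return `grid` augmented with `mean_accuracy`, `mean_mcc` and `rank`,
#'   sorted by rank.
#' @export
grid_search <- function(grid, model_factory, manifest, k = 3, seed = 1,
                        config = train_config()) {
  if (nrow(grid) == 0) {
    stop_aopred("Empty search grid.", "aopred_config_error")
  }
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    cv <- cross_validate(function(s) model_factory(row, s), manifest,
                         k = k, seed = derive_seed(seed, paste0("grid-", i)),
                         config = config)
    tibble::tibble(mean_accuracy = mean(cv$accuracy), mean_mcc = mean(cv$mcc))
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
  ord <- order(-out$mean_accuracy, -out$mean_mcc, seq_len(nrow(out)))
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  dplyr::arrange(out, .data$rank)
}
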