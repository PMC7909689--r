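# Cross-validation protocol: k-fold partition, repeated training of each
# architecture on each split, architecture selection by average
# best-per-split test accuracy, and a ridge logistic baseline fitted on
# the identical folds.

#' Cross-validation configuration
#'
#' @param n_splits Number of folds (default 10). Every record appears in
#'   exactly one test fold; the folds partition the cohort.
#' @param n_repetitions Independent training repetitions per split
#'   (default 10); repetition `r` of split `s` perturbs the training
#'   seed deterministically from `master_seed`.
#' @param stratified Stratify fold assignment by label (default `TRUE`).
#' @param master_seed Integer seed governing fold assignment and all
#'   derived training seeds.
#' @return A list of class `"cv_config"`.
#' @export
cv_config <- function(n_splits = 10L, n_repetitions = 10L,
                      stratified = TRUE, master_seed = 1L) {
  n_splits <- assert_count(n_splits, "n_splits", min = 2L)
  n_repetitions <- assert_count(n_repetitions, "n_repetitions", min = 1L)
  structure(list(n_splits = n_splits, n_repetitions = n_repetitions,
                 stratified = stratified, master_seed = as.integer(master_seed)),
            class = "cv_config")
}

# Fold assignment. Stratified mode shuffles within class and then deals
# the concatenated sequence round-robin, which balances overall fold
# sizes to within one record while keeping each class near-evenly spread.
make_folds <- function(labels, n_splits, master_seed, stratified = TRUE) {
  n <- length(labels)
  if (n < n_splits) stop("cohort smaller than the number of splits", call. = FALSE)
  withr::local_seed(as.integer(master_seed))
  ord <- if (stratified) {
    unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
  } else {
    sample.int(n)
  }
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_splits), n)
  fold
}

#' Run the repeated cross-validation protocol
#'
#' Builds `n_splits` folds from `master_seed`, then trains every
#' architecture `n_repetitions` times on every split (the repetition
#' index perturbs the training seed) and scores each trained model on
#' its held-out test fold. The total number of trained models is
#' `n_splits * n_repetitions * length(archs)`.
#'
#' @param features Numeric feature matrix.
#' @param labels Binary labels (0/1) aligned with the rows.
#' @param archs A single [mlp_spec()] or a list of them (ids must be
#'   unique).
#' @param cv A [cv_config()].
#' @param control An [mlp_control()]; its `seed` is superseded by the
#'   per-(split, repetition) seed derived from `master_seed`.
#' @param keep_models Keep the trained model objects in the result
#'   (default `TRUE`; disable to save memory in large sweeps).
#' @return An object of class `"cv_result"`: `results` (tibble with one
#'   row per split x repetition x architecture: `split`, `repetition`,
#'   `architecture`, `accuracy`, `auc`, `n_test`, plus list-columns
#'   `probabilities`, `metrics` and `model`), `folds` (tibble `row`,
#'   `fold`), and the configuration objects.
#' @export
run_cross_validation <- function(features, labels, archs,
                                 cv = cv_config(), control = mlp_control(),
                                 keep_models = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0L, 1L)))
  stopifnot(inherits(cv, "cv_config"), inherits(control, "mlp_control"))
  if (inherits(archs, "mlp_spec")) archs <- list(archs)
  ids <- vapply(archs, function(a) a$id, character(1))
  if (anyDuplicated(ids)) stop("architecture ids must be unique", call. = FALSE)
  fold <- make_folds(labels, cv$n_splits, cv$master_seed, cv$stratified)
  for (s in seq_len(cv$n_splits)) {
    if (length(unique(labels[fold == s])) < 2L ||
        length(unique(labels[fold != s])) < 2L) {
      stop(sprintf("fold %d contains a single class", s), call. = FALSE)
    }
  }
  rows <- vector("list", cv$n_splits * cv$n_repetitions * length(archs))
  k <- 0L
  for (s in seq_len(cv$n_splits)) {
    te <- which(fold == s)
    tr <- which(fold != s)
    for (r in seq_len(cv$n_repetitions)) {
      ctrl <- control
      ctrl$seed <- mix_seed(cv$master_seed, s, r)
      for (a in seq_along(archs)) {
        model <- train_mlp(features[tr, , drop = FALSE], labels[tr],
                           spec = archs[[a]], control = ctrl)
        probs <- predict(model, features[te, , drop = FALSE])
        met <- compute_metrics(probs, labels[te])
        k <- k + 1L
        rows[[k]] <- tibble(
          split = s, repetition = r, architecture = ids[a],
          accuracy = met$accuracy, auc = met$auc, n_test = length(te),
          n_parameters = model$n_parameters,
          probabilities = list(probs), metrics = list(met),
          model = if (keep_models) list(model) else list(NULL))
      }
    }
  }
  structure(list(results = bind_rows(rows),
                 folds = tibble(row = seq_along(fold), fold = fold),
                 labels = labels, cv = cv, control = control,
                 architectures = archs),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d models (%d splits x %d repetitions x %d architectures)\n",
    nrow(x$results), x$cv$n_splits, x$cv$n_repetitions,
    length(x$architectures)))
  invisible(x)
}

#' Select the best architecture from a cross-validation run
#'
#' For each architecture, the best model in each split is picked by test
#' accuracy (ties: higher AUC, then lower repetition index); those
#' per-split accuracies are averaged, and the architecture with the
#' highest average wins (ties: fewer parameters, then lexicographic id).
#'
#' @param cv_result A `"cv_result"`.
#' @return A list with `architecture` (the winning id), `summary` (one
#'   row per architecture: mean accuracy/AUC over best-per-split models)
#'   and `best_per_split` (the picked rows).
#' @export
select_architecture <- function(cv_result) {
  stopifnot(inherits(cv_result, "cv_result"))
  res <- cv_result$results
  if (nrow(res) == 0L) stop("empty cross-validation result", call. = FALSE)
  best <- res |>
    group_by(.data$architecture, .data$split) |>
    arrange(desc(.data$accuracy), desc(.data$auc), .data$repetition,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  summary <- best |>
    group_by(.data$architecture) |>
    summarise(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = sd(.data$accuracy),
              max_accuracy = max(.data$accuracy),
              mean_auc = mean(.data$auc),
              sd_auc = sd(.data$auc),
              n_parameters = .data$n_parameters[1L],
              .groups = "drop") |>
    arrange(desc(.data$mean_accuracy), .data$n_parameters, .data$architecture)
  list(architecture = summary$architecture[1L],
       summary = summary,
       best_per_split = best)
}

#' Ridge logistic baseline on the same folds
#'
#' Fits an L2-regularized logistic regression per split on exactly the
#' training rows the MLPs saw (the folds are reused byte-identically
#' from the `cv_result`) and reports accuracy and AUC side by side with
#' the best MLP of each split. The comparison quantifies what the hidden
#' layers add over a linear decision rule.
#'
#' @param features,labels The same feature matrix and labels passed to
#'   [run_cross_validation()].
#' @param cv_result The `"cv_result"` whose folds to reuse.
#' @param lambda Ridge penalty (default 1e-3).
#' @return An object of class `"baseline_comparison"`: `per_split`
#'   (tibble: split, logistic/mlp accuracy and AUC), `summary` (their
#'   means) and `fits` (the glmnet objects).
#' @export
train_logistic_baseline <- function(features, labels, cv_result,
                                    lambda = 1e-3) {
  stopifnot(inherits(cv_result, "cv_result"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  fold <- cv_result$folds$fold
  stopifnot(nrow(features) == length(fold))
  pad <- ncol(features) == 1L   # glmnet needs >= 2 columns
  x_all <- if (pad) cbind(features, .pad = 0) else features
  rows <- vector("list", cv_result$cv$n_splits)
  fits <- vector("list", cv_result$cv$n_splits)
  mlp_best <- cv_result$results |>
    group_by(.data$split) |>
    arrange(desc(.data$accuracy), desc(.data$auc), .data$repetition,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  for (s in seq_len(cv_result$cv$n_splits)) {
    tr <- which(fold != s); te <- which(fold == s)
    if (all(apply(x_all[tr, , drop = FALSE], 2L, stats::var) == 0)) {
      # no usable predictor: intercept-only limit, probability = prevalence
      fit <- structure(list(p = mean(labels[tr])),
                       class = "intercept_logistic")
    } else {
      fit <- glmnet::glmnet(x_all[tr, , drop = FALSE], labels[tr],
                            family = "binomial", alpha = 0, lambda = lambda)
    }
    probs <- as.vector(predict(fit, x_all[te, , drop = FALSE],
                               type = "response"))
    met <- compute_metrics(probs, labels[te])
    fits[[s]] <- fit
    rows[[s]] <- tibble(
      split = s,
      logistic_accuracy = met$accuracy, logistic_auc = met$auc,
      mlp_accuracy = mlp_best$accuracy[mlp_best$split == s],
      mlp_auc = mlp_best$auc[mlp_best$split == s])
  }
  per_split <- bind_rows(rows)
  summary <- per_split |>
    summarise(logistic_accuracy = mean(.data$logistic_accuracy),
              logistic_auc = mean(.data$logistic_auc),
              mlp_accuracy = mean(.data$mlp_accuracy),
              mlp_auc = mean(.data$mlp_auc))
  structure(list(per_split = per_split, summary = summary, fits = fits,
                 lambda = lambda),
            class = "baseline_comparison")
}

#' @export
predict.intercept_logistic <- function(object, newx, ...) {
  rep(object$p, NROW(newx))
}

#' @export
print.baseline_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<baseline_comparison> logistic acc %.3f / auc %.3f vs MLP acc %.3f / auc %.3f (mean over %d splits)\n",
    s$logistic_accuracy, s$logistic_auc, s$mlp_accuracy, s$mlp_auc,
    nrow(x$per_split)))
  invisible(x)
}
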