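# broom-style tidiers so results drop straight into dplyr/ggplot2
# pipelines.

#' Tidy a trained MLP's training history
#'
#' @param x A `"trained_mlp"`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `train_accuracy`, `val_loss`, `val_accuracy`).
#' @method tidy trained_mlp
#' @export
tidy.trained_mlp <- function(x, ...) x$history

#' @rdname tidy.trained_mlp
#' @return `glance()` returns a one-row summary: architecture id, best
#'   epoch, its validation accuracy, epochs run and parameter count.
#' @method glance trained_mlp
#' @export
glance.trained_mlp <- function(x, ...) {
  tibble(architecture = x$spec$id,
         best_epoch = x$best_epoch,
         best_val_accuracy = x$history$val_accuracy[x$best_epoch],
         epochs = nrow(x$history),
         n_parameters = x$n_parameters)
}

#' Tidy a cross-validation result
#'
#' @param x A `"cv_result"`.
#' @param ... Unused.
#' @return One row per trained model (`split`, `repetition`,
#'   `architecture`, `accuracy`, `auc`, `n_test`).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  x$results |>
    select("split", "repetition", "architecture", "accuracy", "auc", "n_test")
}

#' @rdname tidy.cv_result
#' @return `glance()` returns a one-row summary across all trained
#'   models.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  x$results |>
    summarise(n_models = dplyr::n(),
              n_splits = x$cv$n_splits,
              n_repetitions = x$cv$n_repetitions,
              mean_accuracy = mean(.data$accuracy),
              sd_accuracy = sd(.data$accuracy),
              mean_auc = mean(.data$auc),
              sd_auc = sd(.data$auc))
}

#' Tidy a metrics report
#'
#' @param x A `"metrics_report"`.
#' @param ... Unused.
#' @return A long tibble (`metric`, `value`).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "ppv", "f1",
                    "auc"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$ppv, x$f1,
                   x$auc))
}

#' @rdname tidy.metrics_report
#' @return `glance()` returns the counts and metrics as one wide row.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(n = x$n, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, ppv = x$ppv, f1 = x$f1, auc = x$auc,
         threshold = x$threshold)
}

#' Tidy an ablation report
#'
#' @param x An `"ablation_report"`.
#' @param ... Unused.
#' @return The per-rule delta tibble, most damaging rules first.
#' @method tidy ablation_report
#' @export
tidy.ablation_report <- function(x, ...) {
  x$deltas |> arrange(.data$delta, .data$rule)
}

#' @rdname tidy.ablation_report
#' @method glance ablation_report
#' @export
glance.ablation_report <- function(x, ...) {
  tibble(baseline_accuracy = x$baseline_accuracy,
         n_rules = nrow(x$deltas),
         n_zero_impact = length(x$zero_impact),
         max_drop = min(x$deltas$delta))
}

#' Tidy a saliency report
#'
#' @param x A `"saliency_report"`.
#' @param ... Unused.
#' @return The class-wise word-frequency tibble.
#' @method tidy saliency_report
#' @export
tidy.saliency_report <- function(x, ...) x$frequencies

#' Tidy an external screen report
#'
#' @param x An `"external_screen_report"`.
#' @param ... Unused.
#' @return The per-rule prevalence-ratio tibble.
#' @method tidy external_screen_report
#' @export
tidy.external_screen_report <- function(x, ...) x$rule_prevalence

#' @rdname tidy.external_screen_report
#' @method glance external_screen_report
#' @export
glance.external_screen_report <- function(x, ...) {
  tibble(n_screened = x$n_screened, positive_rate = x$positive_rate,
         threshold = x$threshold)
}
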