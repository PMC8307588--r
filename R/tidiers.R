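#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per fold with its held-out size and accuracy.
#'
#' @param x a `caries_cv`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.caries_cv <- function(x, ...) {
  folds <- sort(unique(x$folds))
  tibble::tibble(fold = folds,
                 n = vapply(folds, function(f) sum(x$folds == f), integer(1)),
                 accuracy = x$fold_accuracy)
}

#' Glance at a cross-validation result
#'
#' One row of pooled metrics (percent).
#'
#' @inheritParams tidy.caries_cv
#' @export
glance.caries_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = toupper(x$spec$name), k = x$k,
                                  positive = x$positive),
                   x$metrics)
}

#' Tidy a model comparison
#'
#' Long format: one row per model and metric.
#'
#' @param x a `caries_model_comparison`.
#' @param ... unused.
#' @export
tidy.caries_model_comparison <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"model",
                      names_to = "metric", values_to = "value")
}

#' Tidy a confusion matrix
#'
#' @param x a `caries_confusion`.
#' @param ... unused.
#' @export
tidy.caries_confusion <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}

#' @rdname tidy.caries_confusion
#' @export
glance.caries_confusion <- function(x, ...) metrics_from_confusion(x)

#' Plot pooled ROC curve of a cross-validation result
#'
#' @param object a `caries_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.caries_cv <- function(object, ...) {
  pos <- object$predictions$label == object$positive
  sc <- object$predictions$score
  th <- c(Inf, sort(unique(sc), decreasing = TRUE))
  roc <- dplyr::bind_rows(lapply(th, function(t) tibble::tibble(
    fpr = mean(sc[!pos] >= t), tpr = mean(sc[pos] >= t))))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s pooled ROC (AUC = %.1f%%)",
                                  toupper(object$spec$name),
                                  object$metrics$aucroc)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Dodged bar chart of all metrics by model, ranked by accuracy.
#'
#' @param object a `caries_model_comparison`.
#' @param ... unused.
#' @export
autoplot.caries_model_comparison <- function(object, ...) {
  long <- tidy.caries_model_comparison(object)
  long$model <- factor(long$model, levels = object$model)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Cross-validated classifier comparison") +
    ggplot2::theme_minimal()
}

# image/mask -> long tibble for raster plotting
image_df <- function(img) {
  if (length(dim(img)) == 3L) {
    hex <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3],
                          maxColorValue = 255)
    tibble::tibble(row = rep(seq_len(dim(img)[1]), dim(img)[2]),
                   col = rep(seq_len(dim(img)[2]), each = dim(img)[1]),
                   fill = hex)
  } else {
    tibble::tibble(row = rep(seq_len(nrow(img)), ncol(img)),
                   col = rep(seq_len(ncol(img)), each = nrow(img)),
                   fill = grDevices::gray(as.vector(img) / 255))
  }
}

#' Plot a phantom with its ground-truth lesion outline
#'
#' @param object a `caries_phantom`.
#' @param ... unused.
#' @export
autoplot.caries_phantom <- function(object, ...) {
  df <- image_df(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Phantom,", object$label)) +
    ggplot2::theme_void()
  if (fg_count(object$lesion_mask) > 0) {
    idx <- which(object$lesion_mask == 255, arr.ind = TRUE)
    p <- p + ggplot2::annotate("point", x = idx[, 2], y = idx[, 1],
                               shape = ".", color = "red", alpha = 0.25)
  }
  p
}

#' Plot the detection pipeline's mask chain
#'
#' Facets the recorded intermediates in pipeline order.
#'
#' @param object a `caries_detection`.
#' @param ... unused.
#' @export
autoplot.caries_detection <- function(object, ...) {
  stages <- names(object$intermediates)
  df <- dplyr::bind_rows(lapply(stages, function(nm) {
    d <- image_df(object$intermediates[[nm]])
    d$stage <- nm
    d
  }))
  df$stage <- factor(df$stage, levels = stages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~stage) +
    ggplot2::theme_void()
}
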