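#' Classifier specification
#'
#' Declared defaults (all overridable): SVM with RBF kernel, `cost = 1`,
#' `gamma = 1 / (n_features * mean feature variance)`; random forest with 100
#' trees; 5-nearest-neighbours; gradient boosted trees with 100 rounds, depth
#' 3, learning rate 0.1; plain logistic regression.
#'
#' @param name one of `"svm"`, `"rf"`, `"knn"`, `"gbt"`, `"lr"`.
#' @param params named list overriding the defaults above.
#' @param seed integer seed fixed into the spec for reproducible fits.
#' @return a list of class `caries_classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "rf", "knn", "gbt", "lr"),
                            params = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm = list(cost = 1, gamma = NULL),  # NULL -> 1/(p * mean var) at fit time
    rf  = list(ntree = 100),
    knn = list(k = 5),
    gbt = list(nrounds = 100, max_depth = 3, eta = 0.1),
    lr  = list())
  params <- utils::modifyList(defaults, params)
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "caries_classifier_spec")
}

#' Default specs for the five compared classifiers
#'
#' @param seed seed shared by all five specs.
#' @return named list of [classifier_spec()]s.
#' @export
default_classifier_specs <- function(seed = 1L) {
  nms <- c("svm", "rf", "knn", "gbt", "lr")
  setNames(lapply(nms, classifier_spec, seed = seed), nms)
}

#' Build the binary early/late dataset
#'
#' Applies the study's filtering rule: all Non-Caries (NSC) records are
#' discarded, as is every Caries-category (VNC or C) record the detector
#' missed; the remaining labels are binarized VNC vs C.
#'
#' @param records tibble with columns `id`, `label` (`"NSC"/"VNC"/"C"`) and
#'   the five feature columns.
#' @param outcomes the detector's verdict per record: either a logical vector
#'   aligned with `records` (`TRUE` = lesion correctly detected), or a tibble
#'   with columns `id` and `detected` (logical) or `outcome`
#'   (`"tp"/"fp"/"fn"/"tn"`, where `"tp"` counts as detected).
#' @return a `caries_dataset`: tibble of retained records with `label` a
#'   factor with levels `VNC`, `C`.
#' @export
filter_for_classification <- function(records, outcomes) {
  stopifnot(all(c("id", "label") %in% names(records)))
  if (is.data.frame(outcomes)) {
    if ("detected" %in% names(outcomes)) {
      det <- outcomes$detected[match(records$id, outcomes$id)]
    } else if ("outcome" %in% names(outcomes)) {
      det <- outcomes$outcome[match(records$id, outcomes$id)] == "tp"
    } else stop("outcomes needs a 'detected' or 'outcome' column", call. = FALSE)
  } else {
    det <- as.logical(outcomes)
  }
  if (length(det) != nrow(records) || anyNA(det))
    stop("every record needs a detection outcome", call. = FALSE)
  keep <- records$label %in% c("VNC", "C") & det
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no records retained after filtering", call. = FALSE)
  out$label <- factor(as.character(out$label), levels = c("VNC", "C"))
  class(out) <- c("caries_dataset", class(out))
  out
}

#' Undersample the majority class
#'
#' Randomly subsamples the majority class without replacement down to the
#' minority count; row order of retained records is preserved. Deterministic
#' given the seed.
#'
#' @param ds a `caries_dataset` (tibble with a two-level `label` factor).
#' @param seed integer seed.
#' @return balanced `caries_dataset`.
#' @export
balance_undersample <- function(ds, seed) {
  tab <- table(ds$label)
  if (length(tab) != 2L || any(tab == 0))
    stop("two classes must be present", call. = FALSE)
  if (tab[1] == tab[2]) return(ds)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  maj_idx <- which(ds$label == majority)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  keep_maj <- sort(sample(maj_idx, min(tab)))
  keep <- sort(c(which(ds$label == minority), keep_maj))
  out <- ds[keep, , drop = FALSE]
  class(out) <- class(ds)
  out
}

#' Stratified cross-validation folds
#'
#' Deterministic class-blocked assignment: within each class the records are
#' shuffled, the class blocks concatenated, and folds dealt cyclically, so
#' per-class counts and total fold sizes each differ by at most one.
#'
#' @param labels factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_cv_folds <- function(labels, k, seed) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  ord <- unlist(lapply(levels(factor(labels)), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > 1L) sample(idx) else idx
  }), use.names = FALSE)
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

# standardize features with training-fold statistics only
.scale_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# fit one classifier; returns list(predict = function(newx) list(class, score))
# where score is the continuous margin/probability for the positive class
.fit_classifier <- function(spec, x, y, positive) {
  neg <- setdiff(levels(y), positive)
  old <- .Random.seed_save()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  p <- spec$params
  switch(spec$name,
    svm = {
      gamma <- p$gamma %||% (1 / (ncol(x) * mean(apply(x, 2, var))))
      fit <- e1071::svm(x, y, kernel = "radial", cost = p$cost, gamma = gamma)
      function(newx) {
        pr <- predict(fit, newx, decision.values = TRUE)
        dv <- drop(attr(pr, "decision.values"))
        if (!grepl(paste0("^", positive, "/"), colnames(attr(pr, "decision.values"))[1]))
          dv <- -dv
        list(class = as.character(pr), score = dv)
      }
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = p$ntree)
      function(newx) {
        prob <- predict(fit, newx, type = "prob")[, positive]
        list(class = as.character(predict(fit, newx)), score = prob)
      }
    },
    knn = {
      fit <- caret::knn3(x, y, k = p$k)
      function(newx) {
        prob <- predict(fit, newx, type = "prob")[, positive]
        list(class = ifelse(prob >= 0.5, positive, neg), score = prob)
      }
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == positive))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, nthread = 1),
        data = dtrain, nrounds = p$nrounds, verbose = 0)
      function(newx) {
        prob <- predict(fit, xgboost::xgb.DMatrix(newx))
        list(class = ifelse(prob >= 0.5, positive, neg), score = prob)
      }
    },
    lr = {
      df <- as.data.frame(x)
      df$.y <- as.numeric(y == positive)
      # suppressWarnings: quasi-separation on easy folds is expected and benign
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      function(newx) {
        prob <- suppressWarnings(
          predict(fit, as.data.frame(newx), type = "response"))
        list(class = ifelse(prob >= 0.5, positive, neg), score = prob)
      }
    })
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Features are standardized with training-fold statistics only; held-out
#' predictions are pooled and metrics computed once on the pooled confusion
#' matrix (recall therefore equals sensitivity by construction); AUCROC is
#' computed from the pooled continuous scores.
#'
#' @param ds a `caries_dataset`.
#' @param spec a [classifier_spec()].
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param positive positive class for sensitivity/recall (default `"C"`,
#'   late caries).
#' @param folds optional precomputed fold vector (shared across specs by
#'   [compare_classifiers()]).
#' @return object of class `caries_cv`.
#' @export
run_cv <- function(ds, spec, k = 10, seed = 1L, positive = "C",
                   folds = NULL) {
  x <- as.matrix(ds[, feature_columns])
  y <- droplevels(factor(ds$label))
  stopifnot(nlevels(y) == 2L, positive %in% levels(y))
  if (is.null(folds)) folds <- make_cv_folds(y, k, seed)
  stopifnot(length(folds) == nrow(x))
  pred_class <- character(nrow(x))
  score <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a class is absent from a training fold", call. = FALSE)
    sc <- .scale_fit(x[tr, , drop = FALSE])
    model <- .fit_classifier(spec, .scale_apply(x[tr, , drop = FALSE], sc),
                             y[tr], positive)
    out <- model(.scale_apply(x[!tr, , drop = FALSE], sc))
    pred_class[!tr] <- out$class
    score[!tr] <- out$score
  }
  truth_pos <- y == positive
  pred_pos <- pred_class == positive
  cm <- confusion_matrix(sum(pred_pos & truth_pos), sum(pred_pos & !truth_pos),
                         sum(!pred_pos & truth_pos), sum(!pred_pos & !truth_pos),
                         positive = positive)
  pooled <- metrics_from_confusion(cm)
  pooled$aucroc <- 100 * roc_auc(score, truth_pos)
  fold_acc <- vapply(sort(unique(folds)), function(f)
    100 * mean(pred_class[folds == f] == as.character(y[folds == f])),
    numeric(1))
  structure(list(spec = spec, k = k, positive = positive, folds = folds,
                 predictions = tibble::tibble(
                   id = if ("id" %in% names(ds)) ds$id else seq_len(nrow(ds)),
                   label = as.character(y), fold = folds,
                   pred = pred_class, score = score),
                 confusion = cm, metrics = pooled,
                 fold_accuracy = fold_acc),
            class = "caries_cv")
}

#' @export
print.caries_cv <- function(x, ...) {
  cat("<caries_cv> ", toupper(x$spec$name), ", ", x$k, "-fold, positive = ",
      x$positive, "\n", sep = "")
  print(as.data.frame(lapply(x$metrics, round2)), row.names = FALSE)
  invisible(x)
}

#' Compare classifiers under shared cross-validation folds
#'
#' Runs [run_cv()] for each spec with identical fold assignments and returns
#' a ranked metric table (sorted by pooled accuracy, descending).
#'
#' @inheritParams run_cv
#' @param specs list of [classifier_spec()]s.
#' @return object of class `caries_model_comparison`: a tibble with one row
#'   per model (`model`, `accuracy`, `recall`, `precision`, `f1`,
#'   `sensitivity`, `specificity`, `aucroc`, in percent), full `caries_cv`
#'   results in attribute `cv_results`.
#' @export
compare_classifiers <- function(ds, specs = default_classifier_specs(seed),
                                k = 10, seed = 1L, positive = "C") {
  stopifnot(length(specs) >= 1L)
  y <- droplevels(factor(ds$label))
  folds <- make_cv_folds(y, k, seed)
  results <- lapply(specs, function(sp)
    run_cv(ds, sp, k = k, seed = seed, positive = positive, folds = folds))
  tab <- dplyr::bind_rows(lapply(results, function(r)
    tibble::tibble(model = toupper(r$spec$name),
                   accuracy = r$metrics$accuracy, recall = r$metrics$recall,
                   precision = r$metrics$precision, f1 = r$metrics$f1,
                   sensitivity = r$metrics$sensitivity,
                   specificity = r$metrics$specificity,
                   aucroc = r$metrics$aucroc)))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$accuracy))
  attr(tab, "cv_results") <- results
  class(tab) <- c("caries_model_comparison", class(tab))
  tab
}

#' Write a model-comparison table as CSV
#'
#' Columns in the standard report layout (Accuracy, Recall, Precision,
#' F1 Score, Sensitivity, Specificity, AUCROC, in percent, two decimals).
#'
#' @param comparison a `caries_model_comparison`.
#' @param path CSV path.
#' @export
write_comparison <- function(comparison, path) {
  out <- as.data.frame(comparison)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round2)
  names(out) <- c("Model", "Accuracy", "Recall", "Precision", "F1",
                  "Sensitivity", "Specificity", "AUCROC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
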