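#' The activity classes, in canonical order
#'
#' Level walking, stair ascent, stair descent. The order is also the
#' tie-break order for the one-vs-rest classifier.
#'
#' @return Character vector of length 3.
#' @export
activity_classes <- function() c("walk", "stairs_up", "stairs_down")

#' Assemble labeled samples from a recording's stride windows
#'
#' Joins the raw (unscaled) per-stride feature matrix with activity labels
#' and the recording's identifiers. Scaling is applied later, per
#' cross-validation fold, so that scaler parameters never leak from a test
#' fold into training.
#'
#' @param recording An [inertial_recording()].
#' @param windows Data.frame from [segment_steps()].
#' @param labels Character/factor vector of activity classes, one per window.
#' @return Data.frame: 10 feature columns, `label`, `subject_id`, `trial_id`,
#'   `start_time`.
#' @export
make_labeled_samples <- function(recording, windows, labels) {
  stopifnot(nrow(windows) == length(labels))
  labels <- factor(as.character(labels), levels = activity_classes())
  if (anyNA(labels)) stop("make_labeled_samples: unknown activity label")
  df <- as.data.frame(extract_feature_matrix(recording, windows))
  df$label <- labels
  df$subject_id <- recording$subject_id
  df$trial_id <- recording$trial_id
  df$start_time <- windows$start_time
  df
}

# Canonical sample order: results must not depend on how rows were bound
# together, so every fit sorts rows the same way first.
sort_samples <- function(samples) {
  keys <- list(samples$subject_id, samples$trial_id)
  if (!is.null(samples$start_time)) keys <- c(keys, list(samples$start_time))
  keys <- c(keys, unname(as.list(samples[feature_names()])))
  samples[do.call(order, keys), , drop = FALSE]
}

#' Train an activity classifier
#'
#' Two model families are supported: a one-vs-rest support vector machine
#' (`svm_ovr`; one RBF-kernel binary SVM per class, prediction by highest
#' decision score, ties broken by the canonical class order) and a depth-3
#' decision tree (`tree_depth3`). Features are expected already scaled to
#' the unit interval.
#'
#' @param samples Labeled sample table with scaled feature columns.
#' @param model_kind `"svm_ovr"` or `"tree_depth3"`.
#' @param seed Integer seed; training is deterministic given it.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses 1/n_features).
#' @return An object of class `har_model`.
#' @export
train_classifier <- function(samples, model_kind = c("svm_ovr", "tree_depth3"),
                             seed = 1L, cost = 1, gamma = NULL) {
  model_kind <- match.arg(model_kind)
  if (nrow(samples) < 1L) stop("train_classifier: empty training set")
  samples <- sort_samples(samples)
  x <- as.matrix(samples[feature_names()])
  y <- factor(as.character(samples$label), levels = activity_classes())
  present <- levels(droplevels(y))
  set.seed(seed)
  if (model_kind == "svm_ovr") {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    fits <- lapply(present, function(cls) {
      yb <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
      if (nlevels(droplevels(yb)) < 2L) return(NULL) # single-class set
      e1071::svm(x, yb, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE)
    })
    names(fits) <- present
    model <- list(kind = model_kind, fits = fits, classes = present)
  } else {
    df <- data.frame(x, label = y)
    fit <- rpart::rpart(label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(maxdepth = 3L,
                                                       minsplit = 4L,
                                                       cp = 1e-4,
                                                       xval = 0L))
    model <- list(kind = model_kind, fit = fit, classes = present)
  }
  model$seed <- seed
  class(model) <- "har_model"
  model
}

#' Predict activity classes for scaled feature vectors
#'
#' @param object A trained `har_model`.
#' @param newdata Numeric matrix (or single vector) of scaled features.
#' @param ... Unused.
#' @return Factor of predicted classes with the canonical three levels.
#' @export
predict.har_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  colnames(newdata) <- feature_names()
  cls <- activity_classes()
  if (length(object$classes) == 1L) {
    return(factor(rep(object$classes, nrow(newdata)), levels = cls))
  }
  if (object$kind == "svm_ovr") {
    scores <- vapply(object$classes, function(cl) {
      fit <- object$fits[[cl]]
      if (is.null(fit)) return(rep(-Inf, nrow(newdata)))
      p <- predict(fit, newdata, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # decision value is signed towards the first level of the binary
      # factor; levels were fixed as c("pos", "neg"), so positive = class
      if (colnames(dv)[1L] == "pos/neg") dv[, 1L] else -dv[, 1L]
    }, numeric(nrow(newdata)))
    scores <- matrix(scores, ncol = length(object$classes),
                     dimnames = list(NULL, object$classes))
    # argmax with ties broken by canonical class order
    ord <- match(colnames(scores), cls)
    pick <- apply(scores[, order(ord), drop = FALSE], 1L,
                  function(r) colnames(scores)[order(ord)][which.max(r)])
    factor(pick, levels = cls)
  } else {
    df <- as.data.frame(newdata)
    factor(as.character(predict(object$fit, df, type = "class")), levels = cls)
  }
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Precision, recall and F1 are
#' computed per class and averaged over all classes with equal weight;
#' classes with a zero denominator contribute 0. Accuracy is the overall
#' fraction correct.
#'
#' @param confusion Square numeric matrix, rows = true, columns = predicted.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  col_tot <- colSums(confusion)
  row_tot <- rowSums(confusion)
  prec <- ifelse(col_tot > 0, tp / col_tot, 0)
  rec <- ifelse(row_tot > 0, tp / row_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(confusion),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# One cross-validation run: fit scaler + model on the training fold, test on
# the held-out fold, return metrics and the 3x3 confusion matrix.
run_fold <- function(train, test, model_kind, seed, cost, gamma) {
  scaler <- fit_scaler(as.matrix(train[feature_names()]))
  train_sc <- train
  train_sc[feature_names()] <- apply_scaler(scaler, as.matrix(train[feature_names()]))
  model <- train_classifier(train_sc, model_kind, seed = seed,
                            cost = cost, gamma = gamma)
  pred <- predict(model, apply_scaler(scaler, as.matrix(test[feature_names()])))
  truth <- factor(as.character(test$label), levels = activity_classes())
  confusion <- table(truth, pred)
  confusion <- unclass(confusion)[activity_classes(), activity_classes()]
  c(confusion_metrics(confusion), list(confusion = confusion))
}

aggregate_runs <- function(runs, run_ids, protocol) {
  metric_tab <- function(name) {
    v <- vapply(runs, `[[`, numeric(1), name)
    c(mean = mean(v), std = stats::sd(v), min = min(v), max = max(v))
  }
  confusion <- Reduce(`+`, lapply(runs, `[[`, "confusion"))
  per_run <- data.frame(
    run = run_ids,
    accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
    precision = vapply(runs, `[[`, numeric(1), "precision"),
    recall = vapply(runs, `[[`, numeric(1), "recall"),
    f1 = vapply(runs, `[[`, numeric(1), "f1"),
    row.names = NULL)
  structure(
    list(protocol = protocol, n_runs = length(runs), per_run = per_run,
         accuracy = metric_tab("accuracy"), precision = metric_tab("precision"),
         recall = metric_tab("recall"), f1 = metric_tab("f1"),
         confusion = confusion),
    class = "har_evaluation")
}

#' @export
print.har_evaluation <- function(x, ...) {
  cat(sprintf("<har_evaluation> %s, %d runs\n", x$protocol, x$n_runs))
  m <- rbind(accuracy = x$accuracy, precision = x$precision, f1 = x$f1)
  print(round(m, 4))
  cat("summed confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' One run per subject: that subject's strides form the test fold and all
#' other subjects' strides the training fold. The min-max scaler is refit on
#' each training fold. Per-run accuracy and macro precision/recall/F1 are
#' aggregated as mean/std/min/max, and the per-run confusion matrices are
#' summed.
#'
#' @param samples Labeled sample table with raw feature columns.
#' @param model_kind `"svm_ovr"` or `"tree_depth3"`.
#' @param seed Integer seed forwarded to each fold's training.
#' @param cost,gamma SVM hyperparameters.
#' @return A `har_evaluation` object.
#' @export
evaluate_loso <- function(samples, model_kind = "svm_ovr", seed = 1L,
                          cost = 1, gamma = NULL) {
  samples <- sort_samples(samples)
  subjects <- sort(unique(samples$subject_id))
  if (length(subjects) < 2L) stop("evaluate_loso: need at least 2 subjects")
  runs <- lapply(subjects, function(s) {
    run_fold(samples[samples$subject_id != s, ],
             samples[samples$subject_id == s, ],
             model_kind, seed, cost, gamma)
  })
  aggregate_runs(runs, subjects, "leave-one-subject-out")
}

#' Leave-one-trial-out evaluation
#'
#' One run per trial: the trial forms the test fold, and the training fold
#' consists of all trials of all *other* subjects (the tested subject's
#' remaining trials are held out of training too, so a subject can never
#' inform their own test run).
#'
#' @inheritParams evaluate_loso
#' @return A `har_evaluation` object.
#' @export
evaluate_loto <- function(samples, model_kind = "svm_ovr", seed = 1L,
                          cost = 1, gamma = NULL) {
  samples <- sort_samples(samples)
  key <- paste(samples$subject_id, samples$trial_id, sep = "\r")
  trials <- unique(key)
  if (length(trials) < 2L) stop("evaluate_loto: need at least 2 trials")
  runs <- lapply(trials, function(tr) {
    subj <- samples$subject_id[match(tr, key)]
    run_fold(samples[samples$subject_id != subj, ],
             samples[key == tr, ],
             model_kind, seed, cost, gamma)
  })
  aggregate_runs(runs, sub("\r", "/", trials), "leave-one-trial-out")
}

#' Serialise an evaluation report as JSON
#'
#' @param report A `har_evaluation` object.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_evaluation_json <- function(report, file) {
  out <- list(
    protocol = report$protocol, n_runs = report$n_runs,
    metrics = list(accuracy = as.list(report$accuracy),
                   precision = as.list(report$precision),
                   recall = as.list(report$recall),
                   f1 = as.list(report$f1)),
    confusion = list(classes = activity_classes(),
                     rows = "true", columns = "predicted",
                     matrix = unname(apply(report$confusion, 1L, as.list))))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
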