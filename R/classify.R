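# Cell / non-cell discrimination: a random forest over the gyration-tensor
# morphology features plus intensity summaries, with the stratified
# split-and-accuracy evaluation protocol (default 80%:20%, repeated over
# seeds, reported as mean +/- SD).

#' Stratified random split of a labeled feature set
#'
#' Partitions rows into disjoint, exhaustive train/test sets with
#' `round(train_fraction * N)` training rows. Stratified by class by default
#' (per-class counts allocated by largest fractional remainder), which
#' protects small sets from losing a class; plain random splitting is
#' available via `stratify = FALSE`.
#'
#' @param features Tibble with a `label` column.
#' @param train_fraction In (0, 1); default 0.8.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @param stratify Stratify by class (default TRUE).
#' @return `list(train = ..., test = ...)` of tibbles.
#' @export
split_labels <- function(features, train_fraction = 0.8, seed = 1,
                         stratify = TRUE) {
  if (!"label" %in% names(features)) stop("`features` needs a `label` column", call. = FALSE)
  n <- nrow(features)
  if (n == 0L) stop("`features` is empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  set.seed(derive_seed(seed, "split"))
  n_train <- round(train_fraction * n)
  if (stratify) {
    classes <- split(seq_len(n), features$label)
    raw <- vapply(classes, length, integer(1)) * train_fraction
    base <- floor(raw)
    rem <- n_train - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    } else if (rem < 0) {
      drop <- order(raw - base)[seq_len(-rem)]
      base[drop] <- base[drop] - 1L
    }
    train_idx <- unlist(lapply(seq_along(classes), function(k) {
      idx <- classes[[k]]
      sample(idx, min(base[k], length(idx)))
    }), use.names = FALSE)
  } else {
    train_idx <- sample.int(n, n_train)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  out <- list(train = features[train_idx, ], test = features[test_idx, ])
  for (part in c("train", "test")) {
    missing <- setdiff(unique(features$label), unique(out[[part]]$label))
    if (length(missing)) {
      stop("class ", paste(missing, collapse = ", "), " absent from the ",
           part, " split; the set is too small to partition", call. = FALSE)
    }
  }
  out
}

#' Train the cell / non-cell random forest
#'
#' Fits a random forest (default 100 trees, unlimited depth, `sqrt(p)`
#' candidate features per split) on the training rows only and records
#' resubstitution and held-out accuracy. Deterministic for a fixed seed
#' (single-threaded fit).
#'
#' @param train,test Tibbles carrying [feature_columns()] and `label`; both
#'   must contain both classes.
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @return An object of class `cell_classifier` with elements `fit` (the
#'   ranger forest), `features` (persisted feature ordering), `levels`,
#'   `seed`, `train_accuracy`, `test_accuracy`, `n_train`, `n_test`.
#' @export
train_classifier <- function(train, test, seed = 1, num_trees = 100,
                             mtry = NULL) {
  feats <- feature_columns()
  for (nm in c("train", "test")) {
    tbl <- get(nm)
    miss <- setdiff(c(feats, "label"), names(tbl))
    if (length(miss)) {
      stop(nm, " set is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  x <- as.data.frame(train[feats])
  if (anyNA(x)) stop("missing feature values in training set", call. = FALSE)
  y <- factor(train$label)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = num_trees,
    mtry = mtry %||% max(1L, floor(sqrt(length(feats)))),
    seed = derive_seed(seed, "forest"),
    num.threads = 1L,
    importance = "impurity",
    respect.unordered.factors = "order"
  )
  model <- structure(
    list(fit = fit, features = feats, levels = levels(y),
         seed = as.integer(seed),
         train_accuracy = NA_real_, test_accuracy = NA_real_,
         n_train = nrow(train), n_test = nrow(test)),
    class = "cell_classifier"
  )
  model$train_accuracy <- mean(predict(model, train) == train$label)
  model$test_accuracy <- mean(predict(model, test) == test$label)
  model
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf(
    "<cell_classifier> %d trees, %d features; train accuracy %.3f (n=%d), test accuracy %.3f (n=%d)\n",
    x$fit$num.trees, length(x$features), x$train_accuracy, x$n_train,
    x$test_accuracy, x$n_test
  ))
  invisible(x)
}

#' Predict cell / non-cell labels
#'
#' @param object A [train_classifier()] model.
#' @param newdata Tibble carrying exactly the persisted feature columns
#'   (extra non-feature columns are ignored; missing features are an error).
#' @param ... Unused.
#' @return Character vector of labels, one per row (length 0 for empty input).
#' @export
predict.cell_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("missing feature columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(newdata) == 0L) return(character())
  x <- as.data.frame(newdata[object$features])
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  as.character(predict(object$fit, data = x, num.threads = 1L)$predictions)
}

#' Repeated split-train-evaluate protocol
#'
#' Repeats the stratified split and forest fit over `repeats` derived seeds
#' and reports per-split train/test accuracy; summarize with [glance()] for
#' the mean +/- SD view ("on average" accuracy over repeated random splits).
#'
#' @param features Labeled feature tibble.
#' @param train_fraction Split fraction (default 0.8).
#' @param repeats Number of repeated splits (default 10).
#' @param seed Base seed; repeat `k` uses a seed derived from `seed` and `k`.
#' @param num_trees,mtry Forest settings, as in [train_classifier()].
#' @return A tibble of class `classifier_eval`: `repeat_id`, `seed`,
#'   `train_accuracy`, `test_accuracy`.
#' @export
evaluate_classifier <- function(features, train_fraction = 0.8, repeats = 10,
                                seed = 1, num_trees = 100, mtry = NULL) {
  rows <- purrr::map_dfr(seq_len(repeats), function(k) {
    sk <- derive_seed(seed, paste0("eval", k))
    sp <- split_labels(features, train_fraction, seed = sk)
    m <- train_classifier(sp$train, sp$test, seed = sk,
                          num_trees = num_trees, mtry = mtry)
    tibble::tibble(repeat_id = k, seed = sk,
                   train_accuracy = m$train_accuracy,
                   test_accuracy = m$test_accuracy)
  })
  class(rows) <- c("classifier_eval", class(rows))
  rows
}

#' @method glance classifier_eval
#' @export
glance.classifier_eval <- function(x, ...) {
  tibble::tibble(
    repeats = nrow(x),
    mean_train_accuracy = mean(x$train_accuracy),
    sd_train_accuracy = if (nrow(x) > 1) sd(x$train_accuracy) else NA_real_,
    mean_test_accuracy = mean(x$test_accuracy),
    sd_test_accuracy = if (nrow(x) > 1) sd(x$test_accuracy) else NA_real_
  )
}

#' @method tidy cell_classifier
#' @export
tidy.cell_classifier <- function(x, ...) {
  imp <- x$fit$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @method glance cell_classifier
#' @export
glance.cell_classifier <- function(x, ...) {
  tibble::tibble(
    num_trees = x$fit$num.trees,
    n_features = length(x$features),
    n_train = x$n_train, n_test = x$n_test,
    train_accuracy = x$train_accuracy,
    test_accuracy = x$test_accuracy,
    oob_error = x$fit$prediction.error
  )
}

#' Persist / restore a trained classifier
#'
#' The archive stores the fitted forest together with the persisted feature
#' ordering and seeds; a save-load round trip is prediction-identical.
#'
#' @param model A `cell_classifier`.
#' @param path File path for the archive.
#' @return `save_classifier`: `path` invisibly. `load_classifier`: the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cell_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cell_classifier")) {
    stop("file does not contain a cell_classifier archive", call. = FALSE)
  }
  model
}
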