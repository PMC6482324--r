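#' Seeded train/test split
#'
#' Uniform sampling without replacement into disjoint train and test sets.
#' When the pool is smaller than `train_size + test_size` both sets are
#' scaled down proportionally (keeping the requested ratio), with a
#' warning; rows are never reused across the two sets.
#'
#' @param data labeled feature tibble.
#' @param train_size,test_size requested set sizes.
#' @param seed integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, train_size = 50000L, test_size = 150000L,
                             seed = 1L) {
  n <- nrow(data)
  want <- train_size + test_size
  if (n < want) {
    scale <- n / want
    train_size <- max(1L, floor(train_size * scale))
    test_size <- min(n - train_size, floor(test_size * scale))
    warning("pool of ", n, " rows smaller than requested ", want,
            "; scaled split to ", train_size, "/", test_size, call. = FALSE)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  idx <- sample.int(n, train_size + test_size)
  list(train = data[idx[seq_len(train_size)], , drop = FALSE],
       test = data[idx[train_size + seq_len(test_size)], , drop = FALSE])
}

svm_feature_matrix <- function(data, label_col) {
  num <- vapply(data, is.numeric, logical(1))
  num[names(num) %in% c(label_col, "resno")] <- FALSE
  X <- as.matrix(data[, num, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Train the supervised secondary-structure baseline
#'
#' One-vs-one multiclass support vector machine with a Gaussian kernel of
#' width `gamma = 1/N_f` (`N_f` = number of features) and regularization
#' `C = 1`, on features standardized to zero mean and unit variance using
#' statistics fitted on the training set only.
#'
#' @param train labeled training tibble; every numeric column except the
#'   label and `resno` is a feature.
#' @param label_col name of the label column.
#' @param cost regularization parameter C.
#' @param gamma kernel width; default `1 / N_f`.
#' @return An `ss_svm` object (scaler + fitted machine).
#' @export
fit_ss_svm <- function(train, label_col = "label", cost = 1.0, gamma = NULL) {
  X <- svm_feature_matrix(train, label_col)
  y <- factor(as.character(train[[label_col]]))
  if (nlevels(y) < 2L) stop("training set has a single class", call. = FALSE)
  center <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, sdev, "/")
  gamma <- gamma %||% (1 / ncol(Xs))
  fit <- e1071::svm(x = Xs, y = y, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  structure(list(svm = fit, center = center, sdev = sdev,
                 label_col = label_col, features = colnames(X),
                 gamma = gamma, cost = cost, levels = levels(y)),
            class = "ss_svm")
}

#' @export
predict.ss_svm <- function(object, newdata, ...) {
  X <- svm_feature_matrix(newdata, object$label_col)
  if (!identical(colnames(X), object$features)) {
    stop("feature columns do not match the fitted model (",
         paste(object$features, collapse = ", "), ")", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$sdev, "/")
  as.character(predict(object$svm, Xs))
}

#' Q3/Q8 accuracy of predicted labels against reference labels
#'
#' Q8 is the fraction of residues whose eight-state label is predicted
#' exactly; Q3 groups both predictions and truths into strand/helix/coil
#' (via [ss3_class()]) before comparing, so Q3 >= Q8 always.
#'
#' @param truth,prediction character vectors of label codes.
#' @return Tibble with `q3`, `q8`, `n`.
#' @export
label_accuracy <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  g3 <- function(codes) {
    cl <- ss3_class(codes)
    ifelse(is.na(cl), codes, cl)
  }
  tibble::tibble(q3 = mean(g3(prediction) == g3(truth)),
                 q8 = mean(prediction == truth),
                 n = length(truth))
}

#' Evaluate a classifier against reference labels
#'
#' Applies the fitted baseline to the test rows and scores the predicted
#' labels with [label_accuracy()].
#'
#' @param fit an `ss_svm`.
#' @param test labeled test tibble.
#' @return An `ss_report`: list with `q3`, `q8` and a per-class confusion
#'   tibble; [tidy()] returns the confusion table, [glance()] the scores.
#' @export
evaluate_ss_svm <- function(fit, test) {
  truth <- as.character(test[[fit$label_col]])
  pred <- predict(fit, test)
  acc <- label_accuracy(truth, pred)
  conf <- dplyr::count(tibble::tibble(truth = truth, prediction = pred),
                       .data$truth, .data$prediction)
  structure(list(q3 = acc$q3, q8 = acc$q8, confusion = conf,
                 n_test = length(truth)),
            class = "ss_report")
}

#' @export
print.ss_report <- function(x, ...) {
  cat("<ss_report> Q3 =", round(x$q3, 4), " Q8 =", round(x$q8, 4),
      " on", x$n_test, "residues\n")
  invisible(x)
}

#' @export
tidy.ss_report <- function(x, ...) x$confusion

#' @export
glance.ss_report <- function(x, ...) {
  tibble::tibble(q3 = x$q3, q8 = x$q8, n_test = x$n_test)
}

#' Learning curve by seeded subsampling of the training pool
#'
#' Refits the baseline at increasing training sizes and evaluates each fit
#' on the same test set.
#'
#' @param train,test labeled tibbles.
#' @param sizes training sizes to visit.
#' @param label_col label column name.
#' @param seed seed controlling the nested subsamples.
#' @return Tibble with `train_size`, `q3`, `q8`.
#' @export
ss_learning_curve <- function(train, test, sizes, label_col = "label",
                              seed = 1L) {
  purrr::map_dfr(sizes, function(s) {
    s <- min(s, nrow(train))
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed + s)
    sub <- train[sample.int(nrow(train), s), , drop = FALSE]
    fit <- fit_ss_svm(sub, label_col = label_col)
    rep <- evaluate_ss_svm(fit, test)
    tibble::tibble(train_size = s, q3 = rep$q3, q8 = rep$q8)
  })
}
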