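#' Classifier specification
#'
#' Names and families follow the benchmark roster: a prior-sampling dummy
#' baseline, five linear discriminators (ridge, logistic regression, linear
#' SVM, Gaussian naive Bayes, LDA) and five nonlinear ones (QDA, decision
#' tree, random forest, gradient boosting untuned and tuned).
#'
#' @param name classifier name (see [default_classifier_specs()]).
#' @param hyperparameters named list of overrides for the backing estimator.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparameters = list()) {
  families <- c(dummy = "baseline", ridge = "linear", logistic_regression = "linear",
                sgd_svm = "linear", gaussian_nb = "linear", lda = "linear",
                qda = "nonlinear", decision_tree = "nonlinear",
                random_forest = "nonlinear", gradient_boosting = "nonlinear",
                gradient_boosting_tuned = "nonlinear")
  if (!name %in% names(families)) stop("unknown classifier name: ", name)
  structure(list(name = name, family = unname(families[name]),
                 hyperparameters = hyperparameters), class = "classifier_spec")
}

#' Default benchmark roster: dummy baseline plus ten classifiers
#' @return list of [classifier_spec()] objects (11 entries).
#' @export
default_classifier_specs <- function() {
  lapply(c("dummy", "ridge", "logistic_regression", "sgd_svm", "gaussian_nb",
           "lda", "qda", "decision_tree", "random_forest", "gradient_boosting",
           "gradient_boosting_tuned"), classifier_spec)
}

# Internal: map LightGBM-style hyperparameter names onto xgboost parameters.
# bagging_freq > 0 enables per-tree row subsampling (xgboost has no
# every-k-rounds bagging schedule).
gbm_params_to_xgb <- function(hp, n_classes) {
  hp <- utils::modifyList(list(lambda_l1 = 0, lambda_l2 = 1, num_leaves = 31L,
                               feature_fraction = 1, bagging_fraction = 1,
                               bagging_freq = 0L, learning_rate = 0.1,
                               nrounds = 100L), hp)
  list(params = list(
    objective = "multi:softprob", num_class = n_classes,
    tree_method = "hist", grow_policy = "lossguide",
    max_depth = 0L, max_leaves = as.integer(hp$num_leaves),
    eta = hp$learning_rate, alpha = hp$lambda_l1, lambda = hp$lambda_l2,
    colsample_bytree = hp$feature_fraction,
    subsample = if (hp$bagging_freq > 0) hp$bagging_fraction else 1,
    nthread = 1L
  ), nrounds = as.integer(hp$nrounds))
}

fit_gbm <- function(x, y, n_classes, hp = list(), seed = 1L) {
  colnames(x) <- if (is.null(colnames(x))) sprintf("f%04d", seq_len(ncol(x))) else colnames(x)
  cfg <- gbm_params_to_xgb(hp, n_classes)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = c(cfg$params, list(seed = seed)),
                                data = dtrain, nrounds = cfg$nrounds, verbose = 0)
  list(booster = booster, n_classes = n_classes, feature_names = colnames(x))
}

predict_gbm <- function(fit, x) {
  colnames(x) <- fit$feature_names
  p <- predict(fit$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  if (is.null(dim(p))) p <- matrix(p, ncol = fit$n_classes, byrow = TRUE)
  max.col(p, ties.method = "first") - 1L
}

#' Fit one benchmark classifier
#'
#' @param spec a [classifier_spec()] or classifier name.
#' @param x numeric feature matrix (samples x features); t = 1 samples are
#'   flattened 1-TR ROI vectors.
#' @param y 0-based integer class labels.
#' @param n_classes number of classes (defaults to `max(y) + 1`).
#' @param seed integer seed for stochastic estimators.
#' @return object of class `rd_classifier` supporting [predict()] (returns
#'   0-based hard labels).
#' @export
fit_classifier <- function(spec, x, y, n_classes = max(y) + 1L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  lev <- as.character(0:(n_classes - 1L))
  yf <- factor(y, levels = lev)
  hp <- spec$hyperparameters
  set.seed(seed)
  fit <- switch(spec$name,
    dummy = list(prop = as.numeric(table(yf)) / length(yf)),
    ridge = {
      fam <- if (n_classes == 2L) "binomial" else "multinomial"
      list(model = glmnet::glmnet(x, yf, family = fam, alpha = 0,
                                  lambda = hp$lambda %||% 1),
           lambda = hp$lambda %||% 1)
    },
    logistic_regression = {
      df <- data.frame(.y = yf, x)
      list(model = nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                  maxit = hp$maxit %||% 200, MaxNWts = 1e5),
           cols = colnames(df)[-1])
    },
    sgd_svm = list(model = e1071::svm(x, yf, kernel = "linear",
                                      cost = hp$cost %||% 1, scale = FALSE)),
    gaussian_nb = list(model = e1071::naiveBayes(x, yf)),
    lda = list(model = MASS::lda(x, grouping = yf)),
    qda = list(model = MASS::qda(x, grouping = yf)),
    decision_tree = {
      df <- data.frame(.y = yf, x)
      list(model = rpart::rpart(.y ~ ., data = df, method = "class"),
           cols = colnames(df)[-1])
    },
    random_forest = list(model = ranger::ranger(
      x = x, y = yf, num.trees = hp$num.trees %||% 500L, seed = seed,
      num.threads = 1L)),
    gradient_boosting = fit_gbm(x, y, n_classes, hp, seed),
    gradient_boosting_tuned = fit_gbm(x, y, n_classes, hp, seed)
  )
  structure(list(spec = spec, fit = fit, levels = lev, n_features = ncol(x),
                 seed = seed), class = "rd_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict hard class labels
#'
#' @param object an `rd_classifier`.
#' @param newdata feature matrix or `n x rois x t` array (flattened).
#' @param ... unused.
#' @return integer vector of 0-based class labels.
#' @export
predict.rd_classifier <- function(object, newdata, ...) {
  x <- if (length(dim(newdata)) == 3L) flatten_samples(newdata) else as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  name <- object$spec$name
  lev <- object$levels
  out <- switch(name,
    dummy = sample(lev, nrow(x), replace = TRUE, prob = object$fit$prop),
    ridge = {
      p <- predict(object$fit$model, x, s = object$fit$lambda, type = "class")
      as.character(p)
    },
    logistic_regression = {
      df <- as.data.frame(x)
      colnames(df) <- object$fit$cols
      as.character(predict(object$fit$model, newdata = df))
    },
    sgd_svm = as.character(predict(object$fit$model, x)),
    gaussian_nb = as.character(predict(object$fit$model, x)),
    lda = as.character(predict(object$fit$model, x)$class),
    qda = as.character(predict(object$fit$model, x)$class),
    decision_tree = {
      df <- as.data.frame(x)
      colnames(df) <- object$fit$cols
      as.character(predict(object$fit$model, newdata = df, type = "class"))
    },
    random_forest = as.character(predict(object$fit$model, data = x,
                                         num.threads = 1L)$predictions),
    gradient_boosting = return(predict_gbm(object$fit, x)),
    gradient_boosting_tuned = return(predict_gbm(object$fit, x))
  )
  as.integer(out)
}

#' Hard-label predictions from any supported model
#'
#' Dispatch helper used by the perturbation-importance machinery: accepts an
#' `rd_classifier`, an `rd_nn` neural model, or a plain R function mapping an
#' `n x rois x t` array to labels (useful for analytic toy models in tests).
#'
#' @param model fitted model or function.
#' @param x `n x rois x t` sample array.
#' @return integer labels.
#' @export
predict_labels <- function(model, x) {
  if (is.function(model)) return(model(x))
  if (inherits(model, "rd_classifier")) return(predict(model, x))
  if (inherits(model, "rd_nn")) return(predict(model, x, type = "class"))
  stop("unsupported model type: ", paste(class(model), collapse = "/"))
}
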