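# Cross-validated classifier bench for the binary (AD vs rest) task: a bench
# of linear, kernel, tree and Bayes model families, six metrics per model
# under k-fold CV, per-model feature importances, and AUC-gated top-k
# consensus feature selection.

# ---- scaling ----------------------------------------------------------------

fit_scaler <- function(X, type = c("none", "minmax", "zscore")) {
  type <- match.arg(type)
  if (type == "none") return(list(type = "none"))
  if (type == "minmax") {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    span <- hi - lo
    span[span == 0] <- 1
    return(list(type = "minmax", lo = lo, span = span))
  }
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(type = "zscore", mu = mu, sd = sd)
}

apply_scaler <- function(X, scaler) {
  switch(scaler$type,
    none = X,
    minmax = sweep(sweep(X, 2, scaler$lo, "-"), 2, scaler$span, "/"),
    zscore = sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sd, "/"))
}

# Minimum-norm least squares via SVD pseudo-inverse (stable when features
# outnumber subjects, where the normal equations are singular).
pinv_lstsq <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  d_inv <- ifelse(sv$d > tol * sv$d[1], 1 / sv$d, 0)
  sv$v %*% (d_inv * (t(sv$u) %*% y))
}

# ---- adapter constructor ----------------------------------------------------

#' Construct a model adapter for the classifier bench
#'
#' An adapter bundles a fit function, a scoring function, an importance
#' extractor and a bounded hyperparameter sampler behind one interface, so
#' the bench can treat heterogeneous model families uniformly.
#'
#' @param name Display name.
#' @param family One of `linear`, `tree`, `kernel`, `bayes`.
#' @param scaling Feature scaling fit on the training fold only: `none`,
#'   `minmax` or `zscore`.
#' @param fit `function(X, y01, params)` returning a fitted model.
#' @param score `function(model, X)` returning a numeric score per row.
#' @param importance `function(model, feature_names)` returning a
#'   non-negative importance per feature (|coefficient| for linear models,
#'   split gain or split frequency for tree models).
#' @param score_type `"prob"` if scores are probabilities, `"raw"` if they
#'   need min-max rescaling (fitted on training scores) before threshold
#'   metrics.
#' @param default_params Named list of default hyperparameters.
#' @param sample_params `function()` drawing one hyperparameter configuration
#'   from the bounded search space (uses the current RNG stream).
#' @return A `pwabs_model_adapter` object.
#' @export
model_adapter <- function(name, family, scaling, fit, score, importance,
                          score_type = c("prob", "raw"),
                          default_params = list(),
                          sample_params = function() default_params) {
  family <- match.arg(family, c("linear", "tree", "kernel", "bayes"))
  scaling <- match.arg(scaling, c("none", "minmax", "zscore"))
  structure(list(name = name, family = family, scaling = scaling,
                 fit = fit, score = score, importance = importance,
                 score_type = match.arg(score_type),
                 default_params = default_params,
                 sample_params = sample_params),
            class = "pwabs_model_adapter")
}

# glmnet needs >= 2 columns; duplicate a column for degenerate toy inputs
glmnet_x <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `..pad` = X[, 1])
}

glmnet_coefs <- function(model, feature_names) {
  b <- as.numeric(glmnet::coef.glmnet(model))[-1]  # drop intercept
  b <- b[seq_along(feature_names)]
  stats::setNames(abs(b), feature_names)
}

#' Default classifier bench
#'
#' Fourteen adapters spanning the linear, kernel, tree and Bayes families:
#' minimum-norm linear regression, Lasso, Ridge, L2-penalized logistic
#' regression with min-max or z-score scaling, linear SVM with min-max or
#' z-score scaling, random forest, depth-wise gradient boosting (two
#' learning-rate variants), leaf-wise (loss-guided) gradient boosting, a
#' stump-ensemble gradient boost, a single decision tree, and Gaussian naive
#' Bayes. Model fitting is delegated to glmnet, e1071, randomForest, rpart
#' and xgboost; folds, scaling, metrics, importances and consensus are
#' computed here.
#'
#' @return Named list of [model_adapter] objects.
#' @export
default_bench <- function() {
  linear_reg <- model_adapter(
    "Linear Regression (min-norm)", "linear", "none",
    fit = function(X, y, params) {
      Xi <- cbind(`(Intercept)` = 1, X)
      list(beta = pinv_lstsq(Xi, y), features = colnames(X))
    },
    score = function(model, X) drop(cbind(1, X) %*% model$beta),
    importance = function(model, fn) stats::setNames(abs(model$beta[-1]), fn),
    score_type = "raw")

  make_glmnet <- function(name, alpha, family, scaling, lambda, score_type) {
    model_adapter(
      name, "linear", scaling,
      fit = function(X, y, params) {
        glmnet::glmnet(glmnet_x(X), y, alpha = alpha, family = family,
                       lambda = params$lambda, standardize = FALSE)
      },
      score = function(model, X) {
        drop(stats::predict(model, newx = glmnet_x(X), type = "response"))
      },
      importance = glmnet_coefs,
      score_type = score_type,
      default_params = list(lambda = lambda),
      sample_params = function() list(lambda = 10^stats::runif(1, -4, 1)))
  }

  make_svm <- function(name, scaling) {
    model_adapter(
      name, "kernel", scaling,
      fit = function(X, y, params) {
        yf <- factor(y, levels = c(0, 1))
        m <- e1071::svm(X, yf, kernel = "linear", cost = params$cost,
                        scale = FALSE)
        # orient decision values so the positive class scores higher,
        # using training data only
        dv <- attr(stats::predict(m, X, decision.values = TRUE),
                   "decision.values")[, 1]
        flip <- roc_auc(dv, y) < 0.5
        list(svm = m, flip = flip, features = colnames(X))
      },
      score = function(model, X) {
        dv <- attr(stats::predict(model$svm, X, decision.values = TRUE),
                   "decision.values")[, 1]
        if (model$flip) -dv else dv
      },
      importance = function(model, fn) {
        w <- drop(t(model$svm$coefs) %*% model$svm$SV)
        stats::setNames(abs(w)[seq_along(fn)], fn)
      },
      score_type = "raw",
      default_params = list(cost = 1),
      sample_params = function() list(cost = 10^stats::runif(1, -2, 2)))
  }

  make_xgb <- function(name, default_params, sampler) {
    model_adapter(
      name, "tree", "none",
      fit = function(X, y, params) {
        nrounds <- params$nrounds
        params$nrounds <- NULL
        params <- c(params, list(objective = "binary:logistic", nthread = 1))
        dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
        xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                           verbose = 0)
      },
      score = function(model, X) {
        stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
      },
      importance = function(model, fn) {
        imp <- stats::setNames(rep(0, length(fn)), fn)
        tab <- tryCatch(xgboost::xgb.importance(model = model),
                        error = function(e) NULL)
        if (!is.null(tab) && nrow(tab) > 0)
          imp[tab$Feature] <- tab$Gain
        imp
      },
      score_type = "prob",
      default_params = default_params,
      sample_params = sampler)
  }

  list(
    linear_regression = linear_reg,
    lasso = make_glmnet("Lasso Regression", 1, "gaussian", "none",
                        lambda = 0.05, score_type = "raw"),
    ridge = make_glmnet("Ridge Regression", 0, "gaussian", "none",
                        lambda = 1, score_type = "raw"),
    logistic_minmax = make_glmnet("Logistic Regression (min-max)", 0,
                                  "binomial", "minmax", lambda = 0.05,
                                  score_type = "prob"),
    logistic_zscore = make_glmnet("Logistic Regression (z-score)", 0,
                                  "binomial", "zscore", lambda = 0.05,
                                  score_type = "prob"),
    svm_minmax = make_svm("Linear SVM (min-max)", "minmax"),
    svm_zscore = make_svm("Linear SVM (z-score)", "zscore"),
    random_forest = model_adapter(
      "Random Forest", "tree", "none",
      fit = function(X, y, params) {
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = params$ntree, mtry = params$mtry(ncol(X)))
      },
      score = function(model, X) stats::predict(model, X, type = "prob")[, "1"],
      importance = function(model, fn) {
        imp <- randomForest::importance(model)[, 1]
        stats::setNames(imp[fn], fn)
      },
      score_type = "prob",
      default_params = list(ntree = 300, mtry = function(p) max(1, floor(sqrt(p)))),
      sample_params = function() {
        frac <- stats::runif(1, 0.05, 0.8)
        list(ntree = sample(100:500, 1),
             mtry = function(p) max(1, floor(p * frac)))
      }),
    xgboost = make_xgb("XGBoost",
      list(nrounds = 50, max_depth = 3, eta = 0.3),
      function() list(nrounds = sample(20:150, 1),
                      max_depth = sample(2:6, 1),
                      eta = 10^stats::runif(1, -2, -0.3))),
    boost_leafwise = make_xgb("Gradient Boosting (leaf-wise)",
      list(nrounds = 60, eta = 0.1, tree_method = "hist",
           grow_policy = "lossguide", max_depth = 0, max_leaves = 8),
      function() list(nrounds = sample(20:150, 1), eta = 10^stats::runif(1, -2, -0.3),
                      tree_method = "hist", grow_policy = "lossguide",
                      max_depth = 0, max_leaves = sample(4:16, 1))),
    boost_lowlr = make_xgb("Gradient Boosting (slow rate)",
      list(nrounds = 150, max_depth = 4, eta = 0.05, subsample = 0.9),
      function() list(nrounds = sample(50:250, 1), max_depth = sample(2:6, 1),
                      eta = 10^stats::runif(1, -2.5, -1), subsample = stats::runif(1, 0.5, 1))),
    gradient_boosting = make_xgb("Gradient Boosting Machine",
      list(nrounds = 100, max_depth = 1, eta = 0.1),
      function() list(nrounds = sample(50:200, 1), max_depth = sample(1:3, 1),
                      eta = 10^stats::runif(1, -2, -0.5))),
    decision_tree = model_adapter(
      "Decision Tree", "tree", "none",
      fit = function(X, y, params) {
        df <- data.frame(X, check.names = FALSE)
        df$..y <- factor(y, levels = c(0, 1))
        rpart::rpart(..y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = params$cp,
                                                    minsplit = params$minsplit))
      },
      score = function(model, X) {
        stats::predict(model, data.frame(X, check.names = FALSE))[, "1"]
      },
      importance = function(model, fn) {
        imp <- stats::setNames(rep(0, length(fn)), fn)
        vi <- model$variable.importance
        if (!is.null(vi)) imp[names(vi)] <- vi
        imp
      },
      score_type = "prob",
      default_params = list(cp = 0.01, minsplit = 5),
      sample_params = function() list(cp = 10^stats::runif(1, -4, -1),
                                      minsplit = sample(2:10, 1))),
    naive_bayes = model_adapter(
      "Naive Bayes", "bayes", "none",
      fit = function(X, y, params) {
        list(nb = e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
             X = X, y = y)
      },
      score = function(model, X) {
        stats::predict(model$nb, X, type = "raw")[, "1"]
      },
      importance = function(model, fn) {
        # standardized mean difference between classes per feature
        x1 <- model$X[model$y == 1, , drop = FALSE]
        x0 <- model$X[model$y == 0, , drop = FALSE]
        sd_pooled <- apply(model$X, 2, stats::sd)
        sd_pooled[sd_pooled == 0] <- 1
        stats::setNames(abs(colMeans(x1) - colMeans(x0)) / sd_pooled, fn)
      },
      score_type = "prob")
  )
}

# ---- cross-validation -------------------------------------------------------

#' k-fold assignment
#'
#' Shuffles subject order by the seed, then deals subjects into k consecutive
#' chunks whose sizes differ by at most one.
#'
#' @param n_subjects Number of subjects.
#' @param k Number of folds, `2 <= k <= n_subjects`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per subject.
#' @export
kfold_split <- function(n_subjects, k, seed) {
  if (k > n_subjects) stop("kfold_split: k exceeds the number of subjects")
  if (k < 2L) stop("kfold_split: need k >= 2")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- sample(n_subjects)
  sizes <- rep(n_subjects %/% k, k) + c(rep(1L, n_subjects %% k),
                                        rep(0L, k - n_subjects %% k))
  folds <- integer(n_subjects)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

fold_metrics <- function(scores, y_test) {
  ok_two <- length(unique(y_test)) == 2L
  list(
    roc_auc = if (ok_two) roc_auc(scores, y_test) else NaN,
    pr_auc = if (any(y_test == 1L)) pr_auc(scores, y_test) else NaN,
    tm = threshold_metrics(scores, y_test, threshold = 0.5))
}

#' Cross-validated evaluation of one adapter
#'
#' Per fold: scaling parameters are fit on the training portion only and
#' applied to the held-out fold; the adapter is fit on the training portion;
#' scores on the held-out fold give ROC-AUC, PR-AUC, accuracy, precision,
#' recall and F1. Raw-score adapters are min-max rescaled with the training
#' fold's score range before threshold metrics. A fold where fitting fails or
#' a metric is undefined contributes NaN and is excluded from the mean with a
#' warning. The importance vector comes from a final fit on the full data.
#'
#' @param adapter A [model_adapter].
#' @param X Subjects x features numeric matrix.
#' @param y Binary labels (see [roc_auc]).
#' @param folds Either a fold-id vector from [kfold_split] or a single k.
#' @param seed Seed for fold dealing and any stochastic fitting.
#' @param params Hyperparameters (default: the adapter's defaults).
#' @return A `pwabs_cv_report`: per-fold metric data.frame, means, folds,
#'   seed and named importance vector.
#' @export
evaluate_model <- function(adapter, X, y, folds = 5L, seed = 1L,
                           params = adapter$default_params) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as_binary_labels(y)
  if (length(folds) == 1L) {
    # re-deal by seed increment until every training fold holds both classes
    s <- seed
    repeat {
      fvec <- kfold_split(length(y), folds, s)
      ok <- all(vapply(seq_len(max(fvec)), function(f)
        length(unique(y[fvec != f])) == 2L, logical(1)))
      if (ok) break
      s <- s + 1L
      if (s - seed > 50L) stop("evaluate_model: cannot deal folds with both classes")
    }
    if (s != seed) message("evaluate_model: folds re-dealt with seed ", s)
    folds <- fvec
  }
  k <- max(folds)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    res <- tryCatch({
      scaler <- fit_scaler(X[tr, , drop = FALSE], adapter$scaling)
      Xtr <- apply_scaler(X[tr, , drop = FALSE], scaler)
      Xte <- apply_scaler(X[te, , drop = FALSE], scaler)
      set.seed(seed + 1000L * f)
      model <- adapter$fit(Xtr, y[tr], params)
      s_te <- adapter$score(model, Xte)
      if (adapter$score_type == "raw") {
        s_tr <- adapter$score(model, Xtr)
        lo <- min(s_tr); hi <- max(s_tr)
        if (hi - lo > 0) s_te <- (s_te - lo) / (hi - lo)
        s_te <- pmin(1, pmax(0, s_te))
      }
      m <- fold_metrics(s_te, y[te])
      data.frame(fold = f, roc_auc = m$roc_auc, pr_auc = m$pr_auc,
                 accuracy = m$tm$accuracy, precision = m$tm$precision,
                 recall = m$tm$recall, f1 = m$tm$f1)
    }, error = function(e) {
      warning("evaluate_model[", adapter$name, "] fold ", f, " failed: ",
              conditionMessage(e))
      data.frame(fold = f, roc_auc = NaN, pr_auc = NaN, accuracy = NaN,
                 precision = NaN, recall = NaN, f1 = NaN)
    })
    per_fold[[f]] <- res
  }
  per_fold <- do.call(rbind, per_fold)
  means <- colMeans(per_fold[, -1], na.rm = TRUE)
  if (any(is.nan(as.matrix(per_fold[, -1]))))
    warning("evaluate_model[", adapter$name,
            "]: some folds undefined; means exclude them")

  # importance from a final full-data fit
  scaler <- fit_scaler(X, adapter$scaling)
  set.seed(seed + 99991L)
  final_model <- tryCatch(adapter$fit(apply_scaler(X, scaler), y, params),
                          error = function(e) NULL)
  imp <- if (is.null(final_model)) {
    stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  } else {
    adapter$importance(final_model, colnames(X))
  }
  structure(list(name = adapter$name, per_fold = per_fold,
                 mean_metrics = as.list(means), folds = folds, seed = seed,
                 params = params, importance = imp),
            class = "pwabs_cv_report")
}

#' @export
print.pwabs_cv_report <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("%s: ROC-AUC %.3f, PR-AUC %.3f, acc %.3f, prec %.3f, rec %.3f, F1 %.3f\n",
              x$name, m$roc_auc, m$pr_auc, m$accuracy, m$precision, m$recall,
              m$f1))
  invisible(x)
}

#' Bounded random hyperparameter search
#'
#' Evaluates `budget` configurations (the adapter defaults first, then draws
#' from the adapter's bounded sampler) on fixed folds and returns the argmax
#' by mean CV ROC-AUC. Deterministic given the seed.
#'
#' @inheritParams evaluate_model
#' @param budget Number of configurations to evaluate (>= 1).
#' @return List with `best_params`, `best_score`, `scores` (one per
#'   configuration) and `configs`.
#' @export
hyperparameter_search <- function(adapter, X, y, folds = 5L, budget = 5L,
                                  seed = 1L) {
  if (budget < 1L) stop("hyperparameter_search: budget must be >= 1")
  if (length(folds) == 1L) folds <- kfold_split(nrow(as.matrix(X)), folds, seed)
  configs <- vector("list", budget)
  configs[[1L]] <- adapter$default_params
  if (budget > 1L) {
    for (i in 2:budget) {
      set.seed(seed + i)
      configs[[i]] <- adapter$sample_params()
    }
  }
  scores <- vapply(configs, function(p) {
    r <- suppressWarnings(evaluate_model(adapter, X, y, folds = folds,
                                         seed = seed, params = p))
    v <- r$mean_metrics$roc_auc
    if (is.nan(v)) -Inf else v
  }, numeric(1))
  best <- which.max(scores)
  list(best_params = configs[[best]], best_score = scores[best],
       scores = scores, configs = configs)
}

#' Run the full bench
#'
#' @param X Subjects x features matrix.
#' @param y Binary labels.
#' @param adapters Named list of adapters (default [default_bench]).
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed (folds shared across adapters).
#' @param budget If > 0, run [hyperparameter_search] with this budget per
#'   adapter before the final evaluation.
#' @return A `pwabs_bench`: list of `pwabs_cv_report`s plus a summary
#'   data.frame `table` (model x six metrics).
#' @export
bench_run <- function(X, y, adapters = default_bench(), k = 5L, seed = 1L,
                      budget = 0L) {
  X <- as.matrix(X)
  folds <- kfold_split(nrow(X), k, seed)
  y01 <- as_binary_labels(y)
  # shared folds must have two-class training portions for every adapter
  s <- seed
  while (!all(vapply(seq_len(k), function(f)
    length(unique(y01[folds != f])) == 2L, logical(1)))) {
    s <- s + 1L
    folds <- kfold_split(nrow(X), k, s)
  }
  reports <- lapply(adapters, function(ad) {
    params <- ad$default_params
    if (budget > 0L) {
      params <- hyperparameter_search(ad, X, y01, folds = folds,
                                      budget = budget, seed = seed)$best_params
    }
    evaluate_model(ad, X, y01, folds = folds, seed = seed, params = params)
  })
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$name, roc_auc = r$mean_metrics$roc_auc,
               pr_auc = r$mean_metrics$pr_auc,
               accuracy = r$mean_metrics$accuracy,
               precision = r$mean_metrics$precision,
               recall = r$mean_metrics$recall, f1 = r$mean_metrics$f1,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(reports = reports, table = tab, folds = folds, seed = seed),
            class = "pwabs_bench")
}

#' @export
print.pwabs_bench <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}

#' AUC-gated top-k consensus feature selection
#'
#' Keeps models whose mean CV ROC-AUC exceeds `auc_gate`, ranks each
#' qualifying model's features by importance magnitude (ties broken by stable
#' feature order), takes the top `top_k` per model, and selects features
#' appearing in at least `min_models` of those lists.
#'
#' @param reports List of `pwabs_cv_report`s (or a `pwabs_bench`).
#' @param auc_gate Qualification threshold on mean ROC-AUC (exclusive).
#' @param top_k Features taken per qualifying model.
#' @param min_models Minimum number of top-k lists a feature must appear in.
#' @return A `pwabs_consensus`: `qualifying` model names, `top_lists`,
#'   `counts` (per feature), `selected` feature ids. Empty (with a warning)
#'   when no model passes the gate.
#' @export
consensus_select <- function(reports, auc_gate = 0.96, top_k = 10L,
                             min_models = 2L) {
  if (inherits(reports, "pwabs_bench")) reports <- reports$reports
  if (length(reports) < 1L) stop("consensus_select: need at least one report")
  aucs <- vapply(reports, function(r) r$mean_metrics$roc_auc, numeric(1))
  qual <- which(!is.nan(aucs) & aucs > auc_gate)
  if (length(qual) == 0L) {
    warning("consensus_select: no model passed the ROC-AUC gate of ", auc_gate)
    return(structure(list(qualifying = character(0), top_lists = list(),
                          counts = integer(0), selected = character(0),
                          auc_gate = auc_gate, top_k = top_k,
                          min_models = min_models),
                     class = "pwabs_consensus"))
  }
  top_lists <- lapply(reports[qual], function(r) {
    imp <- r$importance
    ord <- order(-imp, seq_along(imp))
    names(imp)[ord][seq_len(min(top_k, length(imp)))]
  })
  names(top_lists) <- vapply(reports[qual], function(r) r$name, character(1))
  counts <- table(unlist(top_lists, use.names = FALSE))
  counts <- counts[order(-as.integer(counts), names(counts))]
  selected <- sort(names(counts)[counts >= min_models])
  structure(list(qualifying = names(top_lists), top_lists = top_lists,
                 counts = counts, selected = selected, auc_gate = auc_gate,
                 top_k = top_k, min_models = min_models),
            class = "pwabs_consensus")
}

#' @export
print.pwabs_consensus <- function(x, ...) {
  cat(sprintf("consensus: %d qualifying model(s) (gate %.2f), %d selected feature(s)\n",
              length(x$qualifying), x$auc_gate, length(x$selected)))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Binary task labels from diagnoses
#'
#' @param diagnosis Character vector of `AD` / `DLB` / `CNI`.
#' @param positive The positive class (default `"AD"`, giving the
#'   AD-vs-rest task).
#' @return Integer 0/1 labels.
#' @export
binary_labels <- function(diagnosis, positive = "AD") {
  as.integer(diagnosis == positive)
}
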