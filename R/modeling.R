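#' SMOTE class balancing
#'
#' Equalises the two classes by synthesising minority rows as convex
#' combinations of minority nearest-neighbour pairs: a synthetic row is
#' `x_i + u (x_j - x_i)` with `u ~ U(0, 1)` and `x_j` one of the `k`
#' nearest minority neighbours of `x_i` (Euclidean distance). Intended to
#' be applied inside training folds only.
#'
#' @param features Feature tibble or matrix (numeric columns only;
#'   `patient_id` is dropped if present).
#' @param labels Binary labels aligned with the rows.
#' @param seed Integer seed.
#' @param k Neighbour count, default 5 (capped at the minority size - 1).
#' @return List with `features` (tibble) and `labels` (0/1 vector), classes
#'   equal-sized; synthetic rows appended after the originals.
#' @export
smote_balance <- function(features, labels, seed = 1, k = 5) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) {
    return(list(features = tibble::as_tibble(x), labels = y))
  }
  minority <- if (n1 < n0) 1 else 0
  xm <- x[y == minority, , drop = FALSE]
  n_min <- nrow(xm)
  if (n_min < 2) stop("minority class has fewer than 2 samples; merge folds or enlarge the split")
  n_new <- abs(n0 - n1)
  k_eff <- min(k, n_min - 1)
  d2 <- as.matrix(stats::dist(xm))^2
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(r) order(r)[seq_len(k_eff)])
  nn <- if (k_eff == 1) matrix(ord, ncol = 1) else t(ord)
  synth <- with_seed(seed, {
    i <- sample.int(n_min, n_new, replace = TRUE)
    j <- nn[cbind(i, sample.int(k_eff, n_new, replace = TRUE))]
    u <- runif(n_new)
    xm[i, , drop = FALSE] + u * (xm[j, , drop = FALSE] - xm[i, , drop = FALSE])
  })
  list(features = tibble::as_tibble(rbind(x, synth)),
       labels = c(y, rep(minority, n_new)))
}

#' Model specification for signature training
#'
#' @param kind One of `"logistic"`, `"random_forest"`,
#'   `"gradient_boosting_xgb_style"` (depth-wise trees),
#'   `"gradient_boosting_lgbm_style"` (leaf-wise, histogram-based trees).
#' @param grid Data frame of hyperparameter combinations; `NULL` uses a
#'   small default grid per kind.
#' @param cv_folds Cross-validation folds for the grid search; default 5.
#' @param seed Integer seed.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("logistic", "random_forest",
                                "gradient_boosting_xgb_style",
                                "gradient_boosting_lgbm_style"),
                       grid = NULL, cv_folds = 5, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("hyperparameter grid is empty")
  structure(list(kind = kind, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

default_grid <- function(kind) {
  switch(kind,
    logistic = data.frame(dummy = 0),
    random_forest = expand.grid(num_trees = c(100, 300),
                                min_node_size = c(1, 5)),
    gradient_boosting_xgb_style = expand.grid(max_depth = c(2, 3),
                                              eta = c(0.05, 0.1),
                                              nrounds = c(100, 300)),
    gradient_boosting_lgbm_style = expand.grid(max_leaves = c(7, 15),
                                               eta = c(0.05, 0.1),
                                               nrounds = c(100, 300)))
}

fit_one_model <- function(kind, params, x, y, seed) {
  with_seed(seed, switch(kind,
    logistic = {
      df <- data.frame(y = y, x)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = params$num_trees,
      min.node.size = params$min_node_size, seed = seed,
      num.threads = 1),
    gradient_boosting_xgb_style = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = params$nrounds, verbose = 0),
    gradient_boosting_lgbm_style = xgboost::xgb.train(
      params = list(objective = "binary:logistic", tree_method = "hist",
                    grow_policy = "lossguide", max_leaves = params$max_leaves,
                    max_depth = 0, eta = params$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = params$nrounds, verbose = 0)))
}

predict_prob <- function(kind, fit, x) {
  switch(kind,
    logistic = as.numeric(predict(fit, newdata = data.frame(x),
                                  type = "response")),
    random_forest = predict(fit, data = as.data.frame(x),
                            num.threads = 1)$predictions[, "1"],
    as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))))
}

# Rank-based AUC (Mann-Whitney with half-weight ties); fast path used
# inside cross-validation loops.
auc_rank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train one signature model
#'
#' Grid search by mean cross-validated AUC with SMOTE applied inside each
#' training fold (validation folds are never resampled), then a refit of
#' the best configuration on the SMOTE-balanced full training split.
#'
#' @param table Training feature tibble.
#' @param labels Training labels.
#' @param spec A `model_spec`.
#' @param branch Branch name carried in the result.
#' @return A `signature_model`: fitted estimator, chosen hyperparameters,
#'   feature names, and the CV grid results (`cv_results` tibble).
#' @export
train_signature <- function(table, labels, spec = model_spec(),
                            branch = "signature") {
  x <- feature_matrix(table)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  folds <- with_seed(spec$seed, make_stratified_folds(y, spec$cv_folds))
  folds <- folds[lengths(folds) > 0]

  grid <- spec$grid
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- grid[gi, , drop = FALSE]
    aucs <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      test_idx <- folds[[fi]]
      keep <- setdiff(seq_along(y), test_idx)
      xtr <- x[keep, , drop = FALSE]; ytr <- y[keep]
      if (length(unique(ytr)) < 2 || min(table(ytr)) < 2 ||
          length(unique(y[test_idx])) < 2) {
        aucs[fi] <- NA_real_
        next
      }
      bal <- smote_balance(xtr, ytr, seed = spec$seed + 31L * fi)
      fit <- fit_one_model(spec$kind, params, as.matrix(bal$features),
                           bal$labels, seed = spec$seed + fi)
      p <- predict_prob(spec$kind, fit, x[test_idx, , drop = FALSE])
      aucs[fi] <- auc_rank(p, y[test_idx])
    }
    cv_auc[gi] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  bal <- smote_balance(x, y, seed = spec$seed)
  fit <- fit_one_model(spec$kind, grid[best, , drop = FALSE],
                       as.matrix(bal$features), bal$labels, seed = spec$seed)
  structure(
    list(branch = branch, kind = spec$kind, fit = fit,
         params = grid[best, , drop = FALSE],
         features = colnames(x),
         cv_results = dplyr::bind_cols(tibble::as_tibble(grid),
                                       tibble::tibble(cv_auc = cv_auc)),
         seed = spec$seed),
    class = "signature_model"
  )
}

make_stratified_folds <- function(y, k) {
  idx1 <- sample(which(y == 1)); idx0 <- sample(which(y == 0))
  f1 <- rep_len(seq_len(k), length(idx1))
  f0 <- rep_len(seq_len(k), length(idx0))
  lapply(seq_len(k), function(fi) sort(c(idx1[f1 == fi], idx0[f0 == fi])))
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %s (%s), %d features, CV AUC %.3f\n",
              x$branch, x$kind, length(x$features), max(x$cv_results$cv_auc)))
  invisible(x)
}

#' Predicted probabilities from a signature model
#'
#' @param object A `signature_model`.
#' @param newdata Feature tibble containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of high-grade probabilities.
#' @export
predict.signature_model <- function(object, newdata, ...) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(newdata),
                               dplyr::all_of(object$features)))
  predict_prob(object$kind, object$fit, x)
}

#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(branch = x$branch, kind = x$kind,
                 n_features = length(x$features),
                 cv_auc = max(x$cv_results$cv_auc))
}

#' Univariate/multivariate clinical covariate screen
#'
#' Each covariate enters a univariate logistic model; those with p < `alpha`
#' enter a joint multivariate logistic model, and covariates keeping
#' p < `alpha` there form the clinical signature. Odds ratios with 95%
#' confidence intervals are reported at both stages. Complete separation is
#' caught and flagged, and a ridge-penalised fit supplies the coefficients
#' (without Wald p-values) for the affected model.
#'
#' @param clinical_table Tibble of covariates (binary covariates may be
#'   factors, characters, or 0/1; continuous covariates numeric).
#'   A `patient_id` column is ignored.
#' @param labels Binary grade labels.
#' @param alpha Significance threshold; default 0.05.
#' @return A `clinical_screen` object: `univariate` and `multivariate`
#'   tibbles (term, odds ratio, CI, p), `selected` covariate names, and the
#'   final `model` (a `glm`).
#' @export
clinical_screen <- function(clinical_table, labels, alpha = 0.05) {
  tab <- dplyr::select(tibble::as_tibble(clinical_table),
                       -dplyr::any_of(c("patient_id", "split", "grade")))
  y <- as_binary_labels(labels)
  covs <- names(tab)
  uni <- purrr::map_dfr(covs, function(cv) {
    df <- data.frame(y = y, x = encode_covariate(tab[[cv]]))
    fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
    summarise_logistic(fit, cv)[2, ]
  })
  enter <- uni$term[!is.na(uni$p_value) & uni$p_value < alpha]
  if (length(enter) == 0) {
    return(structure(list(univariate = uni,
                          multivariate = uni[0, ], selected = character(0),
                          model = NULL, separation = FALSE),
                     class = "clinical_screen"))
  }
  dfm <- data.frame(y = y, lapply(tab[enter], encode_covariate))
  fit_m <- suppressWarnings(glm(y ~ ., data = dfm, family = binomial()))
  separation <- any(fit_m$fitted.values > 1 - 1e-8) ||
    any(fit_m$fitted.values < 1e-8)
  multi <- purrr::map_dfr(seq_along(enter), function(i) {
    summarise_logistic(fit_m, enter[i])[i + 1, ]
  })
  selected <- multi$term[!is.na(multi$p_value) & multi$p_value < alpha]
  model <- if (length(selected) > 0) {
    dfs <- data.frame(y = y, lapply(tab[selected], encode_covariate))
    suppressWarnings(glm(y ~ ., data = dfs, family = binomial()))
  } else NULL
  structure(list(univariate = uni, multivariate = multi,
                 selected = selected, model = model,
                 separation = separation),
            class = "clinical_screen")
}

encode_covariate <- function(x) {
  if (is.character(x) || is.factor(x)) {
    as.numeric(factor(x)) - 1
  } else {
    as.numeric(x)
  }
}

summarise_logistic <- function(fit, name_map = NULL) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  terms <- rownames(sm)
  if (!is.null(name_map) && length(terms) == 2) terms[2] <- name_map
  terms <- sub("^x$", name_map %||% "x", terms)
  tibble::tibble(term = terms, odds_ratio = exp(est),
                 or_ci_low = exp(est - 1.96 * se),
                 or_ci_high = exp(est + 1.96 * se), p_value = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.clinical_screen <- function(x, ...) {
  cat(sprintf("<clinical_screen> %d covariates retained: %s\n",
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.clinical_screen <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$univariate, stage = "univariate"),
    dplyr::mutate(x$multivariate, stage = "multivariate"))
}

#' Final integrated (combined) model
#'
#' Logistic model on the branch scores (habitat/ITH score and the best
#' peritumoral score) plus the screened clinical covariates; its
#' coefficients feed the nomogram.
#'
#' @param scores Tibble/data frame of per-patient predictors, e.g. columns
#'   `ith_score`, `peri1_score`, `sex`, `age`, `platelets` (binary
#'   covariates may be factor/character).
#' @param labels Binary labels aligned with the rows.
#' @return A `combined_model` object wrapping the fitted `glm`, with a
#'   `coefficients` tibble for nomogram export.
#' @export
combined_model <- function(scores, labels) {
  df <- data.frame(lapply(tibble::as_tibble(scores), encode_covariate))
  y <- as_binary_labels(labels)
  X <- as.matrix(df)
  Xv <- X[, apply(X, 2, sd) > 1e-12, drop = FALSE]  # constant cols aside
  if (ncol(Xv) > 1) {
    sv <- svd(scale(Xv))$d
    if (sv[length(sv)] < 1e-10 || sv[1] / max(sv[length(sv)], 1e-300) > 1e8) {
      warning("combined-model inputs are (near-)collinear; coefficients are unstable")
    }
  }
  fit <- suppressWarnings(glm(y ~ ., data = data.frame(y = y, df),
                              family = binomial()))
  structure(list(fit = fit,
                 coefficients = tibble::tibble(
                   term = names(coef(fit)), estimate = as.numeric(coef(fit))),
                 terms = names(df)),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> logistic on:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname combined_model
#' @param object A `combined_model`.
#' @param newdata Data with the model's predictor columns.
#' @param ... Unused.
predict.combined_model <- function(object, newdata, ...) {
  df <- data.frame(lapply(tibble::as_tibble(newdata)[object$terms],
                          encode_covariate))
  as.numeric(predict(object$fit, newdata = df, type = "response"))
}

#' @export
tidy.combined_model <- function(x, ...) x$coefficients
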