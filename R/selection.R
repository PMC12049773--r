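#' Selection cascade configuration
#'
#' @param icc_threshold Keep features with two-reader ICC strictly above
#'   this; default 0.8.
#' @param pearson_threshold Redundancy cut: a feature is dropped when its
#'   absolute Pearson correlation with an already-kept feature exceeds
#'   this; default 0.9.
#' @param mrmr_k mRMR budget; default 64.
#' @param lasso_cv_folds Cross-validation folds for the LASSO path;
#'   default 10.
#' @param seed Integer seed (fold assignment).
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_threshold = 0.8, pearson_threshold = 0.9,
                             mrmr_k = 64, lasso_cv_folds = 10, seed = 1) {
  stopifnot(icc_threshold > 0, icc_threshold < 1,
            pearson_threshold > 0, pearson_threshold < 1, mrmr_k >= 1)
  structure(list(icc_threshold = icc_threshold,
                 pearson_threshold = pearson_threshold,
                 mrmr_k = as.integer(mrmr_k),
                 lasso_cv_folds = as.integer(lasso_cv_folds),
                 seed = as.integer(seed)),
            class = "selection_config")
}

feature_matrix <- function(table) {
  tab <- dplyr::select(table, -dplyr::any_of("patient_id"))
  as.matrix(tab)
}

#' Two-way random absolute-agreement single-measure ICC
#'
#' ICC(2,1) from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param x An `n x k` matrix (subjects x raters).
#' @return The ICC estimate; `NA` if it is undefined (no variance at all).
#' @export
icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - mu)^2)
  ssc <- n * sum((col_m - mu)^2)
  sst <- sum((x - mu)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(den) || abs(den) < 1e-300) return(NA_real_)
  (msr - mse) / den
}

#' Reproducibility filter on two readers' feature tables
#'
#' Computes the per-feature ICC(2,1) between the two readers' extractions
#' and keeps features whose ICC strictly exceeds the threshold. Features
#' with zero variance in both readers have an undefined ICC and are
#' dropped (with a message).
#'
#' @param table_a,table_b Feature tibbles from the two readers; identical
#'   patients (rows, same order) and columns.
#' @param threshold ICC cut, default 0.8.
#' @return Character vector of retained feature names.
#' @export
icc_filter <- function(table_a, table_b, threshold = 0.8) {
  a <- feature_matrix(table_a); b <- feature_matrix(table_b)
  if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b))) {
    stop("the two readers' tables must share patients and columns")
  }
  icc <- vapply(seq_len(ncol(a)), function(j) icc21(cbind(a[, j], b[, j])), 0)
  undef <- is.na(icc)
  if (any(undef)) {
    message(sprintf("%d features with undefined ICC (no variance) dropped", sum(undef)))
  }
  colnames(a)[!undef & icc > threshold]
}

point_biserial <- function(x, y) {
  sx <- sd(x)
  if (!is.finite(sx) || sx < 1e-12) return(0)
  abs(suppressWarnings(cor(x, y)))
}

#' Greedy Pearson redundancy pruning
#'
#' Features are visited in order of decreasing absolute point-biserial
#' correlation with the (binary) label; a feature is dropped when its
#' absolute Pearson correlation with any already-kept feature exceeds the
#' threshold. Constant columns are dropped first. Deterministic.
#'
#' @param table Feature tibble.
#' @param labels Binary labels (0/1, logical, or a two-level factor).
#' @param threshold Correlation cut, default 0.9.
#' @return Character vector of retained feature names, in keep order.
#' @export
pearson_prune <- function(table, labels, threshold = 0.9) {
  x <- feature_matrix(table)
  y <- as_binary_labels(labels)
  if (nrow(x) < 3) stop("need at least 3 patients")
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    message(sprintf("%d constant features dropped before pruning", sum(sds < 1e-12)))
  }
  x <- x[, sds >= 1e-12, drop = FALSE]
  rel <- vapply(seq_len(ncol(x)), function(j) point_biserial(x[, j], y), 0)
  ord <- order(rel, decreasing = TRUE)
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0) {
      kept <- j
      next
    }
    r <- abs(suppressWarnings(cor(x[, j], x[, kept, drop = FALSE])))
    r[is.na(r)] <- 0
    if (max(r) <= threshold) kept <- c(kept, j)
  }
  colnames(x)[kept]
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    # "high" vs "low": treat the level "high" (or the second level) as 1
    pos <- if ("high" %in% levels(labels)) "high" else levels(labels)[2]
    return(as.numeric(labels == pos))
  }
  as.numeric(labels > 0)
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy mRMR with the difference criterion:
#' `score(f) = |r(f, label)| - mean over selected s of |r(f, s)|`,
#' where `r` is the Pearson (point-biserial for the label) correlation.
#' The first pick is the maximum-relevance feature; exactly `k` names are
#' returned in selection order (all candidates, with a warning, if fewer
#' than `k` enter).
#'
#' @param table Feature tibble.
#' @param labels Binary labels.
#' @param k Budget, default 64.
#' @return Character vector of selected names in selection order.
#' @export
mrmr_select <- function(table, labels, k = 64) {
  x <- feature_matrix(table)
  y <- as_binary_labels(labels)
  p <- ncol(x)
  if (p < k) {
    warning(sprintf("only %d candidate features for an mRMR budget of %d; returning all", p, k))
    k <- p
  }
  rel <- vapply(seq_len(p), function(j) point_biserial(x[, j], y), 0)
  selected <- integer(0)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) rel[remaining] else
      rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0) {
      r <- abs(suppressWarnings(cor(x[, remaining, drop = FALSE], x[, pick])))
      r[is.na(r)] <- 0
      red_sum[remaining] <- red_sum[remaining] + as.numeric(r)
    }
  }
  colnames(x)[selected]
}

#' LASSO radiomic signature
#'
#' Fits an L1-penalized logistic path on the z-scored candidate features
#' (standardisation statistics learned from the rows given, which should be
#' the training split only) and picks the penalty minimising the
#' cross-validated deviance. The signature keeps the features with nonzero
#' coefficients; the rad-score of a patient is the linear predictor
#' `intercept + sum(beta_i * z_i)`.
#'
#' @param table Training feature tibble (candidate features only).
#' @param labels Binary training labels.
#' @param config A `selection_config` (folds, seed).
#' @return A `habitat_signature` object with `selected_features`,
#'   `coefficients` (including `(intercept)`), scaling statistics, the CV
#'   curve (`cv` tibble: lambda, mean deviance), and `lambda`.
#' @export
lasso_signature <- function(table, labels, config = selection_config()) {
  x <- feature_matrix(table)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")

  fit <- with_seed(config$seed, {
    # class-stratified folds so no CV fold loses a whole class
    foldid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(config$lasso_cv_folds),
                                    length(idx)))
    }
    glmnet::cv.glmnet(z, y, family = "binomial", alpha = 1,
                      foldid = foldid, type.measure = "deviance",
                      standardize = FALSE)
  })
  beta <- as.numeric(coef(fit, s = "lambda.min"))
  names(beta) <- rownames(coef(fit, s = "lambda.min"))
  nz <- beta[-1][abs(beta[-1]) > 0]
  structure(
    list(selected_features = names(nz),
         coefficients = c("(intercept)" = beta[[1]], nz),
         center = center[names(nz)], scale = scale_[names(nz)],
         lambda = fit$lambda.min,
         cv = tibble::tibble(lambda = fit$lambda, deviance = fit$cvm,
                             deviance_se = fit$cvsd),
         n_train = length(y)),
    class = "habitat_signature"
  )
}

#' @export
print.habitat_signature <- function(x, ...) {
  cat(sprintf("<habitat_signature> %d features at lambda = %.4g (n = %d)\n",
              length(x$selected_features), x$lambda, x$n_train))
  invisible(x)
}

#' Rad-score prediction from a signature
#'
#' @param object A `habitat_signature`.
#' @param newdata Feature tibble containing the selected features.
#' @param ... Unused.
#' @return Numeric rad-score per row (linear predictor scale).
#' @export
predict.habitat_signature <- function(object, newdata, ...) {
  b0 <- object$coefficients[["(intercept)"]]
  if (length(object$selected_features) == 0) {
    return(rep(b0, nrow(newdata)))
  }
  x <- as.matrix(dplyr::select(newdata,
                               dplyr::all_of(object$selected_features)))
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.numeric(b0 + z %*% object$coefficients[object$selected_features])
}

#' @export
tidy.habitat_signature <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients))
}

#' @export
glance.habitat_signature <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected_features),
                 lambda = x$lambda, n_train = x$n_train,
                 cv_deviance = min(x$cv$deviance))
}

#' Run the full selection cascade on one branch
#'
#' ICC filter (optional; skipped for the habitat/ITH branch, whose
#' unsupervised subregions have no second-reader delineation), Pearson
#' redundancy pruning, mRMR to the budget, then the LASSO signature. All
#' statistics are learned from the rows passed in, which should be the
#' training split only.
#'
#' @param table Training feature tibble.
#' @param labels Training labels.
#' @param table_b Optional second-reader tibble for the ICC stage; `NULL`
#'   skips the ICC filter.
#' @param config A `selection_config`.
#' @return A `habitat_signature`; the intermediate kept-feature sets are
#'   attached as the `cascade` attribute.
#' @export
run_selection_cascade <- function(table, labels, table_b = NULL,
                                  config = selection_config()) {
  stages <- list()
  tab <- table
  if (!is.null(table_b)) {
    keep_icc <- icc_filter(tab, table_b, config$icc_threshold)
    stages$icc <- keep_icc
    tab <- dplyr::select(tab, dplyr::any_of(c("patient_id", keep_icc)))
  }
  keep_p <- pearson_prune(tab, labels, config$pearson_threshold)
  stages$pearson <- keep_p
  tab <- dplyr::select(tab, dplyr::any_of(c("patient_id", keep_p)))
  keep_m <- suppressWarnings(mrmr_select(tab, labels, config$mrmr_k))
  stages$mrmr <- keep_m
  tab <- dplyr::select(tab, dplyr::any_of(c("patient_id", keep_m)))
  sig <- lasso_signature(tab, labels, config)
  attr(sig, "cascade") <- stages
  sig
}
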