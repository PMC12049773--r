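# DeLong structural components: for each positive, the placement value
# against all negatives (and vice versa), with half weight on ties.
delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n, 0)
  v01 <- vapply(ys, function(yv) (sum(xs > yv) + 0.5 * sum(xs == yv)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC equals the Mann-Whitney two-sample statistic with half weight on
#' ties; its variance comes from the DeLong structural components, and the
#' 95% CI is the normal approximation `auc +/- 1.96 sd`, clipped to the unit interval.
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param labels Binary labels (1/`"high"` = positive).
#' @return List with `auc`, `variance`, `ci` (length-2 vector).
#' @examples
#' auc_delong(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
auc_delong <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  cp <- delong_components(scores, y)
  v <- var(cp$v10) / cp$m + var(cp$v01) / cp$n
  sdv <- sqrt(v)
  list(auc = cp$auc, variance = v,
       ci = pmin(pmax(c(cp$auc - 1.96 * sdv, cp$auc + 1.96 * sdv), 0), 1))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided z-test on the AUC difference of two score vectors evaluated on
#' the same samples, with the covariance of the paired structural
#' components. Identical score vectors give a zero difference and p = 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels shared by both.
#' @return List with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y)) {
    stop("predictions must be paired on identical samples")
  }
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (v <= 1e-300) {
    p <- if (abs(d) < 1e-12) 1 else 0
    return(list(p_value = p, auc_a = ca$auc, auc_b = cb$auc,
                z = if (abs(d) < 1e-12) 0 else sign(d) * Inf))
  }
  z <- d / sqrt(v)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = ca$auc, auc_b = cb$auc, z = z)
}

#' Youden-optimal threshold
#'
#' The score threshold maximising sensitivity + specificity - 1 on the
#' (training) data; predictions at or above the threshold are positive.
#'
#' @param scores,labels Training scores and labels.
#' @return The threshold (scalar).
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, 0)
  cand[which.max(j)]
}

#' Confusion-matrix metrics at a frozen threshold
#'
#' Accuracy, sensitivity, specificity, PPV and NPV at a threshold fitted on
#' the training split and frozen for validation/test. Undefined ratios
#' (0/0, e.g. the PPV of an all-negative prediction) are reported as 0 and
#' flagged in the `degenerate` field.
#'
#' @param scores,labels Scores and labels of the evaluated split.
#' @param threshold Decision threshold (scores `>=` threshold are called
#'   positive).
#' @return One-row tibble: accuracy, sensitivity, specificity, ppv, npv,
#'   tp/fp/fn/tn, degenerate flag.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  safe <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    accuracy = (tp + tn) / length(y),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn,
    degenerate = (tp + fp == 0) || (tn + fn == 0))
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups predictions into deciles of risk, compares observed and expected
#' event counts with the chi-square statistic on `groups - 2` degrees of
#' freedom. Empty bins (ties in the predicted risk) are merged with a
#' message.
#'
#' @param probabilities Predicted probabilities (between 0 and 1).
#' @param labels Binary outcomes.
#' @param groups Number of risk groups; default 10.
#' @return List with `statistic`, `p_value`, `df`, and the per-group table.
#' @export
hosmer_lemeshow <- function(probabilities, labels, groups = 10) {
  y <- as_binary_labels(labels)
  n <- length(y)
  if (n < groups) stop("need at least `groups` observations")
  br <- unique(quantile(probabilities, seq(0, 1, length.out = groups + 1)))
  if (length(br) == 1) br <- br + c(-1e-9, 1e-9)  # constant risk: one group
  if (length(br) - 1 < groups) {
    message(sprintf("tied risk deciles merged: %d groups used", length(br) - 1))
  }
  g <- cut(probabilities, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, g, sum)
  expd <- tapply(probabilities, g, sum)
  cnt <- tapply(y, g, length)
  keep <- !is.na(cnt) & cnt > 0
  obs <- obs[keep]; expd <- expd[keep]; cnt <- cnt[keep]
  stat <- sum((obs - expd)^2 / pmax(expd * (1 - expd / cnt), 1e-10))
  df <- max(length(obs) - 2, 1)
  list(statistic = stat, p_value = 1 - pchisq(stat, df), df = df,
       table = tibble::tibble(group = names(obs), n = as.numeric(cnt),
                              observed = as.numeric(obs),
                              expected = as.numeric(expd)))
}

#' Decision-curve net benefit
#'
#' Net benefit of treating by the model at threshold probability `pt`:
#' `NB(pt) = TP/N - (FP/N) pt / (1 - pt)`, alongside the treat-all curve
#' `pi - (1 - pi) pt / (1 - pt)` (prevalence `pi`) and the treat-none
#' reference 0.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcomes.
#' @param pt_grid Threshold probabilities; values >= 1 are excluded.
#' @return Tibble: `pt`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           pt_grid = seq(0.01, 0.99, by = 0.01)) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  y <- as_binary_labels(labels)
  pt_grid <- pt_grid[pt_grid < 1 & pt_grid >= 0]
  n <- length(y)
  prev <- mean(y)
  purrr::map_dfr(pt_grid, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    w <- pt / (1 - pt)
    tibble::tibble(pt = pt, net_benefit = tp / n - fp / n * w,
                   treat_all = prev - (1 - prev) * w, treat_none = 0)
  })
}

#' Calibration curve bins
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcomes.
#' @param bins Number of equal-width probability bins; default 10.
#' @return Tibble: bin midpoint, mean predicted, observed frequency, count.
#' @export
calibration_curve <- function(probabilities, labels, bins = 10) {
  y <- as_binary_labels(labels)
  if (length(y) < bins) stop("need at least `bins` observations")
  br <- seq(0, 1, length.out = bins + 1)
  g <- cut(pmin(pmax(probabilities, 0), 1), br, include.lowest = TRUE)
  tibble::tibble(
    bin_mid = (br[-1] + br[-length(br)]) / 2,
    mean_predicted = as.numeric(tapply(probabilities, g, mean)),
    observed = as.numeric(tapply(y, g, mean)),
    n = as.numeric(table(g))) |>
    dplyr::filter(.data$n > 0)
}

#' Cohort balance tests across splits or groups
#'
#' For each continuous variable, Shapiro-Wilk decides between the t-test
#' (normal in both groups) and the Mann-Whitney U-test; binary variables
#' use the chi-square test. Constant variables are skipped with a message.
#'
#' @param clinical_table Tibble of variables (a `patient_id` column is
#'   ignored).
#' @param group Two-level grouping vector (e.g. split or grade).
#' @return Tibble: variable, type, test, p_value.
#' @export
cohort_balance_check <- function(clinical_table, group) {
  tab <- dplyr::select(tibble::as_tibble(clinical_table),
                       -dplyr::any_of("patient_id"))
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("need exactly 2 groups")
  if (min(table(g)) < 2) stop("each group needs at least 2 rows")
  purrr::map_dfr(names(tab), function(v) {
    x <- tab[[v]]
    if (is.character(x) || is.factor(x) ||
        all(stats::na.omit(unique(as.numeric(x))) %in% 0:1)) {
      xt <- table(x, g)
      if (nrow(xt) < 2) {
        message(sprintf("variable %s is constant; skipped", v))
        return(tibble::tibble(variable = v, type = "binary",
                              test = "skipped", p_value = NA_real_))
      }
      p <- suppressWarnings(chisq.test(xt)$p.value)
      tibble::tibble(variable = v, type = "binary", test = "chi-square",
                     p_value = p)
    } else {
      x <- as.numeric(x)
      if (sd(x) < 1e-12) {
        message(sprintf("variable %s is constant; skipped", v))
        return(tibble::tibble(variable = v, type = "continuous",
                              test = "skipped", p_value = NA_real_))
      }
      normal <- all(vapply(levels(g), function(lv) {
        xs <- x[g == lv]
        if (length(xs) < 3 || sd(xs) < 1e-12) return(FALSE)
        shapiro.test(xs[seq_len(min(length(xs), 5000))])$p.value > 0.05
      }, TRUE))
      if (normal) {
        tibble::tibble(variable = v, type = "continuous", test = "t-test",
                       p_value = t.test(x ~ g)$p.value)
      } else {
        tibble::tibble(variable = v, type = "continuous",
                       test = "mann-whitney",
                       p_value = suppressWarnings(wilcox.test(x ~ g)$p.value))
      }
    }
  })
}

#' Nomogram export of a combined logistic model
#'
#' Converts a fitted logistic model into nomogram points: each covariate's
#' contribution `|beta| * range` is scaled so the largest spans 0-100
#' points, and the total-points axis maps back to predicted probability
#' through the logistic link. The round trip points -> probability
#' reproduces the model's own prediction.
#'
#' @param model A `combined_model` (or fitted binomial `glm`).
#' @param data The data used to define covariate ranges (defaults to the
#'   model frame).
#' @return A `nomogram` object: `points` tibble (term, beta, range,
#'   points_per_unit), `scale` (points per unit of linear predictor), and
#'   `risk_map()` function from a covariate row to probability and points.
#' @export
nomogram_export <- function(model, data = NULL) {
  fit <- if (inherits(model, "combined_model")) model$fit else model
  beta <- coef(fit)
  if (all(abs(beta[-1]) < 1e-12)) stop("model has no nonzero covariate coefficients")
  mf <- if (is.null(data)) fit$model else data
  terms <- names(beta)[-1]
  rng <- vapply(terms, function(t) diff(range(mf[[t]])), 0)
  span <- abs(beta[-1]) * rng
  scale_pts <- 100 / max(span)
  points <- tibble::tibble(
    term = terms, beta = as.numeric(beta[-1]), range = rng,
    points_per_unit = abs(beta[-1]) * scale_pts,
    max_points = span * scale_pts)
  base <- vapply(terms, function(t) min(mf[[t]] * sign(beta[[t]])), 0)
  risk_map <- function(row) {
    lp <- beta[1] + sum(beta[-1] * as.numeric(row[terms]))
    pts <- sum((as.numeric(row[terms]) * sign(beta[-1]) - base) *
                 abs(beta[-1]) * scale_pts)
    list(probability = as.numeric(stats::plogis(lp)), total_points = pts)
  }
  # inverse of the total-points axis: points -> linear predictor -> risk
  points_to_probability <- function(pts) {
    as.numeric(stats::plogis(pts / scale_pts + beta[1] +
                               sum(base * abs(beta[-1]))))
  }
  structure(list(points = points, scale = scale_pts, risk_map = risk_map,
                 points_to_probability = points_to_probability,
                 intercept = as.numeric(beta[1])),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat("<nomogram>\n"); print(x$points); invisible(x)
}

#' Full per-branch evaluation report
#'
#' Bundles the metrics reported for a signature on one split: AUC with
#' DeLong CI, threshold metrics at a frozen threshold, Hosmer-Lemeshow
#' calibration, calibration bins, and the decision curve.
#'
#' @param scores Predicted probabilities (or monotone scores; calibration
#'   and decision curves need probabilities).
#' @param labels Binary labels.
#' @param threshold Frozen decision threshold (from the training split).
#' @param branch,split Names carried into the output.
#' @return An `evaluation_report` list with `summary` (one-row tibble),
#'   `calibration`, `decision` tibbles, `hl` list.
#' @export
evaluate_scores <- function(scores, labels, threshold, branch = "model",
                            split = "validation") {
  a <- auc_delong(scores, labels)
  tm <- threshold_metrics(scores, labels, threshold)
  is_prob <- all(scores >= 0 & scores <= 1)
  hl <- if (is_prob) hosmer_lemeshow(scores, labels,
                                     groups = min(10, length(scores) %/% 2))
        else NULL
  cal <- if (is_prob) calibration_curve(scores, labels,
                                        bins = min(10, length(scores) %/% 2))
         else NULL
  dec <- if (is_prob) decision_curve(scores, labels) else NULL
  structure(
    list(summary = dplyr::bind_cols(
           tibble::tibble(branch = branch, split = split, auc = a$auc,
                          auc_ci_low = a$ci[1], auc_ci_high = a$ci[2],
                          hl_statistic = if (is.null(hl)) NA_real_ else hl$statistic,
                          hl_p = if (is.null(hl)) NA_real_ else hl$p_value),
           tm),
         calibration = cal, decision = dec, hl = hl,
         scores = scores, labels = as_binary_labels(labels)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$summary
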