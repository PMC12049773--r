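test_that("SMOTE equalises classes with synthetic rows on minority segments", {
  tab <- rand_table(127, 4, seed = 11)
  y <- c(rep(1, 27), rep(0, 100))
  bal <- smote_balance(tab, y, seed = 5)
  expect_equal(sum(bal$labels == 1), 100)
  expect_equal(sum(bal$labels == 0), 100)

  # already balanced input is returned unchanged
  bal0 <- smote_balance(tab[1:40, ], rep(c(0, 1), 20), seed = 5)
  expect_equal(nrow(bal0$features), 40L)

  # every synthetic row is a convex combination of two minority rows
  xm <- as.matrix(tab)[y == 1, ]
  synth <- as.matrix(bal$features)[-seq_len(127), , drop = FALSE]
  on_segment <- apply(synth, 1, function(srow) {
    for (i in seq_len(nrow(xm))) {
      d <- xm[i, ] - srow
      for (j in seq_len(nrow(xm))) {
        if (j == i) next
        seg <- xm[i, ] - xm[j, ]
        lam <- if (abs(seg[1]) > 1e-12) d[1] / seg[1] else 0
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            max(abs(d - lam * seg)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))

  expect_error(smote_balance(tab[1:11, ], c(1, rep(0, 10)), seed = 1),
               "fewer than 2")

  # a 2-sample minority has a single neighbour; balancing still works
  b2 <- smote_balance(tab[1:12, ], c(1, 1, rep(0, 10)), seed = 3)
  expect_equal(as.numeric(table(b2$labels)), c(10, 10))
})

test_that("signature models separate separable data and stay at chance on noise", {
  set.seed(21)
  x <- tibble::tibble(u = c(rnorm(30, -3), rnorm(30, 3)), v = rnorm(60))
  y <- rep(c(0, 1), each = 30)
  for (kind in c("logistic", "random_forest",
                 "gradient_boosting_xgb_style",
                 "gradient_boosting_lgbm_style")) {
    m <- train_signature(x, y, model_spec(kind, cv_folds = 3, seed = 2,
                                          grid = habitatct:::default_grid(kind)[1, , drop = FALSE]))
    p <- predict(m, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(auc_delong(p, y)$auc, 1.0, tolerance = 1e-6)
  }

  # permuted labels: CV AUC hovers around 0.5
  null_auc <- vapply(1:5, function(s) {
    tabn <- rand_table(80, 5, seed = 300 + s)
    yn <- withr::with_seed(s, sample(rep(c(0, 1), 40)))
    m <- train_signature(tabn, yn, model_spec("logistic", seed = s))
    max(m$cv_results$cv_auc)
  }, 0)
  expect_lt(abs(mean(null_auc) - 0.5), 0.15)

  # determinism: identical seeds choose identical hyperparameters
  tab <- rand_table(90, 6, seed = 13)
  yy <- planted_labels(tab, beta = c(2, -1))
  m1 <- train_signature(tab, yy, model_spec("random_forest", seed = 4))
  m2 <- train_signature(tab, yy, model_spec("random_forest", seed = 4))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$cv_results, m2$cv_results)
})

test_that("clinical screening recovers planted covariates at their power", {
  res <- lapply(1:8, function(s) {
    coh <- generate_cohort(cohort_config(450, seed = 400 + s), volumes = FALSE)
    scr <- clinical_screen(coh$table, coh$table$grade)
    scr$selected
  })
  rate <- function(v) mean(vapply(res, function(s) v %in% s, TRUE))
  expect_gte(rate("age"), 0.8)
  expect_gte(rate("platelets"), 0.8)
  # the sex effect (+0.5 log-odds) has ~50% power at this n; it must still
  # be recovered far more often than the no-effect nuisance covariates
  expect_gt(rate("sex"), max(rate("hematuria"), rate("tumor_side")))

  # null: false-positive retention per covariate stays near the 5% level
  null_sel <- unlist(lapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(
      300, clinical_effects = list(sex_log_odds = 0, age_shift = 0,
                                   platelet_shift = 0),
      seed = 600 + s), volumes = FALSE)
    clinical_screen(coh$table, coh$table$grade)$selected
  }))
  expect_lt(length(null_sel) / (20 * 5), 0.15)

  # single huge-effect covariate: OR > 1 with CI excluding 1
  set.seed(2)
  xx <- rnorm(300)
  yy <- rbinom(300, 1, stats::plogis(-1 + 2 * xx))
  scr1 <- clinical_screen(tibble::tibble(marker = xx), yy)
  row <- scr1$multivariate[scr1$multivariate$term == "marker", ]
  expect_gt(row$odds_ratio, 1)
  expect_gt(row$or_ci_low, 1)
})

test_that("the combined model integrates branch scores and clinical terms", {
  set.seed(31)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  ith <- y * 1.6 + rnorm(n)
  peri <- y * 1.1 + rnorm(n)
  age <- 55 + 6 * y + rnorm(n, sd = 10)
  df <- tibble::tibble(ith_score = ith, peri_score = peri, age = age)
  cm <- combined_model(df, y)
  p <- predict(cm, df)
  auc_comb <- auc_delong(p, y)$auc
  auc_single <- max(auc_delong(ith, y)$auc, auc_delong(peri, y)$auc,
                    auc_delong(age, y)$auc)
  expect_gte(auc_comb, auc_single - 0.02)

  # with useless clinical input the model reduces to the two scores
  df0 <- dplyr::mutate(df, age = rnorm(n))
  cm0 <- combined_model(df0, y)
  cm2 <- combined_model(df0[, 1:2], y)
  expect_equal(auc_delong(predict(cm0, df0), y)$auc,
               auc_delong(predict(cm2, df0), y)$auc, tolerance = 0.02)

  # intercept-only (constant) inputs give chance discrimination
  cmc <- suppressWarnings(combined_model(tibble::tibble(flat = rep(1, n)), y))
  expect_equal(auc_delong(predict(cmc, tibble::tibble(flat = rep(1, n))), y)$auc,
               0.5)

  expect_warning(combined_model(tibble::tibble(a = ith, b = ith), y),
                 "collinear")
  expect_s3_class(tidy(cm), "tbl_df")
})
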