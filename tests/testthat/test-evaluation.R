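test_that("DeLong AUC equals brute-force pair counting and cross-checks pROC", {
  expect_equal(auc_delong(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1.0)

  brute_auc <- function(s, y) {
    xs <- s[y == 1]; ys <- s[y == 0]
    tot <- 0
    for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(xs) * length(ys))
  }
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc_delong(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }

  # independent implementation: pROC's DeLong variance and AUC
  set.seed(7)
  y <- rbinom(80, 1, 0.4); s <- y + rnorm(80)
  got <- auc_delong(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE)
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(got$variance, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-8)

  # null behaviour: AUC within 3 sd of 0.5 at n = 2000
  set.seed(8)
  yn <- rbinom(2000, 1, 0.5); sn <- rnorm(2000)
  a <- auc_delong(sn, yn)
  expect_lt(abs(a$auc - 0.5), 3 * sqrt(a$variance))
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])

  expect_error(auc_delong(rnorm(5), rep(1, 5)), "both classes")
})

test_that("the paired DeLong test matches pROC and behaves at the edges", {
  set.seed(9)
  y <- rbinom(120, 1, 0.4)
  s1 <- y * 1.2 + rnorm(120)
  s2 <- rnorm(120)
  got <- delong_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-8)

  expect_equal(delong_test(s1, s1, y)$p_value, 1)
  expect_error(delong_test(s1, s2[1:50], y), "paired")

  # power: informative vs pure-noise scores rejected in >= 90% of seeds
  rejected <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    yy <- rbinom(500, 1, 0.3)
    delong_test(yy + rnorm(500, sd = 0.8), rnorm(500), yy)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rejected), 0.9)

  # bootstrap oracle on a small instance: z-test sd agrees with a paired
  # bootstrap of the AUC difference within Monte-Carlo error
  set.seed(11)
  yb <- rbinom(60, 1, 0.5)
  a1 <- yb + rnorm(60); a2 <- yb * 0.5 + rnorm(60)
  d_obs <- auc_delong(a1, yb)$auc - auc_delong(a2, yb)$auc
  boot_d <- vapply(1:400, function(b) {
    idx <- sample(60, replace = TRUE)
    if (length(unique(yb[idx])) < 2) return(NA_real_)
    auc_delong(a1[idx], yb[idx])$auc - auc_delong(a2[idx], yb[idx])$auc
  }, 0)
  sd_boot <- sd(boot_d, na.rm = TRUE)
  sd_delong <- abs(d_obs) / abs(qnorm(delong_test(a1, a2, yb)$p_value / 2))
  expect_gt(sd_delong / sd_boot, 0.6)
  expect_lt(sd_delong / sd_boot, 1.6)
})

test_that("threshold metrics reproduce hand confusion-matrix arithmetic", {
  # TP=3 FP=1 FN=2 TN=4 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.6, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$accuracy, 0.7)

  perfect <- threshold_metrics(labels, labels, 0.5)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))

  # degenerate all-negative call: sensitivity 0, specificity 1, flagged
  deg <- threshold_metrics(scores, labels, 2)
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 1)
  expect_equal(deg$ppv, 0)
  expect_true(deg$degenerate)

  # Youden threshold maximises J on its own data
  thr <- youden_threshold(scores, labels)
  j_at <- function(t) {
    mm <- threshold_metrics(scores, labels, t)
    mm$sensitivity + mm$specificity - 1
  }
  expect_equal(j_at(thr), max(vapply(unique(scores), j_at, 0)))
})

test_that("Hosmer-Lemeshow matches hand arithmetic and is calibrated under the null", {
  # two-group toy computed longhand
  p <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  hl <- hosmer_lemeshow(p, y, groups = 2)
  grp <- list(1:4, 5:8)
  stat <- sum(vapply(grp, function(g) {
    o <- sum(y[g]); e <- sum(p[g]); n <- length(g)
    (o - e)^2 / (e * (1 - e / n))
  }, 0))
  expect_equal(hl$statistic, stat, tolerance = 1e-10)
  expect_equal(hl$p_value, 1 - pchisq(stat, 1), tolerance = 1e-10)

  # probabilities equal to the prevalence: single merged group, zero statistic
  set.seed(3)
  yy <- rbinom(4000, 1, 0.3)
  hl0 <- suppressMessages(hosmer_lemeshow(rep(mean(yy), 4000), yy))
  expect_lt(hl0$statistic, 1e-12)

  # null uniformity of p-values for a correctly specified fitted model
  # (the canonical groups-2 degrees of freedom target this setting)
  pv <- vapply(1:120, function(s) {
    set.seed(7000 + s)
    x <- rnorm(400)
    yb <- rbinom(400, 1, stats::plogis(-0.3 + 0.8 * x))
    fit <- glm(yb ~ x, family = binomial())
    hosmer_lemeshow(fitted(fit), yb)$p_value
  }, 0)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)

  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), groups = 10),
               "at least")
})

test_that("net benefit follows its closed forms", {
  # hand toy: N=10, TP=3, FP=2 at pt=0.2 -> NB = 0.3 - 0.2*0.25 = 0.25
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1, 0.1, 0.1, 0.05, 0.01)
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  dc <- decision_curve(p, y, pt_grid = 0.2)
  expect_equal(dc$net_benefit, 0.3 - 0.2 * 0.2 / 0.8)
  expect_equal(dc$treat_none, 0)

  # treat-all curve crosses zero exactly at pt = prevalence
  prev <- mean(y)
  dc2 <- decision_curve(p, y, pt_grid = c(prev - 1e-9, prev, prev + 1e-3))
  expect_equal(dc2$treat_all[2], 0, tolerance = 1e-9)
  expect_gt(dc2$treat_all[1], 0)
  expect_lt(dc2$treat_all[3], 0)

  # perfect classifier: NB equals prevalence below every positive score
  dcp <- decision_curve(y, y, pt_grid = c(0.1, 0.5, 0.9))
  expect_equal(dcp$net_benefit, rep(prev, 3))

  expect_error(decision_curve(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("calibration bins recover the identity for calibrated predictions", {
  set.seed(5)
  pr <- runif(5000)
  yy <- rbinom(5000, 1, pr)
  cal <- calibration_curve(pr, yy)
  expect_equal(nrow(cal), 10L)
  expect_lt(max(abs(cal$observed - cal$mean_predicted)), 0.08)

  toy <- calibration_curve(c(0.05, 0.05, 0.95, 0.95), c(0, 1, 1, 1), bins = 2)
  expect_equal(toy$observed, c(0.5, 1))
  expect_equal(toy$n, c(2, 2))
})

test_that("cohort balance tests gate on normality and catch planted shifts", {
  coh <- generate_cohort(cohort_config(200, seed = 77), volumes = FALSE)
  tab <- dplyr::select(coh$table, -"patient_id", -"grade")
  bal <- cohort_balance_check(dplyr::select(tab, -"split"), tab$split)
  expect_true(all(c("age", "platelets", "sex") %in% bal$variable))
  expect_true(all(bal$p_value[bal$test != "skipped"] >= 0, na.rm = TRUE))
  # randomised split: no variable should be wildly imbalanced
  expect_gt(min(bal$p_value, na.rm = TRUE), 1e-4)

  # planted shift is detected
  g <- rep(c("a", "b"), each = 60)
  x <- tibble::tibble(shifted = c(rnorm(60), rnorm(60, 3)),
                      flat = rep(1, 120))
  expect_message(b2 <- cohort_balance_check(x, g), "constant")
  expect_lt(b2$p_value[b2$variable == "shifted"], 1e-6)

  expect_error(cohort_balance_check(x, rep(c("a", "b", "c"), 40)), "2 groups")
  expect_error(cohort_balance_check(x[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("nomogram points are affine in the model and round-trip exactly", {
  set.seed(6)
  x1 <- rnorm(150); x2 <- rnorm(150, sd = 3)
  y <- rbinom(150, 1, stats::plogis(-0.5 + 1.2 * x1 + 0.4 * x2))
  cm <- combined_model(tibble::tibble(x1 = x1, x2 = x2), y)
  nom <- nomogram_export(cm)
  expect_equal(max(nom$points$max_points), 100)

  # round trip: points -> probability equals the model's own prediction
  for (i in c(3, 50, 111)) {
    row <- list(x1 = x1[i], x2 = x2[i])
    rm_ <- nom$risk_map(row)
    expect_equal(nom$points_to_probability(rm_$total_points),
                 rm_$probability, tolerance = 1e-9)
    expect_equal(rm_$probability, predict(cm, tibble::as_tibble(row))[1],
                 tolerance = 1e-9)
  }

  # single-covariate model: points proportional to the covariate
  cm1 <- combined_model(tibble::tibble(x1 = x1), y)
  nom1 <- nomogram_export(cm1)
  pts <- vapply(c(-1, 0, 1, 2), function(v) {
    nom1$risk_map(list(x1 = v))$total_points
  }, 0)
  expect_equal(diff(pts, lag = 1), rep(pts[2] - pts[1], 3), tolerance = 1e-9)

  flat <- suppressWarnings(glm(y ~ 1, family = binomial()))
  expect_error(nomogram_export(flat), "nonzero")
})

test_that("evaluate_scores bundles the per-branch report", {
  set.seed(12)
  y <- rbinom(150, 1, 0.35)
  p <- stats::plogis(y * 1.5 + rnorm(150) - 0.5)
  rep_ <- evaluate_scores(p, y, threshold = 0.5, branch = "ith",
                          split = "validation")
  s <- rep_$summary
  expect_true(s$auc >= s$auc_ci_low && s$auc <= s$auc_ci_high)
  expect_true(all(unlist(s[c("sensitivity", "specificity", "ppv", "npv")]) >= 0))
  expect_true(all(unlist(s[c("sensitivity", "specificity", "ppv", "npv")]) <= 1))
  expect_s3_class(rep_$decision, "tbl_df")
  expect_s3_class(tidy(rep_), "tbl_df")
})
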