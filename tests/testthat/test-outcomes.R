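# build a patient table with exact outcome counts per group
patients_from_counts <- function(alive, expired, intv = NULL) {
  groups <- seq_along(alive)
  rows <- lapply(groups, function(g) {
    n <- alive[g] + expired[g]
    surv <- c(rep(1, alive[g]), rep(0, expired[g]))
    iv <- if (is.null(intv)) rep(0, n) else
      c(rep(1, intv[g]), rep(0, n - intv[g]))
    data.frame(endotype = g, survived = surv, intervention = iv,
               los = 5, age = 50, gcs = 12, male = 1)
  })
  do.call(rbind, rows)
}

test_that("outcome rates reproduce printed one-decimal percentages", {
  pats <- patients_from_counts(alive = c(52, 984), expired = c(135, 270))
  tab <- outcome_table(pats$endotype, pats)
  expect_equal(tab$survival_rate, c(27.8, 78.5))
  # a zero-member group is flagged with undefined rates
  f <- factor(pats$endotype, levels = c(1, 2, 3))
  tab3 <- outcome_table(f, pats)
  expect_true(tab3$empty[3])
  expect_true(is.na(tab3$survival_rate[3]))
  # half-up rounding convention
  expect_equal(round_half_up(c(27.85, 27.84, -1.25), 1), c(27.9, 27.8, -1.3))
  expect_equal(rate_pct(1665, 2629), 63.3)
})

test_that("Holm adjustment equals the brute-force step-down procedure", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(p.adjust(p, "holm"), bf_holm(p), tolerance = 1e-12)
  }
})

test_that("pairwise rate tests flag real differences and ignore identical groups", {
  pats <- patients_from_counts(alive = c(52, 984, 100, 100),
                               expired = c(135, 270, 50, 50))
  tab <- outcome_table(pats$endotype, pats)
  tests <- pairwise_chisq(tab, "survival")
  expect_equal(nrow(tests), 6)
  expect_true(all(tests$p_adj >= tests$p))
  hfa_he <- tests[tests$group_a == "1" & tests$group_b == "2", ]
  expect_lt(hfa_he$p_adj, 0.05)
  expect_true(hfa_he$significant)
  same <- tests[tests$group_a == "3" & tests$group_b == "4", ]
  expect_equal(same$p, 1)
  expect_false(same$significant)
  # tiny expected counts fall back to Fisher's exact test
  tiny <- outcome_table(rep(1:2, c(10, 2)),
                        patients_from_counts(alive = c(1, 1), expired = c(9, 1)))
  tt <- pairwise_chisq(tiny, "survival")
  expect_equal(tt$test, "fisher")
})

test_that("pairwise LOS tests are Welch with Holm adjustment", {
  set.seed(5)
  a <- rnorm(50, 10, 1); b <- rnorm(50, 5, 1)
  tests <- pairwise_los_tests(list(a = a, b = b, c = a))
  expect_lt(tests$p_adj[tests$group_a == "a" & tests$group_b == "b"], 0.001)
  # identical samples cannot differ
  expect_equal(pairwise_los_tests(list(x = a, y = a))$p, 1)
  # a single pair leaves Holm as the identity
  single <- pairwise_los_tests(list(a = a, b = b))
  expect_equal(single$p, single$p_adj)
  # degenerate constant groups
  z <- pairwise_los_tests(list(u = rep(3, 4), v = rep(3, 5)))
  expect_equal(z$p, 1)
  z2 <- pairwise_los_tests(list(u = rep(3, 4), v = rep(4, 5)))
  expect_equal(z2$p, 0)
})

test_that("covariate-adjusted logistic models behave under null and recovery", {
  set.seed(19)
  n <- 2000
  pats <- data.frame(age = runif(n, 20, 90), gcs = sample(3:15, n, TRUE),
                     male = rbinom(n, 1, 0.5), los = rexp(n, 0.1),
                     survived = rbinom(n, 1, 0.6))
  endo <- sample(c("a", "b", "c"), n, TRUE)
  m0 <- adjusted_binary_model(pats, endo, "survived", reference = "a")
  ors <- m0$coefficients[grepl("endotype", m0$coefficients$term), ]
  expect_true(all(ors$ci_lo < 1 & ors$ci_hi > 1))
  expect_equal(m0$reference, "a")
  # switching the reference leaves covariate terms unchanged
  m1 <- adjusted_binary_model(pats, endo, "survived", reference = "b")
  expect_equal(m0$coefficients$estimate[m0$coefficients$term == "age"],
               m1$coefficients$estimate[m1$coefficients$term == "age"],
               tolerance = 1e-8)
  # age log-odds recovery at large n
  set.seed(23)
  n <- 20000
  age <- runif(n, 20, 90)
  gcs <- sample(3:15, n, TRUE)
  male <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(1.2 - 0.01 * age + 0 * gcs))
  pats2 <- data.frame(age = age, gcs = gcs, male = male, survived = y,
                      los = 1)
  m2 <- adjusted_binary_model(pats2, sample(c("a", "b"), n, TRUE), "survived")
  or_age <- m2$coefficients$or[m2$coefficients$term == "age"]
  expect_gt(or_age, 0.985); expect_lt(or_age, 0.995)
})

test_that("perfect separation triggers the penalised fallback", {
  n <- 80
  pats <- data.frame(age = runif(n, 20, 90), gcs = sample(3:15, n, TRUE),
                     male = rbinom(n, 1, 0.5), los = 1, survived = 0)
  endo <- rep(c("a", "b"), each = n / 2)
  pats$survived[endo == "a"] <- 1
  m <- suppressWarnings(adjusted_binary_model(pats, endo, "survived"))
  expect_true(m$separated)
  expect_true(all(is.finite(m$coefficients$estimate)))
})

test_that("ANCOVA recovers a known adjusted group offset with Tukey comparisons", {
  set.seed(33)
  n <- 300
  age <- runif(n, 30, 80); gcs <- sample(3:15, n, TRUE)
  endo <- rep(c("x", "y"), each = n / 2)
  los <- 6 + 0.05 * age + 0.1 * gcs + 3 * (endo == "y") + rnorm(n, 0, 2)
  pats <- data.frame(los = los, age = age, gcs = gcs,
                     male = rbinom(n, 1, 0.5))
  res <- ancova_los(pats, endo)
  est <- res$tukey$estimate[res$tukey$contrast == "y - x"]
  se <- res$tukey$se[res$tukey$contrast == "y - x"]
  expect_lt(abs(est - 3), 2 * se)
  expect_true("endotype" %in% res$f_table$term)
  # a constant covariate is dropped with a warning
  pats2 <- pats; pats2$male <- 1
  expect_warning(ancova_los(pats2, endo), "constant")
  # collinear covariates are a named error
  pats3 <- pats; pats3$gcs <- pats3$age
  expect_error(ancova_los(pats3, endo), "collinear")
})

test_that("stratified rates and two-proportion tests work on binned strata", {
  set.seed(41)
  n <- 600
  pats <- data.frame(age = sample(c(25, 55, 80), n, TRUE),
                     gcs = sample(c(15, 11, 5), n, TRUE),
                     survived = rbinom(n, 1, 0.7),
                     intervention = 0, los = 1, male = 1)
  endo <- sample(c("HE", "AA"), n, TRUE)
  sr <- stratified_rates(pats, endo)
  expect_equal(sort(unique(sr$rates$age_bin)),
               sort(c("young", "middle-aged", "old")))
  filled <- sr$rates[sr$rates$n > 0, ]
  expect_equal(filled$survival_rate,
               rate_pct(filled$alive, filled$n))
  expect_true(all(sr$tests$p_adj >= sr$tests$p))
  # printed strata counts reproduce their published rates
  expect_equal(rate_pct(177, 188), 94.1)
  expect_equal(rate_pct(35, 50), 70.0)
  # an empty stratum is excluded from testing
  pats_small <- pats[pats$age == 25, ]
  sr2 <- stratified_rates(pats_small, endo[pats$age == 25])
  expect_true(all(sr2$tests$age_bin == "young"))
})

test_that("rank-based AUC equals the pairwise win fraction", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.1, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, TRUE)   # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_rank(scores, labels), bf_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(1:3, c(1, 1, 1))))
  # cross-check against an established ROC implementation
  set.seed(56)
  scores <- runif(100); labels <- rbinom(100, 1, 0.5)
  expect_equal(auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("model comparison ranks nested survival models sensibly", {
  co <- generate_cohort(default_endotype_scenario(seed = 61, n_patients = 800))
  z <- factor(co$truth$z)
  cmp <- model_comparison(co$patients, z, co$matrix)
  expect_equal(nrow(cmp$models), 10)
  expect_true(all(cmp$models$auc >= 0.5 - 1e-9))
  # covariates add real signal in this generator
  expect_gt(cmp$models$auc[cmp$models$model == "base_covariates"],
            cmp$models$auc[cmp$models$model == "sex_only"])
  expect_equal(nrow(cmp$f_tests), 3)
  expect_true(all(cmp$f_tests$df1 == 4))
})

test_that("adding a pure-noise regressor is rarely called significant", {
  set.seed(71)
  hits <- 0
  for (i in 1:100) {
    n <- 150
    y <- rbinom(n, 1, 0.5)
    x1 <- rnorm(n)
    noise <- rnorm(n)
    f <- anova(lm(y ~ x1), lm(y ~ x1 + noise))
    if (f$`Pr(>F)`[2] >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("comorbidity burden model reports the age-count correlation", {
  set.seed(81)
  n <- 10000
  pats <- data.frame(age = runif(n, 20, 90), gcs = sample(3:15, n, TRUE),
                     male = rbinom(n, 1, 0.5), los = 1,
                     survived = rbinom(n, 1, 0.6))
  count <- rpois(n, 2)
  m <- comorbidity_burden_model(pats, count)
  expect_lt(abs(m$age_count_correlation), 0.05)
  or_count <- m$coefficients$or[m$coefficients$term == "count"]
  expect_equal(or_count, 1, tolerance = 0.05)
  # a count that is an exact linear function of age has correlation one
  m2 <- comorbidity_burden_model(pats, 2 * pats$age + 1)
  expect_equal(m2$age_count_correlation, 1, tolerance = 1e-12)
})
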