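small_config <- function(n = 200, pi = c(0.5, 0.5), rho = NULL, seed = 1,
                         surv_int = NULL) {
  K <- length(pi)
  if (is.null(surv_int)) surv_int <- rep(0, K)
  if (is.null(rho)) rho <- matrix(rep(c(0.8, 0.1), each = 3)[1:(K * 3)], K, 3)
  generator_config(
    n_patients = n, n_classes = K, mixing_weights = pi, item_probs = rho,
    covariate_params = list(age_mean = rep(60, K), age_sd = rep(15, K),
                            p_male = rep(0.6, K),
                            gcs_probs = matrix(1 / 3, K, 3)),
    outcome_params = list(
      survival = list(intercept = surv_int, age = 0, gcs = 0, male = 0),
      intervention = list(intercept = rep(-1, K), age = 0, gcs = 0, male = 0),
      los = list(meanlog = rep(2, K), sdlog = rep(0.5, K))),
    seed = seed)
}

test_that("degenerate Bernoulli(0) items give an all-zero matrix", {
  cfg <- small_config(n = 50, pi = 1, rho = matrix(0, 1, 4))
  co <- generate_cohort(cfg)
  expect_true(all(co$matrix == 0))
  expect_equal(dim(co$matrix), c(50, 4))
})

test_that("class counts respect the binomial sampling bound", {
  cfg <- small_config(n = 1000, seed = 7)
  co <- generate_cohort(cfg)
  n1 <- sum(co$truth$z == 1)
  expect_lt(abs(n1 - 500), 4 * sqrt(250))
})

test_that("saturated survival intercepts give per-class rates 1 and 0", {
  cfg <- small_config(n = 400, surv_int = c(20, -20), seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(mean(co$patients$survived[co$truth$z == 1]), 1)
  expect_equal(mean(co$patients$survived[co$truth$z == 2]), 0)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_cohort(small_config(seed = 11))
  b <- generate_cohort(small_config(seed = 11))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$patients, b$patients)
  d <- generate_cohort(small_config(seed = 12))
  expect_false(identical(a$matrix, d$matrix))
})

test_that("generated covariates respect their declared ranges", {
  co <- generate_cohort(default_endotype_scenario(seed = 5, n_patients = 500))
  p <- co$patients
  expect_true(all(p$age >= 16 & p$age <= 100))
  expect_true(all(p$gcs >= 3 & p$gcs <= 15))
  expect_true(all(p$los >= 0))
  expect_true(all(p$los * 10 == round(p$los * 10)))  # 0.1-day rounding
})

test_that("the five-endotype scenario has the documented structure", {
  cfg <- default_endotype_scenario(seed = 1)
  expect_equal(sum(cfg$mixing_weights), 1, tolerance = 1e-12)
  expect_equal(cfg$n_classes, 5L)
  expect_equal(cfg$n_items, 30L)
  # one near-zero healthy class
  expect_true(any(apply(cfg$item_probs, 1, max) <= 0.1))
  # class sizes echo the published group sizes
  expect_equal(cfg$mixing_weights,
               c(187, 1254, 136, 177, 875) / 2629, tolerance = 1e-12)
  # the seed drives sampling only, not the scenario parameters
  cfg2 <- default_endotype_scenario(seed = 999)
  expect_identical(cfg$item_probs, cfg2$item_probs)
  expect_identical(cfg$mixing_weights, cfg2$mixing_weights)
})

test_that("within-class item prevalence converges to the generating probabilities", {
  rho <- matrix(c(0.7, 0.3, 0.05, 0.1, 0.6, 0.9), 2, 3)
  cfg <- small_config(n = 10000, rho = rho, seed = 21)
  co <- generate_cohort(cfg)
  for (k in 1:2) {
    emp <- colMeans(co$matrix[co$truth$z == k, , drop = FALSE])
    expect_lt(max(abs(emp - rho[k, ])), 0.03)
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(small_config(pi = c(0.6, 0.6)), "mixing_weights")
  cfg_bad <- function(rho) small_config(rho = rho)
  expect_error(cfg_bad(matrix(1.2, 2, 3)), "item_probs")
  expect_error(generator_config(
    10, 2, c(0.5, 0.5), matrix(0.5, 2, 3),
    covariate_params = list(age_mean = c(60, 60), age_sd = c(15, 15),
                            p_male = c(0.5, 0.5),
                            gcs_probs = matrix(c(0.5, 0.5, 0.5, 0.5, 0.1, 0.1),
                                               2, 3)),
    outcome_params = list(survival = list(intercept = c(0, 0)),
                          intervention = list(intercept = c(0, 0)),
                          los = list(meanlog = c(2, 2), sdlog = 0.5)),
    seed = 1), "gcs_probs")
})

test_that("emitted ICD-9 codes round-trip through the mapping exactly", {
  mapping <- elixhauser_map(combine_hypertension = TRUE)
  co <- generate_cohort(default_endotype_scenario(seed = 31, n_patients = 200))
  co <- emit_icd9_codes(co, mapping, seed = 8)
  back <- comorbidity_matrix(co$patients, mapping)
  expect_equal(unname(back * 1), unname(co$matrix * 1), ignore_attr = TRUE)
  # deterministic for a fixed seed
  co2 <- emit_icd9_codes(co, mapping, seed = 8)
  expect_identical(co$patients$icd9, co2$patients$icd9)
})

test_that("a patient with no active categories gets no comorbidity codes", {
  cfg <- small_config(n = 20, pi = 1, rho = matrix(0, 1, 30))
  co <- generate_cohort(cfg)
  colnames(co$matrix) <- names(elixhauser_map(combine_hypertension = TRUE))
  co <- emit_icd9_codes(co, seed = 1, add_tbi_code = FALSE)
  expect_true(all(co$patients$icd9 == ""))
})

test_that("cohort files are written as delimited text with truth sidecars", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_config(n = 30, seed = 2))
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  again <- read.csv(paths["matrix"], check.names = FALSE)
  expect_equal(nrow(again), 30)
  expect_equal(again$patient_id, co$patients$patient_id)
})
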