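#' Build and validate a synthetic cohort generator configuration
#'
#' The generator draws a latent class per patient, binary comorbidity
#' indicators from class-specific Bernoulli probabilities, and class-dependent
#' covariates and outcomes: truncated-normal age, hierarchical GCS (severity
#' band, then a uniform integer within the band), Bernoulli survival and
#' neurosurgical-intervention flags through a logistic linear predictor, and
#' lognormal length of stay.
#'
#' @param n_patients cohort size.
#' @param n_classes number of latent classes `K`.
#' @param mixing_weights length-`K` probability vector over classes.
#' @param item_probs `K x J` matrix of per-class item (comorbidity)
#'   probabilities in `[0, 1]`; column names become indicator names.
#' @param covariate_params list with per-class vectors `age_mean`, `age_sd`
#'   (years), `p_male`, and a `K x 3` matrix `gcs_probs` with columns
#'   mild/moderate/severe summing to 1 per row.
#' @param outcome_params list with components `survival` and `intervention`
#'   (each a list `intercept` (length `K`), `age`, `gcs`, `male` on the
#'   log-odds scale) and `los` (`meanlog` length `K`, `sdlog`).
#' @param seed integer seed making the cohort reproducible.
#' @param emit_icd9 whether [emit_icd9_codes()] should be applied downstream.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients, n_classes, mixing_weights, item_probs,
                             covariate_params, outcome_params, seed,
                             emit_icd9 = FALSE) {
  stopifnot(n_patients >= 1, n_classes >= 1)
  item_probs <- as.matrix(item_probs)
  if (nrow(item_probs) != n_classes)
    stop("configuration error in `item_probs`: need one row per class")
  if (any(item_probs < 0 | item_probs > 1))
    stop("configuration error in `item_probs`: entries must lie in [0, 1]")
  if (length(mixing_weights) != n_classes)
    stop("configuration error in `mixing_weights`: need one weight per class")
  if (any(mixing_weights < 0) || abs(sum(mixing_weights) - 1) > 1e-12)
    stop("configuration error in `mixing_weights`: must be a probability vector summing to 1")
  gp <- as.matrix(covariate_params$gcs_probs)
  if (nrow(gp) != n_classes || ncol(gp) != 3 ||
      any(abs(rowSums(gp) - 1) > 1e-12) || any(gp < 0))
    stop("configuration error in `covariate_params$gcs_probs`: need K x 3 row-stochastic matrix")
  if (any(covariate_params$p_male < 0 | covariate_params$p_male > 1))
    stop("configuration error in `covariate_params$p_male`: probabilities required")
  for (nm in c("survival", "intervention"))
    if (length(outcome_params[[nm]]$intercept) != n_classes)
      stop(sprintf("configuration error in `outcome_params$%s`: need one intercept per class", nm))
  structure(list(
    n_patients = as.integer(n_patients), n_items = ncol(item_probs),
    n_classes = as.integer(n_classes),
    mixing_weights = as.numeric(mixing_weights), item_probs = item_probs,
    covariate_params = covariate_params, outcome_params = outcome_params,
    seed = as.integer(seed), emit_icd9 = isTRUE(emit_icd9)
  ), class = "generator_config")
}

#' Five-endotype synthetic scenario
#'
#' A fixed 5-class, 30-item configuration with well-separated class profiles:
#' a cardiac class (heart failure + arrhythmia), a near-zero "healthy" class,
#' a renal-failure-with-hypertension class, an alcohol-abuse class and a
#' hypertension class. Class sizes, per-class age and GCS-severity
#' distributions, and class-level survival / intervention / length-of-stay
#' levels follow the published endotype summary tables; the item-probability
#' values themselves are package conventions. The seed only drives sampling:
#' two configurations from different seeds share identical parameters.
#'
#' @param seed integer seed stored in the configuration.
#' @param n_patients cohort size (default 2629).
#' @return a [generator_config()].
#' @export
default_endotype_scenario <- function(seed, n_patients = 2629) {
  classes <- c("hfa", "healthy", "rfh", "aa", "htn")
  items <- names(elixhauser_map(combine_hypertension = TRUE))
  K <- 5L; J <- length(items)
  stopifnot(J == 30L)
  # Anchor items define one class each; they are kept rare in every other
  # class so each endotype has a crisp multi-item signature (well-separated
  # profiles; see the methods vignette for the design rationale).
  anchors <- c("chf", "arrhythmia", "renal_failure", "dm_comp", "alcohol", "drug")
  rho <- matrix(0.04, K, J, dimnames = list(classes, items))
  rho[, anchors] <- 0.005
  rho["healthy", ] <- 0.02
  rho["healthy", "htn"] <- 0.01
  rho["healthy", anchors] <- 0.002
  rho["htn", ] <- 0.05
  rho["htn", anchors] <- 0.002
  rho["hfa", c("chf", "arrhythmia", "valvular", "fluid_electrolyte")] <-
    c(0.96, 0.96, 0.06, 0.06)
  rho["rfh", c("renal_failure", "htn", "dm_comp", "fluid_electrolyte")] <-
    c(0.96, 0.95, 0.95, 0.06)
  rho["aa", c("alcohol", "drug", "liver", "depression")] <-
    c(0.96, 0.95, 0.06, 0.06)
  rho["htn", c("htn", "dm_uncomp", "chronic_pulm", "obesity", "def_anemia")] <-
    c(0.95, 0.35, 0.25, 0.15, 0.15)
  w <- c(187, 1254, 136, 177, 875)
  pi <- w / sum(w)
  covariate_params <- list(
    age_mean = c(80, 44, 79, 55, 74),
    age_sd   = c(10, 20, 11, 15, 15),
    p_male   = rep(0.62, K),
    gcs_probs = matrix(c(0.500, 0.196, 0.304,
                         0.369, 0.162, 0.469,
                         0.538, 0.174, 0.288,
                         0.406, 0.200, 0.394,
                         0.516, 0.171, 0.313),
                       K, 3, byrow = TRUE,
                       dimnames = list(classes, c("mild", "moderate", "severe")))
  )
  # class-mean covariates; band means are midpoints of 14-15 / 9-13 / 3-8
  age_bar <- covariate_params$age_mean
  gcs_bar <- as.numeric(covariate_params$gcs_probs %*% c(14.5, 11, 5.5))
  surv_target <- c(0.278, 0.785, 0.404, 0.701, 0.514)
  intv_target <- c(0.273, 0.215, 0.132, 0.232, 0.257)
  b_surv <- list(age = -0.04, gcs = 0.15, male = 0)
  b_intv <- list(age = 0, gcs = -0.02, male = 0)
  los_mean <- c(10.2, 7.3, 8.7, 10.6, 7.7); los_sdlog <- 0.70
  outcome_params <- list(
    survival = list(
      intercept = qlogis(surv_target) - b_surv$age * age_bar - b_surv$gcs * gcs_bar,
      age = b_surv$age, gcs = b_surv$gcs, male = b_surv$male),
    intervention = list(
      intercept = qlogis(intv_target) - b_intv$gcs * gcs_bar,
      age = b_intv$age, gcs = b_intv$gcs, male = b_intv$male),
    los = list(meanlog = log(los_mean) - los_sdlog^2 / 2,
               sdlog = rep(los_sdlog, K))
  )
  generator_config(n_patients, K, pi, rho, covariate_params, outcome_params,
                   seed = seed, emit_icd9 = TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws latent labels, the binary comorbidity matrix and class-dependent
#' covariates/outcomes from a [generator_config()]. Deterministic for a fixed
#' configuration seed.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: list with `patients` (data
#'   frame), `matrix` (binary comorbidity matrix) and `truth` (configuration
#'   echo plus latent labels `z`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients; K <- config$n_classes; J <- config$n_items
  cp <- config$covariate_params; op <- config$outcome_params
  z <- sample.int(K, n, replace = TRUE, prob = config$mixing_weights)
  x <- matrix(rbinom(n * J, 1, config$item_probs[z, , drop = FALSE]), n, J)
  colnames(x) <- colnames(config$item_probs)
  ids <- sprintf("P%05d", seq_len(n))
  rownames(x) <- ids
  # age: truncated normal on [16, 100] via inverse-CDF sampling
  lo <- pnorm(16, cp$age_mean[z], cp$age_sd[z])
  hi <- pnorm(100, cp$age_mean[z], cp$age_sd[z])
  age <- qnorm(lo + runif(n) * (hi - lo), cp$age_mean[z], cp$age_sd[z])
  age <- pmin(pmax(round(age), 16), 100)
  male <- rbinom(n, 1, cp$p_male[z])
  band <- vapply(seq_len(n), function(i)
    sample.int(3L, 1L, prob = cp$gcs_probs[z[i], ]), integer(1))
  gcs_lo <- c(14L, 9L, 3L)[band]; gcs_hi <- c(15L, 13L, 8L)[band]
  gcs <- gcs_lo + floor(runif(n) * (gcs_hi - gcs_lo + 1L))
  lp_surv <- op$survival$intercept[z] + op$survival$age * age +
    op$survival$gcs * gcs + op$survival$male * male
  survived <- rbinom(n, 1, plogis(lp_surv))
  lp_intv <- op$intervention$intercept[z] + op$intervention$age * age +
    op$intervention$gcs * gcs + op$intervention$male * male
  intervention <- rbinom(n, 1, plogis(lp_intv))
  sdlog <- rep_len(op$los$sdlog, K)
  los <- round(rlnorm(n, op$los$meanlog[z], sdlog[z]), 1)
  patients <- data.frame(
    patient_id = ids,
    admission_id = sprintf("A%05d", seq_len(n)),
    admit_date = as.Date("2001-01-01") + (seq_len(n) - 1L) %% 3650L,
    age = age, male = male, gcs = gcs, survived = survived,
    intervention = intervention, los = los, icd9 = "",
    stringsAsFactors = FALSE
  )
  truth <- list(config = config, z = z,
                class_sizes = tabulate(z, nbins = K))
  structure(list(patients = patients, matrix = x, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d comorbidity indicators, %d latent classes\n",
              nrow(x$patients), ncol(x$matrix), x$truth$config$n_classes))
  cat("Class sizes:", paste(x$truth$class_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Emit ICD-9 diagnosis codes consistent with the comorbidity matrix
#'
#' For every active comorbidity category of each patient, samples one or two
#' ICD-9 codes that map back to that category and to no other, so the round
#' trip through [map_codes()] reproduces the matrix exactly. Optionally
#' prepends a TBI index code so the emitted table passes [filter_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param mapping an [elixhauser_map()] whose categories match the matrix
#'   columns.
#' @param seed integer seed for the code sampling.
#' @param add_tbi_code prepend one TBI diagnosis code per patient.
#' @return the cohort with the `icd9` column of `patients` filled in.
#' @export
emit_icd9_codes <- function(cohort, mapping = elixhauser_map(combine_hypertension = TRUE),
                            seed = 1L, add_tbi_code = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  x <- cohort$matrix
  if (!identical(colnames(x), names(mapping)))
    stop("matrix columns do not match the mapping categories")
  # codes usable for emission: prefixes that map to exactly their own category
  pools <- lapply(seq_along(mapping), function(j) {
    pref <- mapping[[j]]
    keep <- vapply(pref, function(p) {
      fl <- map_codes(p, mapping)
      sum(fl) == 1L && fl[j] == 1L
    }, logical(1))
    pref[keep]
  })
  names(pools) <- names(mapping)
  empty <- lengths(pools) == 0L
  if (any(empty))
    stop("configuration error: no unambiguous codes available for ",
         paste(names(pools)[empty], collapse = ", "))
  tbi_pool <- c("80100", "80300", "85220", "85400", "9501")
  set.seed(seed)
  icd9 <- vapply(seq_len(nrow(x)), function(i) {
    active <- which(x[i, ] == 1)
    codes <- unlist(lapply(active, function(j) {
      pool <- pools[[j]]
      n_cd <- if (length(pool) > 1L) sample(1:2, 1L) else 1L
      pool[sample.int(length(pool), n_cd, replace = FALSE)]
    }), use.names = FALSE)
    if (add_tbi_code)
      codes <- c(tbi_pool[sample.int(length(tbi_pool), 1L)], codes)
    paste(codes, collapse = ";")
  }, character(1))
  cohort$patients$icd9 <- icd9
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Writes the patient table and comorbidity matrix as comma-separated text
#' (header row, patient id first), the generating truth as JSON and the
#' configuration as YAML.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return (invisibly) named vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             matrix = file.path(dir, "comorbidity_matrix.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  write.csv(data.frame(patient_id = rownames(cohort$matrix), cohort$matrix,
                       check.names = FALSE),
            paths["matrix"], row.names = FALSE)
  cfg <- cohort$truth$config
  jsonlite::write_json(list(z = cohort$truth$z,
                            class_sizes = cohort$truth$class_sizes,
                            mixing_weights = cfg$mixing_weights,
                            item_probs = cfg$item_probs,
                            seed = cfg$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(n_patients = cfg$n_patients, n_classes = cfg$n_classes,
                        n_items = cfg$n_items, seed = cfg$seed),
                   paths["config"])
  invisible(paths)
}
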