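#' Outcome summary table by endotype
#'
#' Counts survival and neurosurgical-intervention outcomes and summarises
#' length of stay per endotype. Rates are percentages rounded half-up to one
#' decimal, the convention of printed clinical tables. An endotype with zero
#' members gets `NA` rates and is flagged.
#'
#' @param assignments endotype label per patient (integer or factor).
#' @param patients patient table with `survived`, `intervention` and `los`
#'   columns aligned row-for-row with `assignments`.
#' @return data frame of class `outcome_table` with counts, rates and LOS
#'   mean/SD per endotype, plus an `empty` flag column.
#' @export
outcome_table <- function(assignments, patients) {
  stopifnot(length(assignments) == nrow(patients))
  groups <- if (is.factor(assignments)) levels(assignments)
            else sort(unique(assignments))
  rows <- lapply(groups, function(g) {
    sel <- assignments == g
    n <- sum(sel)
    alive <- sum(patients$survived[sel] == 1)
    intv <- sum(patients$intervention[sel] == 1)
    data.frame(endotype = as.character(g), n = n,
               alive = alive, expired = n - alive,
               survival_rate = rate_pct(alive, n),
               intervention = intv, no_intervention = n - intv,
               intervention_rate = rate_pct(intv, n),
               los_mean = if (n) mean(patients$los[sel]) else NA_real_,
               los_sd = if (n > 1) sd(patients$los[sel]) else NA_real_,
               empty = n == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_table", "data.frame")
  out
}

# All unordered group pairs as a two-column matrix of indices
pair_grid <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

holm_set <- function(df, alpha) {
  df$p_adj <- p.adjust(df$p, method = "holm")
  df$significant <- df$p_adj < alpha
  class(df) <- c("pairwise_tests", "data.frame")
  df
}

#' Pairwise rate comparisons between endotypes
#'
#' Tests every unordered endotype pair on its 2x2 outcome counts with a
#' Yates-corrected chi-squared test, falling back to Fisher's exact test for
#' a pair when any expected cell count drops below 1. P-values are
#' Holm-adjusted across the pair family.
#'
#' @param table an [outcome_table()].
#' @param outcome `"survival"` or `"intervention"`.
#' @param alpha family-wise significance level applied to adjusted p-values.
#' @return data frame of class `pairwise_tests` with one row per pair:
#'   statistic, test used, raw and adjusted p, significance flag.
#' @export
pairwise_chisq <- function(table, outcome = c("survival", "intervention"),
                           alpha = 0.05) {
  outcome <- match.arg(outcome)
  stopifnot(nrow(table) >= 2)
  yes <- if (outcome == "survival") table$alive else table$intervention
  no <- if (outcome == "survival") table$expired else table$no_intervention
  idx <- pair_grid(nrow(table))
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    a <- idx[r, 1]; b <- idx[r, 2]
    m <- matrix(c(yes[a], no[a], yes[b], no[b]), 2, 2, byrow = TRUE)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expd < 1)) {
      ft <- fisher.test(m)
      stat <- NA_real_; p <- ft$p.value; test <- "fisher"
    } else if (identical(m[1, ], m[2, ])) {
      # identical counts: no evidence of difference by construction
      stat <- 0; p <- 1; test <- "chisq"
    } else {
      ct <- suppressWarnings(chisq.test(m, correct = TRUE))
      stat <- unname(ct$statistic); p <- ct$p.value; test <- "chisq"
    }
    data.frame(group_a = table$endotype[a], group_b = table$endotype[b],
               statistic = stat, test = test, p = p,
               stringsAsFactors = FALSE)
  })
  holm_set(do.call(rbind, rows), alpha)
}

#' Pairwise Welch t-tests for length of stay
#'
#' @param los_by_group named list of numeric LOS vectors, one per endotype
#'   (each of length at least 2).
#' @param alpha family-wise significance level.
#' @return data frame of class `pairwise_tests`, Holm-adjusted. A pair where
#'   both groups are constant gets `p = 1` when the means are equal and
#'   `p = 0` otherwise.
#' @export
pairwise_los_tests <- function(los_by_group, alpha = 0.05) {
  stopifnot(length(los_by_group) >= 2, all(lengths(los_by_group) >= 2))
  nms <- names(los_by_group) %||% as.character(seq_along(los_by_group))
  idx <- pair_grid(length(los_by_group))
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    a <- los_by_group[[idx[r, 1]]]; b <- los_by_group[[idx[r, 2]]]
    if (sd(a) == 0 && sd(b) == 0) {
      stat <- NA_real_
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- t.test(a, b)        # Welch by default
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(group_a = nms[idx[r, 1]], group_b = nms[idx[r, 2]],
               statistic = stat, test = "welch", p = p,
               stringsAsFactors = FALSE)
  })
  holm_set(do.call(rbind, rows), alpha)
}

#' @export
print.pairwise_tests <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# ridge-penalised logistic fit used as the separation fallback
ridge_logit <- function(X, y, lambda = 1e-4) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(beta[-1]^2) / 2
  }
  gr <- function(beta) {
    mu <- plogis(drop(X %*% beta))
    g <- drop(crossprod(X, mu - y))
    g[-1] <- g[-1] + lambda * beta[-1]
    g
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000))
  mu <- plogis(drop(X %*% opt$par))
  W <- mu * (1 - mu)
  H <- crossprod(X * W, X) + diag(c(0, rep(lambda, ncol(X) - 1)))
  list(coef = setNames(opt$par, colnames(X)), vcov = solve(H))
}

#' Covariate-adjusted logistic model of a binary outcome across endotypes
#'
#' Maximum-likelihood logit fit of the outcome on endotype indicators plus
#' age, GCS score and male sex, with Wald 95% intervals on the odds-ratio
#' scale. Rows with missing covariates are dropped (count recorded). If the
#' fit shows signs of perfect separation the model is refit with a small
#' ridge penalty (strength `1e-4`) and flagged.
#'
#' @param patients patient table with `age`, `gcs`, `male` and the outcome
#'   column.
#' @param assignments endotype per patient.
#' @param outcome name of the binary outcome column (e.g. `"survived"`).
#' @param reference endotype level used as the reference class.
#' @return object of class `adjusted_model`: coefficient table (`term`,
#'   `estimate`, `or`, `ci_lo`, `ci_hi`, `p`), reference level, fit metadata
#'   (deviance, McFadden pseudo-R2, linear-probability R2, AUC, rows dropped,
#'   separation flag).
#' @export
adjusted_binary_model <- function(patients, assignments, outcome = "survived",
                                  reference = NULL) {
  stopifnot(outcome %in% names(patients))
  endo <- factor(assignments)
  if (!is.null(reference)) endo <- stats::relevel(endo, ref = as.character(reference))
  dat <- data.frame(y = patients[[outcome]], endotype = endo,
                    age = patients$age, gcs = patients$gcs,
                    male = patients$male)
  cc <- complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (!all(dat$y %in% 0:1)) stop("outcome must be binary 0/1")
  fit <- glm(y ~ endotype + age + gcs + male, binomial(), data = dat)
  separated <- !fit$converged || any(abs(coef(fit)) > 15)
  if (separated) {
    X <- model.matrix(~ endotype + age + gcs + male, dat)
    rf <- ridge_logit(X, dat$y)
    est <- rf$coef; se <- sqrt(diag(rf$vcov))
  } else {
    est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  keep <- names(est) != "(Intercept)"
  tab <- data.frame(term = names(est)[keep], estimate = est[keep],
                    or = exp(est[keep]),
                    ci_lo = exp(est[keep] - 1.96 * se[keep]),
                    ci_hi = exp(est[keep] + 1.96 * se[keep]),
                    p = p[keep], row.names = NULL, stringsAsFactors = FALSE)
  score <- plogis(drop(model.matrix(~ endotype + age + gcs + male, dat) %*% est))
  lpm <- lm(y ~ endotype + age + gcs + male, dat)
  structure(list(
    coefficients = tab, reference = levels(dat$endotype)[1],
    formula = "outcome ~ endotype + age + gcs + male",
    outcome = outcome, n = nrow(dat), n_dropped = n_dropped,
    deviance = if (separated) NA_real_ else fit$deviance,
    mcfadden = if (separated) NA_real_
               else 1 - fit$deviance / fit$null.deviance,
    r2_lpm = summary(lpm)$r.squared,
    auc = auc_rank(score, dat$y),
    separated = separated
  ), class = "adjusted_model")
}

#' @export
print.adjusted_model <- function(x, ...) {
  cat(sprintf("Adjusted logistic model: %s (reference endotype %s, n = %d%s)\n",
              x$formula, x$reference, x$n,
              if (x$n_dropped) sprintf(", %d rows dropped", x$n_dropped) else ""))
  if (x$separated) cat("NOTE: separation detected; ridge-penalised fit\n")
  print(transform(x$coefficients,
                  estimate = round(estimate, 4), or = round(or, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("AUC %.3f | McFadden R2 %.3f | linear-probability R2 %.3f\n",
              x$auc, x$mcfadden, x$r2_lpm))
  invisible(x)
}

#' ANCOVA of length of stay across endotypes
#'
#' Linear model `los ~ endotype + age + gcs + male` with a sequential F
#' table and Tukey honest-significant-difference comparisons of adjusted
#' endotype means (family-wise intervals via \pkg{multcomp}). A constant
#' covariate is dropped with a warning; a rank-deficient design is an error
#' naming the collinear columns.
#'
#' @param patients patient table with `los`, `age`, `gcs`, `male`.
#' @param assignments endotype per patient (at least two groups).
#' @return object of class `ancova_result` with the F table (data frame), the
#'   Tukey comparison table (`contrast`, `estimate`, `se`, `t`, `p_adj`,
#'   family-wise `ci_lo`/`ci_hi`) and the underlying `lm` fit.
#' @export
ancova_los <- function(patients, assignments) {
  endo <- factor(assignments)
  stopifnot(nlevels(endo) >= 2)
  dat <- data.frame(los = patients$los, endotype = endo, age = patients$age,
                    gcs = patients$gcs, male = patients$male)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  covars <- c("age", "gcs", "male")
  constant <- covars[vapply(covars, function(v) sd(dat[[v]]) == 0, logical(1))]
  if (length(constant)) {
    warning("dropping constant covariate(s): ", paste(constant, collapse = ", "))
    covars <- setdiff(covars, constant)
  }
  form <- as.formula(paste("los ~ endotype",
                           paste(c("", covars), collapse = " + ")))
  fit <- lm(form, dat)
  if (any(is.na(coef(fit))))
    stop("singular design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  ftab <- as.data.frame(anova(fit))
  ftab <- data.frame(term = rownames(ftab), ftab, row.names = NULL,
                     check.names = FALSE)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(endotype = "Tukey"))
  sm <- summary(glht_fit)
  ci <- confint(glht_fit)$confint
  tukey <- data.frame(
    contrast = names(sm$test$coefficients),
    estimate = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    t = as.numeric(sm$test$tstat),
    p_adj = as.numeric(sm$test$pvalues),
    ci_lo = ci[, "lwr"], ci_hi = ci[, "upr"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(f_table = ftab, tukey = tukey, fit = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("ANCOVA (sequential F):\n")
  print(x$f_table, row.names = FALSE, digits = 4)
  cat("\nTukey adjusted pairwise comparisons:\n")
  print(transform(x$tukey, estimate = round(estimate, 2), se = round(se, 2),
                  t = round(t, 3), p_adj = signif(p_adj, 3),
                  ci_lo = round(ci_lo, 2), ci_hi = round(ci_hi, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Survival rates stratified by age and injury-severity bins
#'
#' Builds the endotype x age-bin x GCS-severity table of survival counts and
#' rates, and runs two-proportion tests between selected endotype pairs
#' within each stratum, Holm-adjusted across the whole comparison family.
#' Empty strata get `NA` rates and are excluded from testing.
#'
#' @param patients patient table with `age`, `gcs`, `survived`.
#' @param assignments endotype per patient.
#' @param compare character vector of endotype labels to test pairwise within
#'   strata (default: all).
#' @param alpha family-wise level.
#' @return list of class `stratified_rates`: `rates` (long data frame) and
#'   `tests` (`pairwise_tests` with stratum columns).
#' @export
stratified_rates <- function(patients, assignments, compare = NULL,
                             alpha = 0.05) {
  endo <- factor(assignments)
  age_bin <- bin_age(patients$age)
  sev <- bin_gcs(patients$gcs)
  keep <- !is.na(age_bin) & !is.na(sev)
  grid <- expand.grid(endotype = levels(endo), age_bin = levels(age_bin),
                      severity = levels(sev), stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    sel <- keep & endo == grid$endotype[r] & age_bin == grid$age_bin[r] &
      sev == grid$severity[r]
    n <- sum(sel); alive <- sum(patients$survived[sel] == 1)
    data.frame(grid[r, ], n = n, alive = alive, expired = n - alive,
               survival_rate = rate_pct(alive, n), stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  cmp <- compare %||% levels(endo)
  strata <- unique(rates[, c("age_bin", "severity")])
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- rates[rates$age_bin == strata$age_bin[s] &
                 rates$severity == strata$severity[s] &
                 rates$endotype %in% cmp & rates$n > 0, , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- pair_grid(nrow(sub))
    for (r in seq_len(nrow(idx))) {
      a <- idx[r, 1]; b <- idx[r, 2]
      pt <- suppressWarnings(prop.test(c(sub$alive[a], sub$alive[b]),
                                       c(sub$n[a], sub$n[b])))
      rows[[length(rows) + 1L]] <- data.frame(
        age_bin = strata$age_bin[s], severity = strata$severity[s],
        group_a = sub$endotype[a], group_b = sub$endotype[b],
        statistic = unname(pt$statistic), test = "two-proportion",
        p = pt$p.value, stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(rows)) holm_set(do.call(rbind, rows), alpha) else NULL
  structure(list(rates = rates, tests = tests),
            class = "stratified_rates")
}

#' @export
print.stratified_rates <- function(x, ...) {
  print(x$rates[x$rates$n > 0, ], row.names = FALSE)
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve as the tie-corrected Mann-Whitney statistic:
#' the probability that a random positive outscores a random negative, with
#' ties counting one half.
#'
#' @param scores numeric predictions.
#' @param labels binary 0/1 outcomes.
#' @return AUC in `[0, 1]`; `NA` if either class is empty.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare survival models built from comorbidities, endotypes and covariates
#'
#' Fits the ladder of logistic models used to assess the predictive value of
#' endotypes: comorbidities only, endotypes only, both, each with and without
#' the age/GCS/sex covariates, the covariate-only base model, and the
#' single-variable models. For each model the rank-based AUC, the McFadden
#' pseudo-R2 from the logit fit, and the R2 of the matching
#' linear-probability (OLS) fit are reported; nested pairs are compared with
#' an F test on the linear-probability fits.
#'
#' @param patients patient table with `survived`, `age`, `gcs`, `male`.
#' @param assignments endotype per patient.
#' @param x binary comorbidity matrix aligned with the patients.
#' @return object of class `model_comparison`: `models` (per-model fit
#'   statistics) and `f_tests` (nested-pair F comparisons).
#' @export
model_comparison <- function(patients, assignments, x) {
  x <- check_binary_matrix(x)
  stopifnot(nrow(x) == nrow(patients))
  dat <- data.frame(y = patients$survived, endotype = factor(assignments),
                    age = patients$age, gcs = patients$gcs,
                    male = patients$male)
  cm <- as.data.frame(x)
  names(cm) <- make.names(colnames(x) %||% paste0("item", seq_len(ncol(x))))
  dat <- cbind(dat, cm)
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  comorb <- paste(names(cm), collapse = " + ")
  specs <- list(
    comorbidities = paste("y ~", comorb),
    endotypes = "y ~ endotype",
    comorbidities_endotypes = paste("y ~ endotype +", comorb),
    comorbidities_covariates = paste("y ~ age + gcs + male +", comorb),
    endotypes_covariates = "y ~ endotype + age + gcs + male",
    comorbidities_endotypes_covariates =
      paste("y ~ endotype + age + gcs + male +", comorb),
    base_covariates = "y ~ age + gcs + male",
    age_only = "y ~ age", gcs_only = "y ~ gcs", sex_only = "y ~ male")
  fit_one <- function(f) {
    gl <- glm(as.formula(f), binomial(), data = dat)
    ol <- lm(as.formula(f), data = dat)
    list(glm = gl, lm = ol,
         auc = auc_rank(fitted(gl), dat$y),
         mcfadden = 1 - gl$deviance / gl$null.deviance,
         r2_lpm = summary(ol)$r.squared)
  }
  fits <- lapply(specs, fit_one)
  models <- data.frame(
    model = names(specs),
    formula = unlist(specs),
    auc = vapply(fits, `[[`, numeric(1), "auc"),
    r2_lpm = vapply(fits, `[[`, numeric(1), "r2_lpm"),
    mcfadden = vapply(fits, `[[`, numeric(1), "mcfadden"),
    row.names = NULL, stringsAsFactors = FALSE)
  nested <- list(
    c("comorbidities", "comorbidities_endotypes"),
    c("comorbidities_covariates", "comorbidities_endotypes_covariates"),
    c("base_covariates", "endotypes_covariates"))
  f_tests <- do.call(rbind, lapply(nested, function(pr) {
    av <- anova(fits[[pr[1]]]$lm, fits[[pr[2]]]$lm)
    data.frame(reduced = pr[1], full = pr[2],
               df1 = av$Df[2], df2 = av$Res.Df[2],
               f = av$F[2], p = av$`Pr(>F)`[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(models = models, f_tests = f_tests, n = nrow(dat)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Survival model comparison (n = %d):\n", x$n))
  print(transform(x$models[, c("model", "auc", "r2_lpm", "mcfadden")],
                  auc = round(auc, 3), r2_lpm = round(r2_lpm, 3),
                  mcfadden = round(mcfadden, 3)), row.names = FALSE)
  cat("\nNested-model F tests (linear-probability fits):\n")
  print(transform(x$f_tests, f = round(f, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Comorbidity-burden model of survival
#'
#' Logistic fit of survival on the comorbidity count plus age, GCS and sex,
#' with the Pearson correlation between age and count reported as the
#' collinearity check.
#'
#' @param patients patient table with `survived`, `age`, `gcs`, `male`.
#' @param counts comorbidity count per patient (row sums of the matrix).
#' @return object of class `adjusted_model` with the extra element
#'   `age_count_correlation`.
#' @export
comorbidity_burden_model <- function(patients, counts) {
  stopifnot(length(counts) == nrow(patients))
  dat <- data.frame(y = patients$survived, count = counts,
                    age = patients$age, gcs = patients$gcs,
                    male = patients$male)
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  fit <- glm(y ~ count + age + gcs + male, binomial(), data = dat)
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  p <- 2 * pnorm(-abs(est / se))
  keep <- names(est) != "(Intercept)"
  tab <- data.frame(term = names(est)[keep], estimate = est[keep],
                    or = exp(est[keep]),
                    ci_lo = exp(est[keep] - 1.96 * se[keep]),
                    ci_hi = exp(est[keep] + 1.96 * se[keep]),
                    p = p[keep], row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    coefficients = tab, reference = NA_character_,
    formula = "survived ~ count + age + gcs + male", outcome = "survived",
    n = nrow(dat), n_dropped = sum(!cc), deviance = fit$deviance,
    mcfadden = 1 - fit$deviance / fit$null.deviance,
    r2_lpm = summary(lm(y ~ count + age + gcs + male, dat))$r.squared,
    auc = auc_rank(fitted(fit), dat$y), separated = FALSE,
    age_count_correlation = cor(dat$age, dat$count)
  ), class = "adjusted_model")
}
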