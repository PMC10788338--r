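block_data <- function() rbind(matrix(1, 5, 2), matrix(0, 5, 2))

test_that("the mixture log-likelihood matches closed forms and the oracle", {
  # K = 1, J = 1, x = (1,1,0,0), rho = 0.5
  x <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(lca_loglik(x, 1, matrix(0.5, 1, 1)), 4 * log(0.5),
               tolerance = 1e-12)
  # identical class rows collapse to the one-class likelihood
  set.seed(5)
  x2 <- matrix(rbinom(40, 1, 0.4), 10, 4)
  rho <- matrix(runif(4), 1, 4)
  expect_equal(lca_loglik(x2, c(0.5, 0.5), rbind(rho, rho)),
               lca_loglik(x2, 1, rho), tolerance = 1e-12)
  # brute-force per-row summation oracle on random instances
  for (s in 1:5) {
    set.seed(100 + s)
    xi <- matrix(rbinom(100, 1, 0.5), 20, 5)
    K <- sample(2:4, 1)
    pi <- rgamma(K, 1); pi <- pi / sum(pi)
    rh <- matrix(runif(K * 5, 0.05, 0.95), K, 5)
    expect_equal(lca_loglik(xi, pi, rh), bf_loglik(xi, pi, rh),
                 tolerance = 1e-12)
    # permuting class labels leaves the likelihood unchanged
    p <- sample(K)
    expect_equal(lca_loglik(xi, pi[p], rh[p, , drop = FALSE]),
                 lca_loglik(xi, pi, rh), tolerance = 1e-12)
  }
  # boundary parameters can zero out an observation
  expect_warning(
    ll <- lca_loglik(matrix(1, 1, 1), 1, matrix(0, 1, 1)), "zero density")
  expect_identical(ll, -Inf)
})

test_that("EM recovers perfectly separated blocks", {
  f <- lca(block_data(), 2, nrep = 5, seed = 2)
  expect_equal(unname(f$pi), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(f$loglik, 10 * log(0.5), tolerance = 1e-3)
  # item probabilities pinned near 0/1 within the clamp
  expect_true(all(abs(f$rho - round(f$rho)) <= 1e-5))
  # assignments recover the two blocks exactly
  expect_length(unique(f$assignments[1:5]), 1)
  expect_length(unique(f$assignments[6:10]), 1)
  expect_false(f$assignments[1] == f$assignments[6])
  # the spec'd information criteria at m = 5 parameters
  expect_equal(f$npar, 5)
  expect_equal(f$aic, -2 * f$loglik + 10, tolerance = 1e-12)
})

test_that("a one-class fit is the independence model", {
  set.seed(9)
  x <- matrix(rbinom(300, 1, runif(6, 0.2, 0.8)[rep(1:6, each = 50)]), 50, 6)
  f <- lca(x, 1, nrep = 1, seed = 1)
  expect_equal(unname(f$pi), 1)
  expect_equal(unname(f$rho[1, ]), unname(colMeans(x)), tolerance = 1e-9)
  cm <- colMeans(x)
  ll_closed <- sum(x %*% log(cm) + (1 - x) %*% log(1 - cm))
  expect_equal(f$loglik, ll_closed, tolerance = 1e-9)
  expect_equal(f$npar, 6)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(17)
  for (rep in 1:4) {
    x <- matrix(rbinom(30 * 6, 1, runif(1, 0.2, 0.7)), 30, 6)
    f <- lca(x, sample(2:3, 1), nrep = 2, seed = rep)
    expect_true(all(diff(f$loglik_trace) >= -1e-9))
  }
})

test_that("a richer model never fits worse (nesting)", {
  set.seed(23)
  x <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5)
  f1 <- lca(x, 1, nrep = 1, seed = 1)
  f2 <- lca(x, 2, nrep = 10, seed = 1)
  expect_gte(f2$loglik, f1$loglik - 1e-9)
})

test_that("posterior ties break toward the lower class index", {
  f <- lca(block_data(), 2, nrep = 3, seed = 4)
  # force identical classes so every posterior row is exactly (0.5, 0.5)
  f$rho[2, ] <- f$rho[1, ]
  f$pi[] <- 0.5
  tau <- predict(f, block_data())
  expect_true(all(abs(tau - 0.5) < 1e-12))
  expect_true(all(predict(f, block_data(), type = "class") == 1))
})

test_that("invalid inputs are rejected with informative errors", {
  x <- block_data()
  expect_error(lca(x, 0), "at least 1")
  expect_error(lca(x, 11), "exceed")
  x_na <- x; x_na[1, 1] <- NA
  expect_error(lca(x_na, 2), "missing")
  expect_error(lca(matrix(2, 4, 2), 2), "0/1")
  expect_error(lca_loglik(x, c(0.7, 0.7), matrix(0.5, 2, 2)), "summing to 1")
})

test_that("the fitted object supports the standard modelling verbs", {
  set.seed(31)
  x <- rbind(matrix(rbinom(60, 1, 0.85), 15, 4),
             matrix(rbinom(60, 1, 0.10), 15, 4))
  colnames(x) <- paste0("c", 1:4)
  f <- lca(x, 2, nrep = 5, seed = 6)
  expect_s3_class(f, "lca")
  expect_output(print(f), "K = 2 classes")
  expect_output(print(summary(f)), "top items")
  expect_equal(dim(coef(f)), c(2, 4))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), f$npar)
  expect_equal(AIC(ll), f$aic)
  expect_equal(BIC(ll), f$bic)
  # AIC - BIC algebra
  expect_equal(f$aic - f$bic, f$npar * (2 - log(f$N)), tolerance = 1e-10)
  expect_equal(information_criteria(f),
               c(aic = f$aic, bic = f$bic), tolerance = 1e-12)
  expect_identical(assign_classes(f), f$assignments)
  # simulate draws from the fitted generative model, reproducibly
  s1 <- simulate(f, seed = 9); s2 <- simulate(f, seed = 9)
  expect_identical(s1, s2)
  expect_equal(dim(s1), dim(x))
  # fitted probabilities and residuals
  expect_equal(dim(fitted(f)), dim(x))
  expect_equal(residuals(f, x = x), x - fitted(f))
  # posterior prediction on new data matches training posteriors
  expect_equal(predict(f, x), f$posterior, ignore_attr = TRUE)
  # JSON serialisation round-trips the key parameters
  path <- withr::local_tempfile(fileext = ".json")
  write_lca_json(f, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$loglik, f$loglik)
  expect_equal(unname(unlist(js$pi)), unname(f$pi), tolerance = 1e-12)
})
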