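#' Fit a binary latent class model by EM
#'
#' Fits a `K`-class mixture of independent Bernoulli items to a binary
#' indicator matrix:
#' \deqn{f(x_i) = \sum_k \pi_k \prod_j \rho_{kj}^{x_{ij}} (1-\rho_{kj})^{1-x_{ij}}}
#' by expectation-maximisation with random restarts. Each restart initialises
#' the responsibilities from a flat Dirichlet per response pattern, applies an
#' M-step, and iterates E/M until the relative log-likelihood change drops
#' below `tol` or `max_iter` is reached; the restart with the highest final
#' log-likelihood wins. Duplicate response patterns are collapsed to weighted
#' unique rows internally, which leaves the likelihood unchanged. Item
#' probabilities are clamped to `[eps, 1 - eps]`. A restart whose smallest
#' class mass falls below `1e-8 * N` is abandoned and redrawn. Classes of the
#' returned fit are ordered by decreasing mixing weight.
#'
#' @param x binary matrix or data frame, patients in rows, indicators in
#'   columns; no missing values (resolve them during cohort construction).
#' @param k number of latent classes (`1 <= k <= nrow(x)`).
#' @param nrep number of random restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param eps probability clamp for the item-response parameters.
#' @return object of class `lca` with components `pi` (mixing weights), `rho`
#'   (`K x J` item probabilities), `posterior` (`N x K` responsibilities),
#'   `assignments` (modal class per patient), `loglik`, `loglik_trace`
#'   (winning restart), `npar`, `aic`, `bic`, `iterations`, `converged`,
#'   `best_restart`, `n_abandoned` (restarts redrawn for empty classes) and
#'   the call.
#' @seealso [lca_loglik()], [lca_k_range()], [replicate_lca()]
#' @examples
#' x <- rbind(matrix(1, 5, 2), matrix(0, 5, 2))
#' f <- lca(x, 2, nrep = 3, seed = 1)
#' f$pi
#' @export
lca <- function(x, k, nrep = 20, tol = 1e-8, max_iter = 5000, seed = NULL,
                eps = 1e-6) {
  cl <- match.call()
  x <- check_binary_matrix(x)
  n <- nrow(x); J <- ncol(x)
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("k must not exceed the number of patients")
  if (!is.null(seed)) set.seed(seed)
  key <- apply(x, 1, paste, collapse = "")
  ukey <- unique(key)
  xu <- x[match(ukey, key), , drop = FALSE]
  w <- as.numeric(table(factor(key, levels = ukey)))
  u <- nrow(xu)
  best <- NULL; n_abandoned <- 0L
  r <- 0L
  while (r < nrep) {
    tau0 <- matrix(rgamma(u * k, 1), u, k)
    tau0 <- tau0 / rowSums(tau0)
    fit <- em_core(xu, w, tau0, tol, max_iter, eps)
    if (fit$empty_class) {
      n_abandoned <- n_abandoned + 1L
      if (n_abandoned > 50L * nrep)
        stop("EM failed: repeated empty-class collapses; reduce k")
      next
    }
    r <- r + 1L
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit; best$restart <- r
    }
  }
  ord <- order(best$pi, decreasing = TRUE)
  pi <- as.numeric(best$pi)[ord]
  rho <- best$rho[ord, , drop = FALSE]
  tau_u <- best$tau[, ord, drop = FALSE]
  dimnames(rho) <- list(paste0("class", seq_len(k)), colnames(x))
  posterior <- tau_u[match(key, ukey), , drop = FALSE]
  dimnames(posterior) <- list(rownames(x), rownames(rho))
  assignments <- max.col(posterior, ties.method = "first")
  names(assignments) <- rownames(x)
  npar <- (k - 1L) + k * J
  ll <- best$loglik
  structure(list(
    call = cl, N = n, J = J, K = k,
    pi = setNames(pi, rownames(rho)), rho = rho, posterior = posterior,
    assignments = assignments, loglik = ll,
    loglik_trace = as.numeric(best$trace),
    npar = npar, aic = -2 * ll + 2 * npar, bic = -2 * ll + npar * log(n),
    iterations = best$iterations, converged = best$converged,
    best_restart = best$restart, n_abandoned = n_abandoned,
    nrep = nrep, seed = seed, eps = eps, tol = tol,
    item_names = colnames(x)
  ), class = "lca")
}

#' Log-likelihood of a binary latent class model
#'
#' Evaluates the mixture log-likelihood at given parameters, computed stably
#' in log space. Returns `-Inf` with a warning if any observation has zero
#' density (possible only with boundary item probabilities).
#'
#' @param x binary matrix.
#' @param pi mixing weights (probability vector of length `K`).
#' @param rho `K x J` item probability matrix.
#' @return the summed log-likelihood.
#' @export
lca_loglik <- function(x, pi, rho) {
  x <- check_binary_matrix(x)
  rho <- rbind(rho)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability vector summing to 1")
  if (any(rho < 0 | rho > 1)) stop("rho entries must lie in [0, 1]")
  if (ncol(x) != ncol(rho) || length(pi) != nrow(rho))
    stop("dimension mismatch between x, pi and rho")
  lp <- x %*% t(log(rho)) + (1 - x) %*% t(log1p(-rho))
  lp <- sweep(lp, 2, log(pi), "+")
  m <- apply(lp, 1, max)
  ls <- m + log(rowSums(exp(lp - m)))
  bad <- !is.finite(ls)
  if (any(bad)) {
    warning(sprintf("%d observation(s) have zero density under the model", sum(bad)))
    return(-Inf)
  }
  sum(ls)
}

#' Information criteria of a latent class fit
#'
#' `AIC = -2L + 2m` and `BIC = -2L + m log N` with `m = (K - 1) + K * J`
#' free parameters (the unconstrained count is used regardless of clamped
#' boundary estimates).
#'
#' @param fit an [lca()] fit.
#' @param n cohort size (defaults to the fit's).
#' @return named numeric vector with `aic` and `bic`.
#' @export
information_criteria <- function(fit, n = fit$N) {
  c(aic = -2 * fit$loglik + 2 * fit$npar,
    bic = -2 * fit$loglik + fit$npar * log(n))
}

#' Modal class assignments
#'
#' Argmax over each patient's posterior responsibilities; ties break toward
#' the lower class index.
#'
#' @param fit an [lca()] fit.
#' @return integer vector of class labels in `1..K`.
#' @export
assign_classes <- function(fit) {
  a <- max.col(fit$posterior, ties.method = "first")
  names(a) <- rownames(fit$posterior)
  a
}

#' @export
print.lca <- function(x, digits = 3, ...) {
  cat(sprintf("Binary latent class model: K = %d classes, %d items, N = %d\n",
              x$K, x$J, x$N))
  cat(sprintf("logLik %.3f | AIC %.2f | BIC %.2f | %d parameters\n",
              x$loglik, x$aic, x$bic, x$npar))
  cat(sprintf("converged: %s after %d iterations (best of %d restarts)\n",
              x$converged, x$iterations, x$nrep))
  cat("mixing weights:", paste(round(x$pi, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lca <- function(object, n_items = 5, ...) {
  top <- lapply(seq_len(object$K), function(k) {
    p <- sort(object$rho[k, ], decreasing = TRUE)
    head(p, n_items)
  })
  structure(list(fit = object, top_items = top,
                 class_counts = tabulate(object$assignments, object$K)),
            class = "summary.lca")
}

#' @export
print.summary.lca <- function(x, ...) {
  print(x$fit)
  for (k in seq_along(x$top_items)) {
    cat(sprintf("\nclass%d  (n = %d, pi = %.3f) top items:\n", k,
                x$class_counts[k], x$fit$pi[k]))
    print(round(x$top_items[[k]], 3))
  }
  invisible(x)
}

#' @export
coef.lca <- function(object, ...) {
  structure(object$rho, pi = object$pi)
}

#' @export
logLik.lca <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' @rdname lca
#' @param object,newdata an `lca` fit and a binary matrix of new patients.
#' @param type `"posterior"` for responsibilities, `"class"` for modal labels.
#' @param ... unused.
#' @export
predict.lca <- function(object, newdata = NULL, type = c("posterior", "class"),
                        ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    tau <- object$posterior
  } else {
    newdata <- check_binary_matrix(newdata, "newdata")
    lp <- newdata %*% t(log(object$rho)) +
      (1 - newdata) %*% t(log1p(-object$rho))
    lp <- sweep(lp, 2, log(object$pi), "+")
    m <- apply(lp, 1, max)
    tau <- exp(lp - (m + log(rowSums(exp(lp - m)))))
    colnames(tau) <- rownames(object$rho)
  }
  if (type == "posterior") tau else max.col(tau, ties.method = "first")
}

#' @export
simulate.lca <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(s) {
    z <- sample.int(object$K, object$N, replace = TRUE, prob = object$pi)
    x <- matrix(rbinom(object$N * object$J, 1,
                       object$rho[z, , drop = FALSE]),
                object$N, object$J)
    colnames(x) <- object$item_names
    attr(x, "class_labels") <- z
    x
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
fitted.lca <- function(object, ...) {
  object$posterior %*% object$rho
}

#' @export
residuals.lca <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    cl <- object$call
    stop("supply the original data matrix via `x` to compute residuals")
  }
  x <- check_binary_matrix(x)
  x - fitted(object)
}

#' @export
plot.lca <- function(x, ...) {
  matplot(t(x$rho), type = "b", pch = 19, lty = 1,
          xlab = "item", ylab = "item probability", ylim = c(0, 1),
          xaxt = "n", ...)
  axis(1, at = seq_len(x$J), labels = x$item_names, las = 2, cex.axis = 0.6)
  legend("topright", legend = sprintf("class%d (pi=%.2f)", seq_len(x$K), x$pi),
         col = seq_len(x$K), lty = 1, pch = 19, cex = 0.7)
  invisible(x)
}

#' Serialize a latent class fit to JSON
#'
#' @param fit an [lca()] fit.
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_lca_json <- function(fit, path) {
  jsonlite::write_json(list(
    K = fit$K, J = fit$J, N = fit$N, pi = fit$pi, rho = fit$rho,
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic, npar = fit$npar,
    iterations = fit$iterations, converged = fit$converged,
    best_restart = fit$best_restart, seed = fit$seed,
    assignments = unname(fit$assignments)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
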