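#' Replicate latent class fits
#'
#' Repeats the full best-of-restarts fit `r` times at a fixed class count
#' with distinct derived seeds (`base_seed`, `base_seed + 1`, ...), emulating
#' independent reruns of the clustering algorithm on the same data.
#'
#' @param x binary comorbidity matrix.
#' @param k class count.
#' @param r number of replicate fits (at least 2).
#' @param base_seed seed of the first replicate.
#' @param nrep,tol,max_iter passed to [lca()].
#' @return object of class `lca_replicates`: list of fits plus the seeds.
#' @export
replicate_lca <- function(x, k, r = 30, base_seed = 1L, nrep = 20,
                          tol = 1e-8, max_iter = 5000) {
  stopifnot(r >= 2)
  seeds <- as.integer(base_seed) + seq_len(r) - 1L
  stopifnot(!anyDuplicated(seeds))
  fits <- lapply(seeds, function(s)
    lca(x, k, nrep = nrep, tol = tol, max_iter = max_iter, seed = s))
  structure(list(fits = fits, seeds = seeds, k = k), class = "lca_replicates")
}

#' Pool class profiles from replicate fits
#'
#' @param replicates an [replicate_lca()] result.
#' @return matrix of item-probability profiles (one row per class per
#'   replicate) with attributes
#'   `replicate` (source fit per row) and `aic` (per fit).
#' @export
pool_profiles <- function(replicates) {
  profs <- do.call(rbind, lapply(replicates$fits, `[[`, "rho"))
  attr(profs, "replicate") <- rep(seq_along(replicates$fits),
                                  each = replicates$k)
  attr(profs, "aic") <- vapply(replicates$fits, `[[`, numeric(1), "aic")
  profs
}

#' Align class labels between two profile matrices
#'
#' Finds the row permutation of `candidate` minimising the total Euclidean
#' distance to the rows of `reference` (optimal assignment, solved with the
#' Hungarian algorithm). Entry `p[i]` of the result is the candidate row
#' matched to reference row `i`.
#'
#' @param reference,candidate `K x J` item-probability matrices.
#' @return integer permutation of `1..K` with attribute `cost` (the total
#'   matched distance).
#' @export
align_labels <- function(reference, candidate) {
  reference <- rbind(reference); candidate <- rbind(candidate)
  if (!all(dim(reference) == dim(candidate)))
    stop("reference and candidate must have identical dimensions")
  K <- nrow(reference)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- sqrt(sum((reference[i, ] - candidate[j, ])^2))
  p <- solve_assignment(cost)
  structure(p, cost = sum(cost[cbind(seq_len(K), p)]))
}

# Hungarian algorithm (shortest augmenting path with dual potentials),
# O(n^3); returns assigned column per row of the square cost matrix.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Meta-cluster replicate class profiles
#'
#' Pools the class profiles of replicate fits and fits Gaussian mixtures with
#' diagonal covariances (latent profile analysis) for `G = 1..g_max`,
#' choosing `G` by BIC via \pkg{mclust} with a regularising prior. Reports,
#' per meta-cluster, the mean and SD profile; a stability score (the fraction
#' of replicates contributing exactly one profile to each of the `K` largest
#' meta-clusters); the representative replicate (globally lowest AIC, ties
#' toward the lowest index); and the maximum elementwise difference between
#' each replicate's profiles and the representative's after optimal label
#' alignment.
#'
#' @param replicates an [replicate_lca()] result, or a plain profile matrix
#'   (rows in `[0,1]`) with attributes `replicate` and `aic` as produced by
#'   [pool_profiles()].
#' @param g_max largest number of meta-clusters searched; capped at the
#'   number of distinct profiles (with a message) since more components than
#'   distinct points cannot be fit.
#' @return object of class `stability_report`.
#' @export
meta_cluster <- function(replicates, g_max = 10) {
  stopifnot(g_max >= 1)
  if (inherits(replicates, "lca_replicates")) {
    profiles <- pool_profiles(replicates)
    k <- replicates$k
  } else {
    profiles <- replicates
    k <- nrow(profiles) / length(unique(attr(profiles, "replicate")))
  }
  if (any(profiles < 0 | profiles > 1))
    stop("profiles must lie in [0, 1]")
  rep_id <- attr(profiles, "replicate")
  aics <- attr(profiles, "aic")
  if (is.null(rep_id) || length(unique(rep_id)) < 2)
    stop("need profiles from at least two replicate fits")
  n_distinct <- nrow(unique(round(profiles, 8)))
  g_hi <- min(g_max, n_distinct)
  if (g_hi < g_max)
    message(sprintf("only %d distinct profiles; searching G = 1..%d", n_distinct, g_hi))
  fit <- suppressWarnings(mclust::Mclust(
    profiles, G = seq_len(g_hi),
    modelNames = c("EII", "VII", "EEI", "VVI"),
    prior = mclust::priorControl(), verbose = FALSE))
  if (is.null(fit))
    stop("meta-clustering failed; try lowering g_max")
  G <- fit$G
  cls <- fit$classification
  meta_mean <- t(vapply(seq_len(G), function(g)
    colMeans(profiles[cls == g, , drop = FALSE]), numeric(ncol(profiles))))
  meta_sd <- t(vapply(seq_len(G), function(g)
    apply(profiles[cls == g, , drop = FALSE], 2, sd), numeric(ncol(profiles))))
  colnames(meta_mean) <- colnames(meta_sd) <- colnames(profiles)
  # stability: each replicate should place exactly one profile in each of the
  # K most-populated meta-clusters
  top_k <- as.integer(names(sort(table(cls), decreasing = TRUE)))[seq_len(min(k, G))]
  reps <- sort(unique(rep_id))
  ok <- vapply(reps, function(r) {
    tab <- table(factor(cls[rep_id == r], levels = top_k))
    all(tab == 1L)
  }, logical(1))
  score <- mean(ok)
  representative <- which.min(aics)   # ties: which.min takes the first
  rep_rho <- profiles[rep_id == representative, , drop = FALSE]
  max_aligned_diff <- max(vapply(reps, function(r) {
    cand <- profiles[rep_id == r, , drop = FALSE]
    if (nrow(cand) != nrow(rep_rho)) return(NA_real_)
    perm <- align_labels(rep_rho, cand)
    max(abs(rep_rho - cand[perm, , drop = FALSE]))
  }, numeric(1)), na.rm = TRUE)
  structure(list(
    n_replicates = length(reps), k = k, G = G,
    model_name = fit$modelName, classification = cls,
    meta_mean = meta_mean, meta_sd = meta_sd,
    stability_score = score, representative = representative,
    replicate_aic = aics, max_aligned_diff = max_aligned_diff,
    profiles = profiles, g_max = g_max
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability of %d replicate %d-class fits\n", x$n_replicates, x$k))
  cat(sprintf("meta-clusters: G = %d (%s), stability score %.3f\n",
              x$G, x$model_name, x$stability_score))
  cat(sprintf("representative replicate: %d (AIC %.2f); max aligned profile difference %.4f\n",
              x$representative, x$replicate_aic[x$representative],
              x$max_aligned_diff))
  print(table(meta_cluster = x$classification))
  invisible(x)
}

#' @export
plot.stability_report <- function(x, ...) {
  matplot(t(x$meta_mean), type = "l", lty = 1,
          xlab = "item", ylab = "mean item probability", ylim = c(0, 1), ...)
  legend("topright", legend = sprintf("meta-cluster %d", seq_len(x$G)),
         col = seq_len(x$G), lty = 1, cex = 0.7)
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report a [meta_cluster()] result.
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_stability_json <- function(report, path) {
  jsonlite::write_json(list(
    n_replicates = report$n_replicates, k = report$k, G = report$G,
    stability_score = report$stability_score,
    representative = report$representative,
    max_aligned_diff = report$max_aligned_diff,
    classification = report$classification,
    meta_mean = report$meta_mean, meta_sd = report$meta_sd
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
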