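#' Fit latent class models over a range of class counts
#'
#' One best-of-restarts fit per `K`; the fits are cached on the returned
#' object for reuse by the stability stage. A failure at one `K` is recorded
#' and does not abort the curve.
#'
#' @param x binary comorbidity matrix.
#' @param k_min,k_max contiguous class-count range (`1 <= k_min < k_max`).
#' @param nrep,tol,max_iter passed to [lca()].
#' @param seed base seed; the fit at class count `K` uses `seed + K`.
#' @return object of class `aic_curve`: data frame of `(k, loglik, aic, bic,
#'   converged)` with the fit list, the selected `K` from [detect_elbow()]
#'   and any per-`K` errors attached.
#' @export
lca_k_range <- function(x, k_min = 1, k_max = 8, nrep = 20, tol = 1e-8,
                        max_iter = 5000, seed = 1L) {
  stopifnot(k_min >= 1, k_min < k_max, k_max <= nrow(x))
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks)); errors <- character(length(ks))
  for (idx in seq_along(ks)) {
    res <- tryCatch(lca(x, ks[idx], nrep = nrep, tol = tol,
                        max_iter = max_iter, seed = seed + ks[idx]),
                    error = function(e) e)
    if (inherits(res, "error")) errors[idx] <- conditionMessage(res)
    else fits[[idx]] <- res
  }
  ok <- !vapply(fits, is.null, logical(1))
  curve <- data.frame(
    k = ks[ok],
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    bic = vapply(fits[ok], `[[`, numeric(1), "bic"),
    converged = vapply(fits[ok], `[[`, logical(1), "converged"))
  obj <- structure(list(curve = curve, fits = fits[ok],
                        errors = errors[errors != ""], seed = seed),
                   class = "aic_curve")
  sel <- detect_elbow(obj)
  obj$selected_k <- sel
  obj$no_elbow <- attr(sel, "no_elbow")
  obj
}

#' Select the class count at the AIC elbow
#'
#' Rescales the `(K, AIC)` curve to the unit square and selects the `K`
#' maximising the distance below the chord joining the first and last points
#' (the "knee" of the curve). The unit-square normalisation makes the choice
#' invariant to affine rescaling of either axis. Ties break toward the
#' smaller `K`. The curve is declared elbow-free -- returning the smallest
#' `K` with attribute `no_elbow = TRUE` and a warning -- in two cases: no
#' point lies below the chord (e.g. a monotone increasing curve), or the
#' curve is not predominantly decreasing, i.e. the net drop from the first
#' point to the minimum is less than half the curve's total variation.
#' The latter guard is scale-free and stops a near-flat curve whose only
#' movement is fitting noise (structureless data) from yielding a
#' noise-driven knee.
#'
#' @param curve an `aic_curve` object, or a data frame with columns `k` and
#'   `aic` (at least three points, all finite).
#' @return selected `K` (integer, with a `no_elbow` attribute).
#' @export
detect_elbow <- function(curve) {
  cv <- if (inherits(curve, "aic_curve")) curve$curve else curve
  k <- as.numeric(cv$k); aic <- as.numeric(cv$aic)
  if (length(k) < 3) stop("need at least three curve points")
  if (any(!is.finite(aic))) stop("AIC values must be finite")
  if (is.unsorted(k, strictly = TRUE)) stop("k values must be strictly increasing")
  xs <- (k - k[1]) / (k[length(k)] - k[1])
  yr <- diff(range(aic))
  ys <- if (yr == 0) rep(0, length(aic)) else (aic - min(aic)) / yr
  # flatness guard: a knee needs the curve's movement to be mostly downward
  drop_ <- aic[1] - min(aic)
  tv <- sum(abs(diff(aic)))
  if (tv > 0 && drop_ / tv < 0.5) {
    warning("curve has no elbow (not predominantly decreasing); returning the smallest class count")
    return(structure(as.integer(k[1]), no_elbow = TRUE))
  }
  # signed vertical gap between the chord and each point (positive = below)
  chord <- ys[1] + (ys[length(ys)] - ys[1]) * xs
  gap <- chord - ys
  if (max(gap) <= 1e-12) {
    warning("curve has no elbow; returning the smallest class count")
    return(structure(as.integer(k[1]), no_elbow = TRUE))
  }
  structure(as.integer(k[which.max(gap)]), no_elbow = FALSE)
}

#' @export
print.aic_curve <- function(x, ...) {
  cat(sprintf("AIC curve over K = %d..%d; selected K = %d%s\n",
              min(x$curve$k), max(x$curve$k), x$selected_k,
              if (isTRUE(x$no_elbow)) " (no elbow; fell back to k_min)" else ""))
  print(x$curve, row.names = FALSE)
  if (length(x$errors)) cat("failed fits:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.aic_curve <- function(x, ...) {
  plot(x$curve$k, x$curve$aic, type = "b", pch = 19,
       xlab = "number of classes K", ylab = "AIC", ...)
  points(x$selected_k, x$curve$aic[x$curve$k == x$selected_k],
         col = "firebrick", pch = 19, cex = 1.6)
  invisible(x)
}

#' Serialize an AIC curve to JSON
#'
#' @param curve an `aic_curve`.
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_curve_json <- function(curve, path) {
  jsonlite::write_json(list(curve = curve$curve,
                            selected_k = curve$selected_k,
                            no_elbow = isTRUE(curve$no_elbow)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
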