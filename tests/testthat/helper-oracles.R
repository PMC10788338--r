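# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# mixture log-likelihood by direct per-row summation over classes
bf_loglik <- function(x, pi, rho) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    fi <- 0
    for (k in seq_along(pi)) {
      pk <- pi[k]
      for (j in seq_len(ncol(x)))
        pk <- pk * (if (x[i, j] == 1) rho[k, j] else 1 - rho[k, j])
      fi <- fi + pk
    }
    total <- total + log(fi)
  }
  total
}

# Holm step-down adjustment by explicit enumeration
bf_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (r in seq_len(n)) {
    running <- max(running, (n - r + 1) * p[o[r]])
    adj[o[r]] <- min(1, running)
  }
  adj
}

# AUC as the pairwise win fraction (ties count one half)
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# perpendicular distance from each unit-square-normalised curve point to the
# first-last chord, restricted to points below the chord
bf_chord_gaps <- function(k, aic) {
  xs <- (k - k[1]) / (k[length(k)] - k[1])
  ys <- (aic - min(aic)) / diff(range(aic))
  x1 <- xs[1]; y1 <- ys[1]; x2 <- xs[length(xs)]; y2 <- ys[length(ys)]
  num <- (y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1
  # positive where the point lies below the chord
  num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
}

# assignment problem by exhaustive search over permutations
bf_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(perm = best, cost = best_cost)
}

# a small multi-admission fixture: 10 admissions over 6 patients, 4 of whom
# carry a TBI code on at least one admission
admissions_fixture <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p5", "p6", "p6"),
    admission_id = c("a01", "a02", "a04", "a03", "a05", "a06", "a07", "a08",
                     "a09", "a10"),
    admit_date = c("2001-01-01", "2003-05-05",   # p1: earliest TBI wins
                   "2002-02-02", "2002-02-02",   # p2: same day, id tie-break
                   "2001-06-01", "2000-06-01",   # p3: only second is TBI-coded
                   "2004-01-01",                 # p4: TBI
                   "2001-09-09",                 # p5: no TBI codes
                   "2002-03-03", "2001-03-03"),  # p6: neither TBI-coded
    age = 40, male = 1, gcs = 12, survived = 1, intervention = 0, los = 3,
    icd9 = c("85220;4019", "85400", "80100", "80300", "4280", "9501;4280",
             "85221", "4019;2500", "4280", "42731"),
    stringsAsFactors = FALSE
  )
}
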