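#' Co-occurrence statistics for one comorbidity pair
#'
#' The relative risk of observing categories *i* and *j* in the same patient
#' is the observed joint count over the count expected under independence:
#' `RR = C_ij * N / (P_i * P_j)`, where `C_ij` is the co-occurrence count,
#' `P_i`, `P_j` the category prevalences and `N` the cohort size. The
#' confidence interval is a Katz-style log-scale interval,
#' `log RR +/- z_{0.975} / sqrt(C_ij)` (undefined at `C_ij = 0`), and the
#' p-value is a two-sided Fisher exact test on the 2x2 table.
#'
#' @param x binary comorbidity matrix (patients x categories).
#' @param i,j distinct column indices (or names).
#' @param conf_level confidence level for the interval.
#' @return one-row data frame with counts, `rr`, `ci_lo`, `ci_hi`, `p_value`
#'   and an `undefined` flag (set when either prevalence is zero, in which
#'   case the ratio is reported as 0 with `p = 1` and no interval).
#' @export
pair_stats <- function(x, i, j, conf_level = 0.95) {
  x <- check_binary_matrix(x)
  if (is.character(i)) i <- match(i, colnames(x))
  if (is.character(j)) j <- match(j, colnames(x))
  if (identical(i, j)) stop("i and j must name distinct categories")
  n <- nrow(x)
  xi <- x[, i]; xj <- x[, j]
  c_ij <- sum(xi * xj); p_i <- sum(xi); p_j <- sum(xj)
  undefined <- (p_i * p_j) == 0
  rr <- if (undefined) 0 else c_ij * n / (p_i * p_j)
  if (!undefined && c_ij > 0) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    half <- z / sqrt(c_ij)
    ci_lo <- rr * exp(-half); ci_hi <- rr * exp(half)
  } else ci_lo <- ci_hi <- NA_real_
  tab <- matrix(c(c_ij, p_i - c_ij, p_j - c_ij, n - p_i - p_j + c_ij), 2, 2)
  p_value <- if (undefined) 1 else fisher.test(tab)$p.value
  nm <- colnames(x)
  data.frame(i = i, j = j,
             cat_i = if (is.null(nm)) as.character(i) else nm[i],
             cat_j = if (is.null(nm)) as.character(j) else nm[j],
             count = c_ij, prev_i = p_i, prev_j = p_j, n = n,
             rr = rr, ci_lo = ci_lo, ci_hi = ci_hi, p_value = p_value,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' All pairwise co-occurrence statistics
#'
#' @param x binary comorbidity matrix with at least two columns.
#' @param conf_level confidence level passed to [pair_stats()].
#' @return data frame of class `pair_associations` with `J*(J-1)/2` rows,
#'   each unordered pair once (`i < j`).
#' @export
all_pairs <- function(x, conf_level = 0.95) {
  x <- check_binary_matrix(x)
  J <- ncol(x)
  stopifnot(J >= 2)
  idx <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r)
    pair_stats(x, idx[r, 1], idx[r, 2], conf_level)))
  rownames(out) <- NULL
  class(out) <- c("pair_associations", "data.frame")
  out
}

#' Build the filtered comorbidity association network
#'
#' Keeps edges with `p < p_max` and `RR > rr_min` (both strict). The true
#' relative risk is preserved on each edge; a separate `rr_display` attribute
#' carries `min(RR, rr_cap)` for plotting, so a handful of very strong
#' associations do not skew the colour scale.
#'
#' @param pairs a [all_pairs()] result.
#' @param p_max significance threshold (edges with smaller p survive).
#' @param rr_min relative-risk threshold (edges with larger RR survive).
#' @param rr_cap cap applied to the display attribute only.
#' @param prevalence optional named prevalence counts for the nodes; defaults
#'   to the values recorded in `pairs`.
#' @return object of class `assoc_network`: list with the `igraph` graph, the
#'   retained edge table and the filter settings.
#' @export
build_network <- function(pairs, p_max = 0.05, rr_min = 1.5, rr_cap = 5,
                          prevalence = NULL) {
  stopifnot(p_max >= 0, rr_min >= 0, rr_cap >= 0)
  keep <- !pairs$undefined & pairs$p_value < p_max & pairs$rr > rr_min
  edges <- pairs[keep, , drop = FALSE]
  cats <- sort(unique(c(pairs$cat_i, pairs$cat_j)))
  if (is.null(prevalence)) {
    prevalence <- setNames(numeric(length(cats)), cats)
    for (cat in cats) {
      pi_ <- c(pairs$prev_i[pairs$cat_i == cat], pairs$prev_j[pairs$cat_j == cat])
      prevalence[cat] <- pi_[1]
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$cat_i, to = edges$cat_j,
               count = edges$count, rr = edges$rr,
               rr_display = pmin(edges$rr, rr_cap),
               p_value = edges$p_value, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = cats, prevalence = as.numeric(prevalence[cats]),
                          stringsAsFactors = FALSE))
  structure(list(graph = g, edges = edges,
                 settings = list(p_max = p_max, rr_min = rr_min,
                                 rr_cap = rr_cap)),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("Comorbidity association network: %d nodes, %d edges (p < %g, RR > %g, display cap %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$settings$p_max, x$settings$rr_min, x$settings$rr_cap))
  invisible(x)
}

#' @export
plot.assoc_network <- function(x, ...) {
  g <- x$graph
  pr <- igraph::V(g)$prevalence
  sz <- 5 + 15 * pr / max(pr, 1)
  wd <- 1 + 4 * igraph::E(g)$count / max(igraph::E(g)$count, 1)
  cols <- grDevices::colorRampPalette(c("grey70", "firebrick"))(100)
  rrv <- igraph::E(g)$rr_display
  ci <- pmax(1, ceiling(99 * (rrv - min(rrv)) / max(rrv - min(rrv), 1e-9)))
  plot(g, vertex.size = sz, edge.width = wd, edge.color = cols[ci],
       layout = igraph::layout_with_fr(g), ...)
  invisible(x)
}

#' Write the association network to GraphML and delimited text
#'
#' @param network an [build_network()] result.
#' @param graphml_path path for the GraphML export (skipped if `NULL`).
#' @param edges_path path for the edge table CSV (skipped if `NULL`).
#' @return (invisibly) the network.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(network)
}
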