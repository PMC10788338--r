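#' Build or load a pipeline configuration
#'
#' A configuration holds either paths to input files (`patients`, optionally
#' `matrix`) or a `synthetic` block (arguments for
#' [default_endotype_scenario()]), but not both, plus the analysis settings.
#'
#' @param synthetic list with `n_patients` (and optionally `seed`) for the
#'   synthetic scenario, or `NULL`.
#' @param input list with `patients` (CSV path) and optionally `matrix` (CSV
#'   path), or `NULL`.
#' @param dialect,combine_hypertension Elixhauser mapping options.
#' @param tbi_prefixes TBI filter prefixes.
#' @param k_min,k_max class-count range for model selection.
#' @param replicates replicate fits for the stability stage.
#' @param nrep EM restarts per fit.
#' @param alpha significance level for outcome testing.
#' @param p_max,rr_min,rr_cap network filter settings.
#' @param seed global seed; per-stage seeds are derived as
#'   `seed + 1000 * stage_index`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            dialect = "quan2005", combine_hypertension = TRUE,
                            tbi_prefixes = tbi_code_prefixes(),
                            k_min = 1, k_max = 8, replicates = 30, nrep = 20,
                            alpha = 0.05, p_max = 0.05, rr_min = 1.5,
                            rr_cap = 5, seed = 1L) {
  if (is.null(synthetic) == is.null(input))
    stop("exactly one of `synthetic` or `input` must be given")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(synthetic = synthetic, input = input, dialect = dialect,
                 combine_hypertension = combine_hypertension,
                 tbi_prefixes = tbi_prefixes, k_min = k_min, k_max = k_max,
                 replicates = replicates, nrep = nrep, alpha = alpha,
                 p_max = p_max, rr_min = rr_min, rr_cap = rr_cap,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the endotype discovery pipeline end to end
#'
#' Stages, in order: cohort construction (synthetic scenario or file input),
#' comorbidity matrix, co-occurrence network, class-count selection,
#' replicate-fit stability, and outcome comparison. Every artifact is written
#' under `out_dir` and listed in a JSON manifest together with seeds, stage
#' timings and row counts. Reruns with the same configuration are
#' deterministic.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input) && !file.exists(config$input$patients))
    stop("input file not found: ", config$input$patients)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = character())
  t_stage <- function(expr) {
    t0 <- Sys.time()
    val <- force(expr)
    attr(val, "elapsed") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    val
  }
  record <- function(name, elapsed, files, rows) {
    manifest$stages[[name]] <<- list(elapsed_sec = round(elapsed, 3),
                                     files = unname(files), rows = rows)
    manifest$files <<- c(manifest$files, unname(files))
    message(sprintf("[%s] %.2fs, %d rows -> %s", name, elapsed, rows,
                    paste(basename(files), collapse = ", ")))
  }
  on.exit({
    manifest$completed <- names(manifest$stages)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  mapping <- elixhauser_map(config$dialect, config$combine_hypertension)

  # stage 1: cohort
  t0 <- Sys.time()
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    cfg <- default_endotype_scenario(
      seed = derive_seed(sc$seed %||% config$seed, 1L),
      n_patients = sc$n_patients %||% 2629)
    cohort <- generate_cohort(cfg)
    cohort <- emit_icd9_codes(cohort, mapping,
                              seed = derive_seed(config$seed, 1L, 1L))
    patients <- cohort$patients
  } else {
    patients <- read.csv(config$input$patients, stringsAsFactors = FALSE)
    cohort <- NULL
  }
  patients <- filter_cohort(patients, config$tbi_prefixes)
  f_pat <- file.path(out_dir, "patients.csv")
  write.csv(patients, f_pat, row.names = FALSE)
  record("cohort", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_pat, nrow(patients))

  # stage 2: comorbidity matrix
  t0 <- Sys.time()
  if (!is.null(config$input$matrix)) {
    m <- read.csv(config$input$matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
    x <- as.matrix(m[, -1, drop = FALSE]); rownames(x) <- m[[1]]
  } else {
    x <- comorbidity_matrix(patients, mapping)
  }
  f_mat <- file.path(out_dir, "comorbidity_matrix.csv")
  write.csv(data.frame(patient_id = rownames(x), x, check.names = FALSE),
            f_mat, row.names = FALSE)
  record("matrix", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_mat, nrow(x))

  # stage 3: co-occurrence network
  t0 <- Sys.time()
  pairs <- all_pairs(x)
  net <- build_network(pairs, config$p_max, config$rr_min, config$rr_cap)
  f_net <- c(file.path(out_dir, "network.graphml"),
             file.path(out_dir, "network_edges.csv"))
  write_network(net, f_net[1], f_net[2])
  record("network", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_net, nrow(net$edges))

  # stage 4: class-count selection
  t0 <- Sys.time()
  curve <- lca_k_range(x, config$k_min, config$k_max, nrep = config$nrep,
                       seed = derive_seed(config$seed, 4L))
  f_sel <- file.path(out_dir, "aic_curve.json")
  write_curve_json(curve, f_sel)
  record("selection", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_sel, nrow(curve$curve))
  k_star <- curve$selected_k

  # stage 5: replicate-fit stability
  t0 <- Sys.time()
  reps <- replicate_lca(x, k_star, r = config$replicates,
                        base_seed = derive_seed(config$seed, 5L),
                        nrep = config$nrep)
  report <- meta_cluster(reps)
  best <- reps$fits[[report$representative]]
  f_stab <- c(file.path(out_dir, "stability.json"),
              file.path(out_dir, "representative_fit.json"))
  write_stability_json(report, f_stab[1])
  write_lca_json(best, f_stab[2])
  record("stability", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_stab, nrow(report$profiles))

  # stage 6: outcomes
  t0 <- Sys.time()
  assignments <- best$assignments
  tab <- outcome_table(assignments, patients)
  surv_tests <- pairwise_chisq(tab, "survival", config$alpha)
  intv_tests <- pairwise_chisq(tab, "intervention", config$alpha)
  los_tests <- pairwise_los_tests(split(patients$los, assignments),
                                  config$alpha)
  adj <- adjusted_binary_model(patients, assignments, "survived")
  anc <- ancova_los(patients, assignments)
  strat <- stratified_rates(patients, assignments, alpha = config$alpha)
  cmp <- model_comparison(patients, assignments, x)
  burden <- comorbidity_burden_model(patients, rowSums(x))
  f_out <- c(file.path(out_dir, "outcome_table.csv"),
             file.path(out_dir, "outcomes.json"))
  write.csv(tab, f_out[1], row.names = FALSE)
  jsonlite::write_json(list(
    outcome_table = tab, survival_tests = surv_tests,
    intervention_tests = intv_tests, los_tests = los_tests,
    adjusted_survival = adj$coefficients,
    ancova_f = anc$f_table, tukey = anc$tukey,
    stratified = strat$rates, stratified_tests = strat$tests,
    model_comparison = cmp$models, model_f_tests = cmp$f_tests,
    burden = burden$coefficients,
    age_count_correlation = burden$age_count_correlation
  ), f_out[2], auto_unbox = TRUE, digits = NA)
  record("outcomes", as.numeric(difftime(Sys.time(), t0, units = "secs")),
         f_out, nrow(tab))

  manifest$selected_k <- k_star
  manifest$stability_score <- report$stability_score
  invisible(manifest)
}
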