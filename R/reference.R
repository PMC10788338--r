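#' Published reference outcome counts for the TBI endotype cohort
#'
#' Loads the printed summary counts of the source TBI study that the package
#' reproduces as rates: whole-cohort survival/intervention counts, per-endotype
#' outcome counts, and survival counts stratified by age bin and injury
#' severity for the Healthy (HE), Alcohol Abuse (AA) and Hypertension (HTN)
#' endotypes. These tables are inputs, not computed results; [rate_pct()]
#' applied to the counts reproduces the printed percentages.
#'
#' @param which one of `"cohort"`, `"endotype"`, `"stratified"`.
#' @return data frame of counts with the printed rate column.
#' @examples
#' ref <- reference_counts("endotype")
#' all(rate_pct(ref$alive, ref$alive + ref$expired) == ref$printed_survival_rate)
#' @export
reference_counts <- function(which = c("cohort", "endotype", "stratified")) {
  which <- match.arg(which)
  fn <- switch(which,
               cohort = "cohort_outcome_counts.csv",
               endotype = "endotype_outcome_counts.csv",
               stratified = "stratified_survival_counts.csv")
  read.csv(system.file("extdata", fn, package = "endolca"),
           stringsAsFactors = FALSE)
}
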