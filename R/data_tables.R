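#' Published condition-level mean CI-bar tables
#'
#' Mean normalized concentration-index values (mean +- SEM, n) per reporter
#' group and treatment, transcribed from the reporter-validation study's
#' printed condition tables: `"15min"` (15 minutes after serum/FGF4
#' stimulation; three reporter groups) and `"late"` (1 h and 2 h after
#' stimulation; two groups). These are inputs for
#' [summarize_conditions()], which recomputes the tables' derived
#' fold-change, delta and cross-ratio columns from the means.
#'
#' @param which `"15min"` or `"late"`.
#' @return data.frame: `group`, `label`, `mean_ci`, `sem`, `n`.
#' @export
published_ci_table <- function(which = c("15min", "late")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "15min") "table2_ci.csv" else "table3_ci.csv",
                   package = "nucytoloc", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
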