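# Readers for the in-package reference tables: the factor levels of the
# screening study, the printed 18-run design/response table, and the
# optimization-vs-verification comparison.

.extdata <- function(f) system.file("extdata", f, package = "ireplan", mustWork = TRUE)

#' Factor levels of the five-parameter screening study
#' @return data.frame with columns factor, level1, level2, level3.
#' @export
ire_table_levels <- function() utils::read.csv(.extdata("table1_levels.csv"))

#' The 18-run screening design with its simulated responses
#'
#' Columns: run_id, the five factor settings in natural units, the ablation
#' area (mm^2) and the maximum temperature (degrees C).
#' @return data.frame, 18 rows.
#' @export
ire_screening_table <- function() utils::read.csv(.extdata("table5_design_responses.csv"))

#' Reference optimization-vs-verification comparison
#' @return data.frame with columns response, rsm, models, error_pct.
#' @export
ire_verification_table <- function() utils::read.csv(.extdata("table6_comparison.csv"))
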