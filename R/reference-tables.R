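# Published summary tables shipped as plain-text inputs for the
# arithmetic-consistency stages (aggregation additivity, share
# percentages, record-count bookkeeping).

#' Published continent/biome carbon summary table
#'
#' The printed global, continental and biome-level summary of additionally
#' preserved PA carbon (Gt, with SE), total PA carbon stock (Gt, with SE)
#' and PA area (million km2), shipped as CSV. Used as the input to the
#' aggregation-consistency checks (summing the continental rows must
#' reproduce the printed global total).
#'
#' @return Data frame with columns `level` (`globe`/`continent`/`biome`),
#'   `name`, `additional_gt`, `additional_se_gt`, `total_agc_gt`,
#'   `total_agc_se_gt`, `area_mkm2`.
#' @export
published_carbon_table <- function() {
  utils::read.csv(system.file("extdata", "published_carbon_table.csv",
                              package = "pacarbon"),
                  stringsAsFactors = FALSE)
}

#' Published protected-area database record counts
#'
#' Record-count bookkeeping of the protected-area database snapshot used:
#' polygon and point record counts and the printed total.
#'
#' @return List with `polygons`, `points`, `printed_total`.
#' @export
wdpa_record_counts <- function() {
  df <- utils::read.csv(system.file("extdata", "wdpa_counts.csv",
                                    package = "pacarbon"),
                        stringsAsFactors = FALSE)
  list(polygons = df$count[df$record_type == "polygon"],
       points = df$count[df$record_type == "point"],
       printed_total = df$count[df$record_type == "printed_total"])
}
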