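# Serialisation of a synthetic landscape: cell and footprint tables as CSV,
# PA outlines as GeoJSON with WDPA-like attributes, a JSON run manifest,
# and the ground-truth table in its own file so analysis stages cannot
# silently read it.

#' Write a landscape (and optionally footprints) to disk
#'
#' Writes `cells.csv`, `pas.csv`, `truth.csv` (ground truth, separate file
#' by design), `pas.geojson` (polygon outlines with `pa_id`, `status_yr`,
#' `country`, `area_km2` attributes), optionally `footprints.csv`, and a
#' `manifest.json` recording the full configuration including the seed.
#'
#' @param landscape A `pacarbon_landscape`.
#' @param out_dir Output directory (created if needed).
#' @param footprints Optional footprint table from [sample_footprints()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_landscape <- function(landscape, out_dir, footprints = NULL) {
  stopifnot(inherits(landscape, "pacarbon_landscape"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    cells = file.path(out_dir, "cells.csv"),
    pas = file.path(out_dir, "pas.csv"),
    truth = file.path(out_dir, "truth.csv"),
    geojson = file.path(out_dir, "pas.geojson"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(landscape$cells, paths["cells"], row.names = FALSE)
  utils::write.csv(landscape$pas, paths["pas"], row.names = FALSE)
  utils::write.csv(landscape$truth, paths["truth"], row.names = FALSE)
  writeLines(pa_geojson(landscape$pas, landscape$cells), paths["geojson"])
  manifest <- list(seed = landscape$config$seed,
                   true_delta = landscape$true_delta,
                   config = unclass(landscape$config))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(footprints)) {
    paths <- c(paths, footprints = file.path(out_dir, "footprints.csv"))
    utils::write.csv(footprints, paths["footprints"], row.names = FALSE)
  }
  invisible(paths)
}

# GeoJSON FeatureCollection of the PA cell-set outlines (planar km
# coordinates; one unit-square polygon per member cell, as a MultiPolygon;
# WDPA-like attribute names)
pa_geojson <- function(pas, cells) {
  features <- lapply(seq_len(nrow(pas)), function(i) {
    p <- pas[i, ]
    member <- cells[!is.na(cells$pa_id) & cells$pa_id == p$pa_id, ]
    squares <- lapply(seq_len(nrow(member)), function(j) {
      x0 <- member$col[j] - 1; y0 <- member$row[j] - 1
      list(list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                c(x0, y0 + 1), c(x0, y0)))
    })
    list(
      type = "Feature",
      properties = list(pa_id = p$pa_id, status_yr = p$status_yr,
                        country = p$country, area_km2 = p$area_km2),
      geometry = list(type = "MultiPolygon", coordinates = squares)
    )
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param dir Directory containing the files written by [write_landscape()].
#' @param with_truth Read the ground-truth table too (tests only).
#' @return A `pacarbon_landscape` (with `truth = NULL` unless
#'   `with_truth = TRUE`), plus `footprints` if present in `dir`.
#' @export
read_landscape <- function(dir, with_truth = FALSE) {
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  pas <- utils::read.csv(file.path(dir, "pas.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  truth <- NULL
  if (with_truth) truth <- utils::read.csv(file.path(dir, "truth.csv"))
  cfg <- manifest$config
  cfg$status_year_range <- as.integer(cfg$status_year_range)
  config <- do.call(landscape_config, cfg[names(cfg) %in% names(formals(landscape_config))])
  out <- structure(list(cells = cells, pas = pas, truth = truth,
                        true_delta = manifest$true_delta, config = config),
                   class = "pacarbon_landscape")
  fp_path <- file.path(dir, "footprints.csv")
  if (file.exists(fp_path)) out$footprints <- utils::read.csv(fp_path)
  out
}
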