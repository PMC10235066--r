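# Along-track lidar footprint sampling over a generated landscape.

#' Sample lidar footprints along parallel tracks
#'
#' Places shots on parallel north-south tracks crossing the grid
#' (`track_spacing_m` apart, shots every `footprint_spacing_along_m` along
#' track, random phase per track). Random along-track dropout segments
#' emulate non-continuous lidar coverage, so some cells receive few or no
#' shots. Per-shot AGBD is the cell expectation plus Gaussian noise
#' truncated at zero; canopy height (RH98), canopy cover and plant area
#' index are saturating monotone transforms of AGBD with independent noise;
#' the quality flag is Bernoulli and sensitivity Beta-distributed.
#'
#' Uses its own seed stream (`config$seed + 1000003`), so the same
#' landscape and configuration always yield the same shot table.
#'
#' @param landscape A `pacarbon_landscape` from [generate_landscape()].
#' @param config A [landscape_config()]; defaults to the landscape's own.
#' @return A data frame of footprints: `shot_id`, `cell_id`, `track_id`,
#'   `x`, `y` (km), `rh98` (m), `canopy_cover` (fraction), `pai`,
#'   `agbd` (Mg/ha), `quality_flag` (0/1), `sensitivity` (fraction).
#' @export
sample_footprints <- function(landscape, config = landscape$config) {
  stopifnot(inherits(landscape, "pacarbon_landscape"))
  set.seed(config$seed + 1000003L)

  width <- config$grid_cols; height <- config$grid_rows  # km
  ts <- config$track_spacing_m / 1000
  fs <- config$footprint_spacing_along_m / 1000
  seg <- config$dropout_segment_km

  x0 <- stats::runif(1, 0, ts)
  track_x <- seq(x0, width, by = ts)
  track_x <- track_x[track_x < width]
  n_tracks <- length(track_x)
  n_seg <- ceiling(height / seg)

  shots <- vector("list", n_tracks)
  for (j in seq_len(n_tracks)) {
    y0 <- stats::runif(1, 0, fs)
    ys <- seq(y0, height, by = fs)
    ys <- ys[ys < height]
    keep_seg <- stats::runif(n_seg) >= config$track_dropout_rate
    keep <- keep_seg[pmin(n_seg, floor(ys / seg) + 1L)]
    ys <- ys[keep]
    if (length(ys) == 0) next
    shots[[j]] <- data.frame(track_id = j, x = track_x[j], y = ys)
  }
  shots <- do.call(rbind, shots)
  if (is.null(shots) || nrow(shots) == 0) {
    stop("footprint sampling produced no shots; check spacing and dropout settings",
         call. = FALSE)
  }

  n <- nrow(shots)
  shots$shot_id <- seq_len(n)
  shots$cell_id <- as.integer(floor(shots$y) * width + floor(shots$x) + 1)
  expected <- landscape$truth$agbd_expected[shots$cell_id]
  agbd <- pmax(0, expected + stats::rnorm(n, 0, config$shot_noise_sd))

  p <- pmin(1 - 1e-9, pmax(1e-9, agbd / (agbd + 90)))
  shots$rh98 <- 35 * agbd / (agbd + 120) * exp(stats::rnorm(n, 0, 0.1))
  shots$canopy_cover <- stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, 0.25))
  shots$pai <- 7 * agbd / (agbd + 160) * exp(stats::rnorm(n, 0, 0.1))
  shots$agbd <- agbd
  shots$quality_flag <- as.integer(stats::runif(n) >= config$p_bad_quality)
  shots$sensitivity <- stats::rbeta(n, config$sensitivity_shape1,
                                    config$sensitivity_shape2)
  shots[, c("shot_id", "cell_id", "track_id", "x", "y", "rh98",
            "canopy_cover", "pai", "agbd", "quality_flag", "sensitivity")]
}
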