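# Counterfactual matching: control-pool construction with buffering, the
# logistic propensity model, common support + caliper, greedy 1:1
# nearest-neighbour matching without replacement within exact strata
# (land cover x country x ecoregion x biome), and balance diagnostics.

exact_strata_cols <- function() c("land_cover", "country", "ecoregion", "biome")

# distance from points to the nearest boundary of the PA cell union (km):
# minimum Euclidean distance to any protected cell's unit square; points
# inside a protected square get distance 0
min_dist_to_pas <- function(px, py, pa_cells) {
  d <- rep(Inf, length(px))
  sq_x0 <- pa_cells$col - 1; sq_y0 <- pa_cells$row - 1
  for (i in seq_len(nrow(pa_cells))) {
    dx <- pmax(sq_x0[i] - px, px - (sq_x0[i] + 1), 0)
    dy <- pmax(sq_y0[i] - py, py - (sq_y0[i] + 1), 0)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Build the treated set and eligible control pool
#'
#' Treated cells are protected cells lying entirely within a PA (full
#' coverage: `pa_cover_fraction == 1`; cells straddling a PA boundary are
#' excluded). Controls are unprotected cells whose center lies farther
#' than `buffer_km` from every PA boundary (the buffer removes mixed
#' pixels and local spillover). If `cell_metrics` is supplied, both sides
#' are restricted to qualified cells (enough passing shots).
#'
#' @param cells Cell table from the landscape (or real-data equivalent);
#'   an optional `pa_cover_fraction` column gives the fraction of each
#'   protected cell covered by its PA (assumed 1 when absent).
#' @param pas PA table (used for bookkeeping; geometry is taken from the
#'   protected cells).
#' @param buffer_km Buffer width around PA boundaries, km (default 10).
#' @param cell_metrics Optional output of [aggregate_to_cells()].
#' @return List with `treated` and `controls` cell tables (controls carry
#'   `in_buffer = FALSE`; buffer-excluded cells are counted in
#'   `n_buffer_excluded`).
#' @export
build_control_pool <- function(cells, pas, buffer_km = 10,
                               cell_metrics = NULL) {
  qualified <- rep(TRUE, nrow(cells))
  if (!is.null(cell_metrics)) {
    qualified <- cell_metrics$qualified[match(cells$cell_id,
                                              cell_metrics$cell_id)]
    qualified[is.na(qualified)] <- FALSE
  }

  prot <- cells$is_protected
  within <- if ("pa_cover_fraction" %in% names(cells)) {
    cells$pa_cover_fraction >= 1
  } else rep(TRUE, nrow(cells))
  treated <- cells[prot & within & qualified, , drop = FALSE]

  unprot <- cells[!prot, , drop = FALSE]
  d <- min_dist_to_pas(unprot$x, unprot$y, cells[prot, c("row", "col")])
  in_buffer <- d <= buffer_km
  controls <- unprot[!in_buffer & qualified[!prot], , drop = FALSE]
  controls$in_buffer <- FALSE
  list(treated = treated, controls = controls,
       n_buffer_excluded = sum(in_buffer), buffer_km = buffer_km)
}

#' Fit the logistic propensity model
#'
#' Maximum-likelihood logistic regression of the protection indicator on
#' z-standardized quantitative covariates (standardized over the pooled
#' sample for numerical stability). Fitting uses iteratively reweighted
#' least squares with convergence tolerance 1e-8 and at most 100
#' iterations. Under (near-)perfect separation the fit falls back to a
#' ridge-penalized version (penalty 1e-4 on the covariate coefficients)
#' with a warning.
#'
#' @param treated,controls Cell tables from [build_control_pool()].
#' @param covariates Names of the quantitative covariates
#'   (default [pa_covariates()]).
#' @return An object of class `propensity_model` with the standardized-scale
#'   coefficients, standardization constants, fitted-score ranges for both
#'   groups, and the SD of the fitted scores on the logit scale (used for
#'   the default caliper).
#' @export
fit_propensity <- function(treated, controls, covariates = pa_covariates()) {
  if (nrow(treated) == 0 || nrow(controls) == 0) {
    stop("both treated and control groups must be non-empty", call. = FALSE)
  }
  stopifnot_cols(treated, covariates, "treated cell table")
  stopifnot_cols(controls, covariates, "control cell table")
  X <- as.matrix(rbind(treated[, covariates, drop = FALSE],
                       controls[, covariates, drop = FALSE]))
  if (any(!is.finite(X))) {
    stop("quantitative covariates must be finite", call. = FALSE)
  }
  y <- c(rep(1L, nrow(treated)), rep(0L, nrow(controls)))
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  scales[!is.finite(scales) | scales == 0] <- 1
  Xs <- scale(X, center = centers, scale = scales)

  method <- "irls"
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xs), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  separated <- !fit$converged || any(!is.finite(beta)) ||
    any(mu > 1 - 1e-10) || any(mu < 1e-10)
  if (separated) {
    warning("(near-)perfect separation in the propensity fit; ",
            "using a ridge-penalized fit (penalty 1e-4)", call. = FALSE)
    method <- "ridge"
    beta <- ridge_logistic(Xs, y, lambda = 1e-4)
    mu <- as.vector(stats::plogis(cbind(1, Xs) %*% beta))
  }

  scores_t <- mu[y == 1]; scores_c <- mu[y == 0]
  structure(list(
    coefficients = stats::setNames(beta, c("(Intercept)", covariates)),
    centers = centers, scales = scales, covariates = covariates,
    method = method,
    range_treated = range(scores_t), range_control = range(scores_c),
    sd_logit = stats::sd(stats::qlogis(pmin(pmax(mu, 1e-12), 1 - 1e-12)))
  ), class = "propensity_model")
}

# Newton-IRLS for ridge-penalized logistic regression (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-8, maxit = 100) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Propensity scores for new cells
#'
#' @param object A `propensity_model`.
#' @param newdata Cell table containing the model covariates.
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict.propensity_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$covariates, drop = FALSE])
  Xs <- scale(X, center = object$centers, scale = object$scales)
  as.vector(stats::plogis(cbind(1, Xs) %*% object$coefficients))
}

#' Common support and score caliper
#'
#' The common-support restriction confines matching to the overlapping
#' score range `[max(min_t, min_c), min(max_t, max_c)]`; in addition a
#' score-distance caliper is set to `width_sd` times the SD of the fitted
#' scores on the logit scale (default 0.2, a conventional choice).
#'
#' @param model A fitted `propensity_model` (any list with elements
#'   `range_treated`, `range_control`, `sd_logit` works).
#' @param width_sd Caliper width as a multiple of SD(logit scores).
#' @return List with `support` (length-2 numeric; `NA`s and a warning when
#'   the ranges do not overlap), `caliper` (in logit-score units), and
#'   `scale = "logit"` (the caliper from this rule is applied to the gap
#'   between logit scores, the conventional usage).
#' @export
set_caliper <- function(model, width_sd = 0.2) {
  lo <- max(model$range_treated[1], model$range_control[1])
  hi <- min(model$range_treated[2], model$range_control[2])
  if (lo > hi) {
    warning("treated and control propensity-score ranges do not overlap; ",
            "no cells are matchable", call. = FALSE)
    support <- c(NA_real_, NA_real_)
  } else {
    support <- c(lo, hi)
  }
  list(support = support, caliper = width_sd * model$sd_logit,
       width_sd = width_sd, scale = "logit")
}

#' Match treated cells to counterfactual controls
#'
#' Within each exact stratum (land cover x country x ecoregion x biome),
#' treated cells are processed in descending propensity order and each is
#' paired, without replacement, with the eligible control of minimal
#' absolute score gap within the caliper (`match_rule = "nearest"`; the
#' literal highest-score reading is available as `"max_score"`). Cells
#' outside the common support are unmatched. Ties in the score gap are
#' broken by the lowest control `cell_id`, making the assignment
#' deterministic.
#'
#' @param treated,controls Cell tables from [build_control_pool()].
#' @param model A fitted `propensity_model`.
#' @param caliper Output of [set_caliper()] (gap measured on the logit
#'   scale), or a single number used directly as the probability-scale
#'   score-gap caliper with support taken from the model ranges; `NULL`
#'   (default) computes [set_caliper()] with its defaults.
#' @param match_rule `"nearest"` (default) or `"max_score"`.
#' @return An object of class `pacarbon_match`: list with `pairs` (one row
#'   per matched pair incl. stratum labels, `pa_id`, scores and
#'   `abs_score_gap`), `unmatched` (treated `cell_id` + reason), `caliper`,
#'   `support`.
#' @export
match_cells <- function(treated, controls, model, caliper = NULL,
                        match_rule = c("nearest", "max_score")) {
  match_rule <- match.arg(match_rule)
  if (is.null(caliper)) caliper <- set_caliper(model)
  if (is.numeric(caliper) && length(caliper) == 1) {
    caliper <- list(support = c(max(model$range_treated[1],
                                    model$range_control[1]),
                                min(model$range_treated[2],
                                    model$range_control[2])),
                    caliper = caliper, scale = "score")
  }
  cal <- caliper$caliper
  support <- caliper$support
  logit_gap <- identical(caliper$scale, "logit")

  st <- predict(model, treated)
  sc <- predict(model, controls)
  # gaps are measured on the same scale the caliper is defined on
  gs <- function(s) if (logit_gap) stats::qlogis(pmin(pmax(s, 1e-12), 1 - 1e-12)) else s
  gt <- gs(st); gc_ <- gs(sc)
  strat_t <- interaction(treated[exact_strata_cols()], drop = FALSE)
  strat_c <- interaction(controls[exact_strata_cols()], drop = FALSE)

  in_support <- function(s) {
    !is.na(support[1]) & s >= support[1] - 1e-12 & s <= support[2] + 1e-12
  }
  ok_t <- in_support(st); ok_c <- in_support(sc)

  unmatched <- data.frame(cell_id = treated$cell_id[!ok_t],
                          reason = rep("outside_support", sum(!ok_t)))
  pairs <- list()
  for (s in intersect(unique(strat_t[ok_t]), unique(strat_c[ok_c]))) {
    ti <- which(ok_t & strat_t == s)
    ci <- which(ok_c & strat_c == s)
    ti <- ti[order(-st[ti], treated$cell_id[ti])]
    avail <- rep(TRUE, length(ci))
    sci <- sc[ci]; gci <- gc_[ci]; idc <- controls$cell_id[ci]
    for (i in ti) {
      gaps <- abs(gci - gt[i])
      elig <- avail & gaps <= cal + 1e-12
      if (!any(elig)) {
        unmatched <- rbind(unmatched, data.frame(
          cell_id = treated$cell_id[i], reason = "no_control_in_caliper"))
        next
      }
      j <- which(elig)
      key <- if (match_rule == "nearest") gaps[j] else -sci[j]
      best <- j[key == min(key)]
      pick <- best[which.min(idc[best])]
      pairs[[length(pairs) + 1L]] <- data.frame(
        pa_cell_id = treated$cell_id[i],
        control_cell_id = idc[pick],
        pa_id = treated$pa_id[i],
        land_cover = treated$land_cover[i], country = treated$country[i],
        ecoregion = treated$ecoregion[i], biome = treated$biome[i],
        continent = if ("continent" %in% names(treated))
          treated$continent[i] else NA,
        score_pa = st[i], score_control = sci[pick],
        abs_score_gap = gaps[pick]
      )
      avail[pick] <- FALSE
    }
  }
  # treated cells whose stratum has no in-support controls at all
  seen <- c(if (length(pairs)) do.call(rbind, pairs)$pa_cell_id,
            unmatched$cell_id)
  rest <- setdiff(treated$cell_id, seen)
  if (length(rest) > 0) {
    unmatched <- rbind(unmatched, data.frame(
      cell_id = rest, reason = "no_control_in_stratum"))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  structure(list(pairs = pairs, unmatched = unmatched,
                 caliper = cal, support = support,
                 match_rule = match_rule),
            class = "pacarbon_match")
}

#' @export
print.pacarbon_match <- function(x, ...) {
  cat(sprintf("pacarbon_match: %d pairs, %d unmatched treated cells, caliper %.4g\n",
              nrow(x$pairs), nrow(x$unmatched), x$caliper))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (SMD, pooled-SD denominator) of each
#' quantitative covariate between treated and control cells, before
#' matching (full pools) and after (matched cells only), plus
#' propensity-score distribution summaries.
#'
#' @param pools Output of [build_control_pool()].
#' @param match Output of [match_cells()].
#' @param model The fitted `propensity_model`.
#' @param covariates Covariate names (default [pa_covariates()]).
#' @return Data frame with `covariate`, `smd_before`, `smd_after`.
#'   Score summaries are attached as attribute `"score_summary"`.
#' @export
balance_report <- function(pools, match, model,
                           covariates = pa_covariates()) {
  tr <- pools$treated; co <- pools$controls
  mt <- tr[match(match$pairs$pa_cell_id, tr$cell_id), , drop = FALSE]
  mc <- co[match(match$pairs$control_cell_id, co$cell_id), , drop = FALSE]
  out <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v) smd(tr[[v]], co[[v]]),
                        numeric(1)),
    smd_after = vapply(covariates, function(v) smd(mt[[v]], mc[[v]]),
                       numeric(1)),
    row.names = NULL
  )
  qs <- function(s) stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1))
  attr(out, "score_summary") <- rbind(
    treated_before = qs(predict(model, tr)),
    control_before = qs(predict(model, co)),
    treated_after = qs(match$pairs$score_pa),
    control_after = qs(match$pairs$score_control)
  )
  out
}
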