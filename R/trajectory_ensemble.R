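# Multi-decade projection driver: chains allocation steps into
# trajectories, varies the seeding sample size across realizations, and
# summarizes fragmentation change distributions.

#' Recompute land-use-derived predictor layers
#'
#' Refreshes the layers that depend on the current landscape (focal class
#' percents at the given windows and the current class code) while leaving
#' static layers (topography, hydrology, protection) untouched.
#'
#' @param predictors named list of predictor matrices.
#' @param grid the current [lu_grid()].
#' @param windows window sizes of the focal-percent layers.
#' @return the updated predictor list.
#' @export
refresh_landuse_predictors <- function(predictors, grid,
                                       windows = c(3L, 9L, 27L)) {
  for (cl in LU_LABELS) {
    for (w in windows) {
      nm <- sprintf("pct_%s_%d", cl, w)
      if (nm %in% names(predictors)) {
        predictors[[nm]] <- compute_focal_percent(grid, cl, w)
      }
    }
  }
  if ("t1_class" %in% names(predictors)) {
    predictors$t1_class <- grid$values * 1
  }
  predictors
}

#' Run an ensemble of multi-step trajectories
#'
#' Each realization draws its seeding sample size n uniformly from
#' `n_range`, then chains the steps: land-use-derived predictors are
#' recomputed from the current grid, probability surfaces are re-predicted
#' with the fixed per-grouping models, and the step's quotas are
#' allocated; each step's output is the next step's input. Fully
#' deterministic given `master_seed`. A step that fails validation aborts
#' that realization (recorded in its `error` field) and the ensemble
#' continues.
#'
#' @param base [lu_grid()] at the starting date.
#' @param counties a [county_partition()].
#' @param models named list of grouping models (held fixed across steps).
#' @param predictors named list of predictor matrices for the base grid.
#' @param step_quotas list over time steps; each element a quota
#'   data.frame (see [build_quota_ledgers()]).
#' @param patch_models named list from [fit_patch_models()].
#' @param realizations number of realizations.
#' @param n_range integer length-2, inclusive range for n.
#' @param master_seed master RNG seed.
#' @param windows focal windows used in the land-use predictors and the
#'   fragmentation summaries.
#' @return object of class `realization_ensemble`: list of realizations,
#'   each with `n`, `seed`, `grids` (per step), `frag` (per-step
#'   fragmentation summaries), `reports`.
#' @export
run_trajectory <- function(base, counties, models, predictors, step_quotas,
                           patch_models, realizations = 20L,
                           n_range = c(20L, 200L), master_seed = 1L,
                           windows = c(3L, 9L, 27L)) {
  if (n_range[1] > n_range[2]) stop("n_range must be (low, high)")
  if (realizations < 1L) stop("realizations must be >= 1")
  out <- vector("list", realizations)
  for (i in seq_len(realizations)) {
    rseed <- derive_seed(master_seed, paste0("realization-", i))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(rseed)
    n_i <- as.integer(sample_vec(n_range[1]:n_range[2], 1L))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    grids <- list()
    frags <- list()
    reports <- list()
    err <- NULL
    current <- base
    preds <- predictors
    for (s in seq_along(step_quotas)) {
      res <- tryCatch({
        preds <- refresh_landuse_predictors(preds, current, windows)
        stack <- predict_probability_stack(models, current, preds, counties)
        ledgers <- build_quota_ledgers(step_quotas[[s]],
                                       counties = counties$county_ids)
        cfg <- seeding_config(n = n_i,
                              seed = derive_seed(rseed, paste0("step-", s)))
        allocate_all(current, counties, stack, ledgers, patch_models, cfg)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        err <- conditionMessage(res)
        break
      }
      current <- res$t2
      grids[[s]] <- current
      frags[[s]] <- summarize_frag_areas(current, counties, windows)
      reports[[s]] <- res$reports
    }
    out[[i]] <- list(n = n_i, seed = rseed, grids = grids, frag = frags,
                     reports = reports, error = err)
  }
  structure(out, class = "realization_ensemble")
}

#' @export
print.realization_ensemble <- function(x, ...) {
  ns <- vapply(x, function(r) r$n, 0L)
  cat(sprintf("<realization_ensemble> %d realizations, %d step(s), n in [%d, %d]\n",
              length(x), length(x[[1]]$grids), min(ns), max(ns)))
  invisible(x)
}

#' Summarize fragmentation trajectories across an ensemble
#'
#' Per (region, fragmentation class, window, step): percent change of the
#' class's area versus the base summary, per realization, then the median
#' and first/third quartiles across realizations (type-7 quantiles:
#' linear interpolation between order statistics). A base area of 0 with a
#' nonzero later area is flagged undefined (`NA` change,
#' `undefined = TRUE`) rather than reported as a number.
#'
#' @param ensemble a `realization_ensemble` (realizations that errored
#'   out are skipped).
#' @param base_frag fragmentation summary of the base grid
#'   ([summarize_frag_areas()]).
#' @param measure column to compare (default `"cells"`).
#' @return data.frame `window, region, class, step, q1, median, q3,
#'   undefined`.
#' @export
summarize_trajectories <- function(ensemble, base_frag, measure = "cells") {
  ok <- Filter(function(r) is.null(r$error), ensemble)
  if (!length(ok)) stop("every realization failed")
  n_steps <- length(ok[[1]]$frag)
  key <- paste(base_frag$window, base_frag$region, base_frag$class, sep = "|")
  rows <- list()
  for (s in seq_len(n_steps)) {
    change <- sapply(ok, function(r) {
      f <- r$frag[[s]]
      f <- f[match(key, paste(f$window, f$region, f$class, sep = "|")), ]
      ifelse(base_frag[[measure]] == 0,
             ifelse(f[[measure]] == 0, 0, NA_real_),
             100 * (f[[measure]] - base_frag[[measure]]) / base_frag[[measure]])
    })
    change <- matrix(change, nrow = nrow(base_frag))
    qs <- t(apply(change, 1, function(x) {
      if (anyNA(x)) return(c(NA_real_, NA_real_, NA_real_))
      stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    }))
    rows[[s]] <- data.frame(
      window = base_frag$window, region = base_frag$region,
      class = base_frag$class, step = s,
      q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3],
      undefined = apply(change, 1, anyNA),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
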