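# Multi-scale focal-class forest-fragmentation classification and the
# ensemble coverage assessment used to evaluate allocated realizations.

#' Forest-fragmentation classes
#'
#' Percent-forest bands used to classify each forest cell by the forest
#' share of its focal window. Half-open intervals partition [0, 100]:
#' Rare [0,10), Patchy [10,40), Transitional [40,60), Dominant [60,90),
#' Interior [90,100].
#'
#' @format Character vector of class names, from sparse to intact.
#' @export
FRAG_CLASSES <- c("Rare", "Patchy", "Transitional", "Dominant", "Interior")

FRAG_BREAKS <- c(0, 10, 40, 60, 90, 100)

#' Classify percent-forest values into fragmentation classes
#'
#' @param percent_forest numeric matrix (or vector) of percents in
#'   `[0, 100]`; `NA` propagates.
#' @return factor (matrix dimensions preserved via a character matrix)
#'   with levels [FRAG_CLASSES].
#' @export
classify_fragmentation <- function(percent_forest) {
  ok <- !is.na(percent_forest)
  if (any(percent_forest[ok] < 0 | percent_forest[ok] > 100)) {
    stop("percent forest must lie in [0, 100]")
  }
  cls <- cut(percent_forest, breaks = FRAG_BREAKS, labels = FRAG_CLASSES,
             right = FALSE, include.lowest = FALSE)
  cls[ok & percent_forest == 100] <- "Interior"
  if (is.matrix(percent_forest)) {
    out <- matrix(as.character(cls), nrow(percent_forest))
    return(out)
  }
  cls
}

#' Summarize forest-fragmentation areas
#'
#' For each window size: computes percent forest with
#' [compute_focal_percent()], classifies it, and tallies the area per
#' fragmentation class over forest cells only (focal-class restriction: a
#' developed cell surrounded by forest is not counted; a forest cell
#' surrounded by development is), per reporting region.
#'
#' @param grid an [lu_grid()].
#' @param counties a [county_partition()] supplying the region of each
#'   cell.
#' @param windows integer vector of odd window sizes (default 3, 9, 27).
#' @return data.frame `window, region, class, cells, hectares`, covering
#'   every (window, region, class) combination (zero-filled).
#' @export
summarize_frag_areas <- function(grid, counties, windows = c(3L, 9L, 27L)) {
  check_alignment(grid, counties)
  forest <- !is.na(grid$values) & grid$values == class_code("f")
  region <- matrix(counties$region_of[counties$labels], nrow(grid$values))
  regions <- sort(unique(counties$region_of))
  cell_ha <- grid$cell_size^2 / 1e4
  rows <- list()
  for (w in windows) {
    pf <- compute_focal_percent(grid, "f", w)
    cls <- classify_fragmentation(pf)
    for (rg in regions) {
      sel <- forest & !is.na(region) & region == rg
      tab <- table(factor(cls[sel], levels = FRAG_CLASSES))
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, region = rg, class = FRAG_CLASSES,
        cells = as.integer(tab), hectares = as.integer(tab) * cell_ha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assess ensemble coverage of observed fragmentation
#'
#' For each (window, region, fragmentation class): the observed area is
#' covered when it lies within the min-max range of the realized areas;
#' the deviation is 0 when covered, otherwise the minimum absolute
#' difference to any realization as a percent of the observed area.
#'
#' @param observed a fragmentation summary ([summarize_frag_areas()]) of
#'   the reference grid.
#' @param ensemble list of fragmentation summaries, one per realization.
#' @param measure column to compare (default `"cells"`).
#' @return data.frame `window, region, class, observed, min, max,
#'   deviation_pct`; attribute `coverage_fraction` = share of cases with
#'   deviation 0.
#' @export
assess_coverage <- function(observed, ensemble, measure = "cells") {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  key <- function(d) paste(d$window, d$region, d$class, sep = "|")
  obs_key <- key(observed)
  realized <- sapply(ensemble, function(d) {
    if (!identical(key(d), obs_key)) {
      d <- d[match(obs_key, key(d)), ]
    }
    d[[measure]]
  })
  realized <- matrix(realized, nrow = nrow(observed))
  lo <- apply(realized, 1, min)
  hi <- apply(realized, 1, max)
  obs <- observed[[measure]]
  covered <- lo <= obs & obs <= hi
  dev <- numeric(length(obs))
  for (i in which(!covered)) {
    dev[i] <- if (obs[i] == 0) NA_real_ else
      100 * min(abs(realized[i, ] - obs[i])) / obs[i]
  }
  out <- data.frame(window = observed$window, region = observed$region,
                    class = observed$class, observed = obs,
                    min = lo, max = hi, deviation_pct = dev,
                    stringsAsFactors = FALSE)
  attr(out, "coverage_fraction") <- mean(covered)
  out
}
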