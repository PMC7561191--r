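# Transition-probability surfaces: county clustering into model groupings,
# training-sample assembly from paired reference grids, a delegated
# bagged-tree classifier behind a thin adapter, and per-cell probability
# stacks with the donor-masked generalized surface.

#' Cluster counties into model groupings
#'
#' Partitions counties into k groupings of similar character with k-means
#' on standardized features (z-scores). Counties in one grouping share a
#' single transition model.
#'
#' @param features data.frame with a `county` column and numeric feature
#'   columns (land-use fractions, mean elevation, mean slope, population,
#'   income, centroid coordinates, ...).
#' @param k number of groupings.
#' @param seed RNG seed; k-means is run with 10 restarts and the best
#'   inertia kept.
#' @return named character vector mapping county id to grouping id
#'   (`"g1"..."gk"`).
#' @export
cluster_counties <- function(features, k, seed = 1L) {
  if (!"county" %in% names(features)) stop("features needs a county column")
  ids <- as.character(features$county)
  x <- as.matrix(features[, setdiff(names(features), "county"), drop = FALSE])
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of counties")
  if (k == 1L || nrow(x) == 1L) {
    return(stats::setNames(rep("g1", length(ids)), ids))
  }
  sds <- apply(x, 2, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)
  stats::setNames(paste0("g", km$cluster), ids)
}

#' Assemble a training sample of observed transitions
#'
#' Census the gross transition types (donor-to-target pairs, including
#' persistence) between two aligned grids within one county grouping, then
#' sample up to `per_label` cells per type without replacement. Each row
#' carries the cell's predictor vector.
#'
#' @param t1,t2 aligned [lu_grid()]s at the two reference dates.
#' @param predictors named list of numeric matrices aligned to the grids
#'   (a predictor stack).
#' @param counties a [county_partition()].
#' @param grouping grouping id to sample within.
#' @param per_label target rows per transition type (default 500).
#' @param seed RNG seed.
#' @return data.frame with a `label` factor column (transition keys) and
#'   one column per predictor; attribute `grouping`.
#' @export
assemble_training_sample <- function(t1, t2, predictors, counties, grouping,
                                     per_label = 500L, seed = 1L) {
  if (!identical(dim(t1$values), dim(t2$values))) stop("t1/t2 shapes differ")
  check_alignment(t1, counties)
  in_grp <- !is.na(counties$labels) &
    counties$grouping_of[counties$labels] == grouping
  in_grp[is.na(in_grp)] <- FALSE
  usable <- in_grp & !is.na(t1$values) & !is.na(t2$values)
  idx <- which(usable)
  if (!length(idx)) stop("grouping ", grouping, " has no usable cells")
  d1 <- class_label(t1$values[idx])
  d2 <- class_label(t2$values[idx])
  lab <- transition_key(d1, d2)
  # only Forest/Agriculture/Other donate; Developed is terminal and Water
  # exchanges with nothing, so neither is modelled
  keep <- is_allowed(d1, d2) & d1 %in% c("f", "a", "o")
  idx <- idx[keep]
  lab <- lab[keep]
  if (!length(idx)) stop("no observed transitions in grouping ", grouping)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  take <- unlist(lapply(split(idx, lab), function(cells) {
    sample_vec(cells, size = min(per_label, length(cells)))
  }), use.names = FALSE)
  x <- as.data.frame(lapply(predictors, function(m) m[take]))
  out <- cbind(
    data.frame(label = factor(transition_key(class_label(t1$values[take]),
                                             class_label(t2$values[take])))),
    x)
  attr(out, "grouping") <- grouping
  out
}

#' Fit a grouping's transition classifier
#'
#' Thin adapter over an established bagged-tree ensemble
#' (\pkg{randomForest}): fit, per-label class probabilities, and the
#' out-of-bag error estimate. The ensemble internals are delegated, not
#' reimplemented.
#'
#' @param sample output of [assemble_training_sample()] (a data.frame with
#'   `label` plus predictor columns).
#' @param ntree number of trees (default 300).
#' @param seed RNG seed; fits are deterministic given the seed.
#' @return an object of class `grouping_model`: list with `grouping`,
#'   `labels`, `oob_error`, and the fitted ensemble.
#' @export
fit_grouping_model <- function(sample, ntree = 300L, seed = 1L) {
  if (length(unique(sample$label)) < 2L) {
    stop("degenerate training sample: a classifier needs >= 2 labels")
  }
  y <- droplevels(factor(sample$label))
  x <- sample[, setdiff(names(sample), "label"), drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  structure(
    list(grouping = attr(sample, "grouping") %||% "g1",
         labels = levels(y),
         oob_error = unname(rf$err.rate[ntree, "OOB"]),
         fit = rf),
    class = "grouping_model")
}

#' @export
print.grouping_model <- function(x, ...) {
  cat(sprintf("<grouping_model> grouping %s, %d labels, OOB error %.1f%%\n",
              x$grouping, length(x$labels), 100 * x$oob_error))
  invisible(x)
}

#' Per-row label probabilities from a grouping model
#'
#' @param model a `grouping_model` (or any list with a `$predict_prob`
#'   function, which lets tests supply analytic surfaces).
#' @param newdata data.frame of predictor columns.
#' @return numeric matrix, rows = input rows, columns = labels; each row
#'   sums to 1.
#' @export
predict_grouping_model <- function(model, newdata) {
  if (!is.null(model$predict_prob)) {
    p <- model$predict_prob(newdata)
  } else {
    p <- stats::predict(model$fit, newdata = newdata, type = "prob")
  }
  p
}

#' Build a transition-probability stack
#'
#' Container for per-cell, per-(donor, target) transition probabilities
#' and the collapsed generalized surface. The donor mask is enforced at
#' construction: `probs[["m->l"]]` is zeroed wherever the time-1 class is
#' not `m`, so the generalized probability of cell i converting to l
#' equals the probability under the cell's own class.
#'
#' @param probs named list of numeric matrices keyed by transition key.
#' @param t1 the time-1 [lu_grid()] the stack is aligned to.
#' @return object of class `prob_stack` with elements `probs` (masked) and
#'   `generalized` (one matrix per target class letter).
#' @export
probability_stack <- function(probs, t1) {
  dims <- dim(t1$values)
  for (k in names(probs)) {
    if (!identical(dim(probs[[k]]), dims)) stop("layer ", k, " misaligned")
  }
  ks <- split_key(names(probs))
  bad <- !is_allowed(ks$donor, ks$target)
  if (any(bad)) stop("disallowed layers: ",
                     paste(names(probs)[bad], collapse = ", "))
  masked <- probs
  for (i in seq_along(masked)) {
    donor_code <- class_code(ks$donor[i])
    m <- masked[[i]]
    m[is.na(t1$values) | t1$values != donor_code] <- 0
    m[is.na(m)] <- 0
    masked[[i]] <- m
  }
  gen <- lapply(stats::setNames(LU_LABELS, LU_LABELS), function(l) {
    g <- matrix(0, dims[1], dims[2])
    for (i in seq_along(masked)) if (ks$target[i] == l) g <- g + masked[[i]]
    g[is.na(t1$values)] <- 0
    g
  })
  structure(list(probs = masked, generalized = gen), class = "prob_stack")
}

#' @export
print.prob_stack <- function(x, ...) {
  cat(sprintf("<prob_stack> %d transition layers, %d x %d cells\n",
              length(x$probs), nrow(x$generalized[[1]]),
              ncol(x$generalized[[1]])))
  invisible(x)
}

#' Predict the transition-probability stack for a landscape
#'
#' Applies each grouping's classifier to the cells of its counties,
#' producing the per-pair probability layers and the generalized surface.
#' Label probabilities whose donor is not the cell's time-1 class are
#' zeroed (the donor mask); Developed and Water cells get probability 1 of
#' persisting and 0 elsewhere.
#'
#' @param models named list of `grouping_model`s keyed by grouping id.
#' @param t1 time-1 [lu_grid()].
#' @param predictors named list of predictor matrices.
#' @param counties a [county_partition()].
#' @return a `prob_stack`.
#' @export
predict_probability_stack <- function(models, t1, predictors, counties) {
  check_alignment(t1, counties)
  dims <- dim(t1$values)
  groupings <- unique(counties$grouping_of)
  missing_m <- setdiff(groupings, names(models))
  if (length(missing_m)) {
    stop("no model for grouping(s): ", paste(missing_m, collapse = ", "))
  }
  layers <- list()
  for (g in groupings) {
    in_grp <- !is.na(counties$labels) &
      counties$grouping_of[counties$labels] == g
    in_grp[is.na(in_grp)] <- FALSE
    cells <- which(in_grp & !is.na(t1$values) &
                     !(t1$values %in% class_code(c("d", "w"))))
    if (!length(cells)) next
    nd <- as.data.frame(lapply(predictors, function(m) m[cells]))
    p <- predict_grouping_model(models[[g]], nd)
    for (k in colnames(p)) {
      kk <- split_key(k)
      if (!is_allowed(kk$donor, kk$target)) next
      if (is.null(layers[[k]])) layers[[k]] <- matrix(0, dims[1], dims[2])
      donor_code <- class_code(kk$donor)
      sel <- t1$values[cells] == donor_code
      layers[[k]][cells[sel]] <- p[sel, k]
    }
  }
  # terminal classes persist with certainty
  for (cl in c("d", "w")) {
    k <- transition_key(cl, cl)
    if (is.null(layers[[k]])) layers[[k]] <- matrix(0, dims[1], dims[2])
    layers[[k]][!is.na(t1$values) & t1$values == class_code(cl)] <- 1
  }
  probability_stack(layers, t1)
}
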