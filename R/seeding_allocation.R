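# The hybrid seeding demand-allocation algorithm: tunable seed selection
# (sample size n spans the random-to-contagious continuum), odd-sized
# square patch windows around each seed, distance-modified ranking of
# candidate cells, and quota-constrained conversion, iterated per county.

#' Seeding configuration
#'
#' @param n seeding sample size: 1 reproduces random allocation, values at
#'   or above the eligible-cell count reproduce contagious allocation.
#' @param target_class_order order in which target classes consume their
#'   quotas. Developed first by default: it is terminal, so competition
#'   for donor cells is resolved in its favour.
#' @param seed RNG seed used by [allocate_all()] to derive per-county
#'   streams.
#' @param max_failed_seeds consecutive zero-conversion seeds tolerated
#'   before a target class is abandoned with its remaining quota recorded
#'   as shortfall.
#' @return a `seeding_config` list.
#' @export
seeding_config <- function(n = 16L, target_class_order = c("d", "f", "a", "o"),
                           seed = 1L, max_failed_seeds = 25L) {
  if (n < 1L) stop("n must be >= 1")
  if (anyDuplicated(target_class_order)) {
    stop("target_class_order must not repeat classes")
  }
  if (!all(target_class_order %in% c("d", "f", "a", "o"))) {
    stop("targets must be among d, f, a, o")
  }
  structure(list(n = as.integer(n), target_class_order = target_class_order,
                 seed = as.integer(seed),
                 max_failed_seeds = as.integer(max_failed_seeds)),
            class = "seeding_config")
}

#' Annular (Chebyshev) distance between two cells
#'
#' `max(|row_a - row_b|, |col_a - col_b|)`: the ring index of the square
#' annulus around a cell, so all cells of a k x k window centered on a
#' seed lie within distance (k-1)/2.
#'
#' @param a,b integer length-2 vectors `(row, col)` (or two-column
#'   matrices for vectorized use).
#' @return non-negative integer distance(s).
#' @export
annular_distance <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2)
    b <- matrix(b, ncol = 2)
    return(pmax(abs(a[, 1] - b[, 1]), abs(a[, 2] - b[, 2])))
  }
  max(abs(a[1] - b[1]), abs(a[2] - b[2]))
}

#' Select a seed cell
#'
#' Draws `min(n, #eligible)` distinct eligible cells uniformly and returns
#' the one with the highest generalized transition probability; ties are
#' broken by a uniform draw among the tied cells.
#'
#' @param gen_prob numeric matrix: generalized probability of converting
#'   each cell to the target class.
#' @param eligible logical matrix flagging the sampling frame (positive
#'   probability, class not in {target, Developed}, unconverted, in
#'   county).
#' @param n seeding sample size.
#' @return list `cell` (row, col), `index` (linear), `prob`; or `NULL`
#'   when no cell is eligible (the caller records shortfall).
#' @export
select_seed <- function(gen_prob, eligible, n) {
  frame <- which(eligible)
  if (!length(frame)) return(NULL)
  draws <- sample_vec(frame, size = min(n, length(frame)))
  p <- gen_prob[draws]
  best <- draws[p == max(p)]
  pick <- sample_vec(best, 1L)
  rc <- arrayInd(pick, dim(gen_prob))
  list(cell = c(rc[1, 1], rc[1, 2]), index = pick, prob = gen_prob[pick])
}

#' Build the patch window around a seed
#'
#' The k x k square of cells within annular distance r = (k-1)/2 of the
#' seed, clipped to the seed's county and the study area. Candidate cells
#' are those whose current class is neither the target nor Developed (nor
#' Water, which never donates) and whose generalized probability of
#' converting to the target is positive.
#'
#' @param seed_cell integer (row, col) of the seed.
#' @param k odd patch size (cells).
#' @param county_mask logical matrix: cells of the seed's county.
#' @param values current class-code matrix.
#' @param gen_prob generalized-probability matrix for the target class.
#' @param target target class letter.
#' @return list with `cells` (m x 2 row/col), `dist`, `prob`, `candidate`
#'   flags, and `r`.
#' @export
build_patch_window <- function(seed_cell, k, county_mask, values, gen_prob,
                               target) {
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 1L) stop("k must be odd and >= 1")
  r <- (k - 1L) %/% 2L
  nr <- nrow(values)
  nc <- ncol(values)
  rows <- max(1L, seed_cell[1] - r):min(nr, seed_cell[1] + r)
  cols <- max(1L, seed_cell[2] - r):min(nc, seed_cell[2] + r)
  cells <- as.matrix(expand.grid(row = rows, col = cols))
  keep <- county_mask[cells] & !is.na(values[cells])
  cells <- cells[keep, , drop = FALSE]
  dist <- pmax(abs(cells[, 1] - seed_cell[1]), abs(cells[, 2] - seed_cell[2]))
  prob <- gen_prob[cells]
  cls <- values[cells]
  candidate <- !(cls %in% class_code(c(target, "d", "w"))) & prob > 0
  list(cells = cells, dist = dist, prob = prob, candidate = candidate, r = r)
}

#' Distance-modify candidate probabilities
#'
#' Adds `(1 - dist/r) * (1 - sigma)` to each candidate's generalized
#' probability, where sigma is the population standard deviation of the
#' candidates' probabilities. Near-seed cells are boosted; the boost fades
#' where the probability surface is already informative (large sigma).
#' The scores rank candidates only: they may exceed 1 and are never
#' renormalized. With r = 0 (k = 1) the probabilities pass through
#' unchanged.
#'
#' @param window a patch window from [build_patch_window()].
#' @return numeric vector of scores aligned to the window's candidate
#'   cells.
#' @export
distance_modify <- function(window) {
  p <- window$prob[window$candidate]
  if (!length(p)) return(numeric(0))
  if (window$r == 0L) return(p)
  d <- window$dist[window$candidate]
  sigma <- pop_sd(p)
  p + (1 - d / window$r) * (1 - sigma)
}

#' Convert a patch of cells
#'
#' Visits the window's candidates in descending score order (ties broken
#' by ascending distance to the seed, then row-major cell index) and
#' converts each to the target class while its own donor's quota for the
#' target remains positive, stopping after k conversions. Converted cells
#' take the target class, their probabilities are zeroed so they are
#' removed from every later frame, and their donor's quota is decremented.
#' The realized patch size is min(k, #candidates, available quota) when
#' the window has a single donor class; with mixed donors, spent-quota
#' candidates are skipped rather than truncating the patch.
#'
#' @param window a patch window.
#' @param scores distance-modified scores from [distance_modify()].
#' @param k requested patch size.
#' @param ledger the county's [quota_ledger()].
#' @param target target class letter.
#' @param state environment holding `values` (class codes) and `gen` (the
#'   named list of generalized-probability matrices), both mutated.
#' @return integer vector of linear indices of converted cells.
#' @export
convert_patch <- function(window, scores, k, ledger, target, state) {
  cand <- which(window$candidate)
  if (!length(cand)) return(integer(0))
  dims <- dim(state$values)
  lin <- (window$cells[cand, 2] - 1L) * dims[1] + window$cells[cand, 1]
  ord <- order(-scores, window$dist[cand], lin)
  converted <- integer(0)
  for (j in ord) {
    if (length(converted) >= k) break
    idx <- lin[j]
    donor <- class_label(state$values[idx])
    key <- transition_key(donor, target)
    if (ledger$remaining[key] <= 0L) next
    state$values[idx] <- class_code(target)
    for (l in names(state$gen)) state$gen[[l]][idx] <- 0
    ledger_decrement(ledger, key)
    converted <- c(converted, idx)
  }
  converted
}

#' Allocate one county's quotas
#'
#' For each target class in the configured order, repeats
#' seed-sample-grow until the class's quotas (summed over donors) are
#' spent: select a seed among eligible cells, draw an odd patch size from
#' the (seed donor, target) patch model, build the annular window, rank
#' candidates by distance-modified probability, convert under the quota
#' constraint. Seed failure (no eligible cells) or `max_failed_seeds`
#' consecutive zero-conversion seeds abandons the class and records the
#' unmet quota as shortfall. Non-converted cells keep their time-1 class;
#' Developed and Water cells never change.
#'
#' @param state environment with `values` and `gen`, mutated in place
#'   (see [allocate_all()] for the usual entry point).
#' @param county_mask logical matrix of the county's cells.
#' @param ledger the county's [quota_ledger()].
#' @param patch_models named list from [fit_patch_models()].
#' @param config a [seeding_config()].
#' @return an allocation report: list with per-key `converted`,
#'   `shortfall`, `seeds_drawn`, `patches_placed`.
#' @export
allocate_county <- function(state, county_mask, ledger, patch_models, config) {
  seeds_drawn <- 0L
  patches_placed <- 0L
  fallback <- fit_patch_distribution(integer(), county = ledger$county)
  for (target in config$target_class_order) {
    keys <- allowed_keys()
    keys <- keys[split_key(keys)$target == target]
    failed <- 0L
    repeat {
      if (sum(ledger$remaining[keys]) <= 0L) break
      eligible <- county_mask & state$gen[[target]] > 0 &
        !is.na(state$values) &
        !(state$values %in% class_code(c(target, "d", "w")))
      sel <- select_seed(state$gen[[target]], eligible, config$n)
      if (is.null(sel)) {
        for (key in keys) {
          ledger_record_shortfall(ledger, key, ledger$remaining[key])
        }
        break
      }
      seeds_drawn <- seeds_drawn + 1L
      donor <- class_label(state$values[sel$index])
      pm_key <- paste0(ledger$county, "|", transition_key(donor, target))
      model <- patch_models[[pm_key]] %||% fallback
      k <- sample_patch_size(model)
      window <- build_patch_window(sel$cell, k, county_mask, state$values,
                                   state$gen[[target]], target)
      scores <- distance_modify(window)
      done <- convert_patch(window, scores, k, ledger, target, state)
      if (length(done)) {
        patches_placed <- patches_placed + 1L
        failed <- 0L
      } else {
        failed <- failed + 1L
        if (failed >= config$max_failed_seeds) {
          for (key in keys) {
            ledger_record_shortfall(ledger, key, ledger$remaining[key])
          }
          break
        }
      }
    }
  }
  list(county = ledger$county,
       converted = ledger_converted(ledger),
       shortfall = ledger$shortfall,
       seeds_drawn = seeds_drawn,
       patches_placed = patches_placed,
       n = config$n)
}

#' Allocate all county quotas over a landscape
#'
#' Runs [allocate_county()] for every county. Counties are independent
#' (windows never cross county lines) and each county's RNG stream is
#' derived from `(config$seed, county id)`, so the processing order never
#' affects the result and identical inputs and seed give a bit-identical
#' output grid.
#'
#' @param t1 time-1 [lu_grid()].
#' @param counties a [county_partition()].
#' @param stack a `prob_stack` for `t1`.
#' @param ledgers named list of [quota_ledger()]s (one per county;
#'   counties absent from the list are left unchanged).
#' @param patch_models named list from [fit_patch_models()].
#' @param config a [seeding_config()].
#' @return list with `t2` (the realized [lu_grid()]) and `reports` (one
#'   allocation report per county).
#' @export
allocate_all <- function(t1, counties, stack, ledgers, patch_models, config) {
  check_alignment(t1, counties)
  state <- new.env(parent = emptyenv())
  state$values <- t1$values
  state$gen <- stack$generalized
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  reports <- list()
  for (cid in names(ledgers)) {
    if (!cid %in% counties$county_ids) {
      stop("ledger for unknown county: ", cid)
    }
    county_mask <- !is.na(counties$labels) & counties$labels == cid
    county_mask[is.na(county_mask)] <- FALSE
    set.seed(derive_seed(config$seed, cid))
    reports[[cid]] <- allocate_county(state, county_mask, ledgers[[cid]],
                                      patch_models, config)
  }
  t2 <- lu_grid(state$values, cell_size = t1$cell_size, origin = t1$origin)
  list(t2 = t2, reports = reports)
}

#' Flatten allocation reports to a table
#'
#' @param reports `reports` element of [allocate_all()]'s result.
#' @return data.frame `county, donor, target, initial, converted,
#'   shortfall`.
#' @export
allocation_report_table <- function(reports) {
  rows <- lapply(reports, function(rep) {
    keys <- names(rep$converted)
    ks <- split_key(keys)
    data.frame(county = rep$county, donor = ks$donor, target = ks$target,
               initial = unname(rep$converted + rep$shortfall),
               converted = unname(rep$converted),
               shortfall = unname(rep$shortfall),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$initial > 0 | out$converted > 0 | out$shortfall > 0, ]
}
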