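# Synthetic landscapes, predictor stacks, reference grid pairs and quota
# tables with controlled spatial structure, so the whole pipeline is
# testable without any external data.

neighbors4 <- function(idx, nr, nc) {
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  if (row > 1L) out <- c(out, idx - 1L)
  if (row < nr) out <- c(out, idx + 1L)
  if (col > 1L) out <- c(out, idx - nr)
  if (col < nc) out <- c(out, idx + nr)
  out
}

neighbors8 <- function(idx, nr, nc) {
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  rows <- max(1L, row - 1L):min(nr, row + 1L)
  cols <- max(1L, col - 1L):min(nc, col + 1L)
  out <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
  out[out != idx]
}

# 3x3 maximum filter iterated r times = Chebyshev-ball dilation of radius r.
max_filter <- function(m, r) {
  for (i in seq_len(r)) {
    nr <- nrow(m)
    nc <- ncol(m)
    p <- matrix(-Inf, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    m <- pmax(p[1:nr, 1:nc], p[1:nr, 2:(nc + 1L)], p[1:nr, 3:(nc + 2L)],
              p[2:(nr + 1L), 1:nc], p[2:(nr + 1L), 2:(nc + 1L)],
              p[2:(nr + 1L), 3:(nc + 2L)],
              p[3:(nr + 2L), 1:nc], p[3:(nr + 2L), 2:(nc + 1L)],
              p[3:(nr + 2L), 3:(nc + 2L)])
  }
  m
}

# Two-pass chamfer transform: Chebyshev distance (in cells) to the nearest
# TRUE cell; Inf when none exists.
chebyshev_distance_to <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  for (col in seq_len(nc)) {
    for (row in seq_len(nr)) {
      v <- d[row, col]
      if (row > 1L) v <- min(v, d[row - 1L, col] + 1)
      if (col > 1L) {
        v <- min(v, d[row, col - 1L] + 1)
        if (row > 1L) v <- min(v, d[row - 1L, col - 1L] + 1)
        if (row < nr) v <- min(v, d[row + 1L, col - 1L] + 1)
      }
      d[row, col] <- v
    }
  }
  for (col in rev(seq_len(nc))) {
    for (row in rev(seq_len(nr))) {
      v <- d[row, col]
      if (row < nr) v <- min(v, d[row + 1L, col] + 1)
      if (col < nc) {
        v <- min(v, d[row, col + 1L] + 1)
        if (row < nr) v <- min(v, d[row + 1L, col + 1L] + 1)
        if (row > 1L) v <- min(v, d[row - 1L, col + 1L] + 1)
      }
      d[row, col] <- v
    }
  }
  d
}

place_classes <- function(nr, nc, mixture, clumpiness) {
  n <- nr * nc
  frac <- mixture / sum(mixture)
  counts <- floor(frac * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(frac * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  counts <- counts[counts > 0]
  classes <- names(counts)
  if (clumpiness <= 0) {
    lab <- sample(rep(class_code(classes), counts))
    return(matrix(lab, nr, nc))
  }
  assign_m <- integer(n)
  need <- as.integer(counts)
  names(need) <- classes
  frontier <- vector("list", length(classes))
  names(frontier) <- classes
  # seed count per class interpolates random (every cell a seed) ... clumped
  for (cl in classes) {
    k <- max(1L, as.integer(round(need[cl] * (1 - clumpiness))))
    free <- which(assign_m == 0L)
    seeds <- sample_vec(free, min(k, need[cl]))
    assign_m[seeds] <- class_code(cl)
    frontier[[cl]] <- seeds
    need[cl] <- need[cl] - length(seeds)
  }
  while (sum(need) > 0L) {
    live <- names(need)[need > 0L]
    cl <- if (length(live) == 1L) live else
      sample(live, 1L, prob = need[live])
    grown <- FALSE
    while (length(frontier[[cl]])) {
      j <- sample.int(length(frontier[[cl]]), 1L)
      cell <- frontier[[cl]][j]
      nb <- neighbors4(cell, nr, nc)
      nb <- nb[assign_m[nb] == 0L]
      if (!length(nb)) {
        frontier[[cl]] <- frontier[[cl]][-j]
        next
      }
      new <- sample_vec(nb, 1L)
      assign_m[new] <- class_code(cl)
      frontier[[cl]] <- c(frontier[[cl]], new)
      need[cl] <- need[cl] - 1L
      grown <- TRUE
      break
    }
    if (!grown) {
      free <- which(assign_m == 0L)
      new <- sample_vec(free, 1L)
      assign_m[new] <- class_code(cl)
      frontier[[cl]] <- new
      need[cl] <- need[cl] - 1L
    }
  }
  matrix(assign_m, nr, nc)
}

smooth_field <- function(nr, nc, n_bumps = 4L, base = 100) {
  f <- matrix(base, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n_bumps)) {
    cr <- stats::runif(1, 1, nr)
    cc <- stats::runif(1, 1, nc)
    amp <- stats::runif(1, 20, 120)
    sg <- stats::runif(1, 0.1, 0.35) * max(nr, nc)
    f <- f + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
  }
  f
}

#' Generate a synthetic landscape
#'
#' Places the five land-use classes by seeded region growing so that the
#' realized class mixture matches the requested fractions exactly (up to
#' rounding) and the spatial clumping is tunable: `clumpiness = 0` gives
#' spatially independent labels, values near 1 give large contiguous
#' patches. Counties are a rectangular tiling. Predictors are synthesized
#' to echo their real counterparts: a smooth elevation field with its
#' slope magnitude (max-filtered at 3/9/27), a smooth wetness-index
#' stand-in, Chebyshev distance to the nearest Water cell, a random
#' rectangular protection mask, focal class percents computed (not
#' simulated) from the generated grid, and the class code itself.
#'
#' @param shape integer (rows, cols).
#' @param county_grid integer (county rows, county cols): counties tile
#'   the landscape in rectangles.
#' @param mixture named fractions per class letter, summing to 1.
#' @param clumpiness patch-growth intensity in `[0, 1]`.
#' @param seed RNG seed; everything is deterministic given it.
#' @param n_groupings,n_regions number of model groupings / reporting
#'   regions, assigned to counties in contiguous blocks.
#' @param cell_size cell edge in meters.
#' @return list with `grid` ([lu_grid()]), `counties`
#'   ([county_partition()]), `predictors` (named list of matrices).
#' @export
generate_landscape <- function(shape = c(60L, 60L), county_grid = c(2L, 2L),
                               mixture = c(d = 0.08, f = 0.5, a = 0.25,
                                           w = 0.05, o = 0.12),
                               clumpiness = 0.7, seed = 1L,
                               n_groupings = 1L, n_regions = 1L,
                               cell_size = 90) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  if (clumpiness < 0 || clumpiness > 1) stop("clumpiness must be in [0, 1]")
  nr <- shape[1]
  nc <- shape[2]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  values <- place_classes(nr, nc, mixture, clumpiness)
  grid <- lu_grid(values, cell_size = cell_size)
  # rectangular county tiling
  blocks <- function(n, k) {
    if (k <= 1L) rep(1L, n) else cut(seq_len(n), k, labels = FALSE)
  }
  rband <- blocks(nr, county_grid[1])
  cband <- blocks(nc, county_grid[2])
  labels <- matrix(sprintf("c%02d", (matrix(rband, nr, nc) - 1L) * county_grid[2] +
                             matrix(cband, nr, nc, byrow = TRUE)), nr, nc)
  ids <- sort(unique(as.vector(labels)))
  grouping_of <- stats::setNames(
    sprintf("g%d", blocks(length(ids), n_groupings)), ids)
  region_of <- stats::setNames(
    sprintf("r%d", blocks(length(ids), n_regions)), ids)
  counties <- county_partition(labels, grouping_of, region_of)
  # predictors
  elev <- smooth_field(nr, nc)
  dx <- elev - elev[c(1L, seq_len(nr - 1L)), ]
  dy <- elev - elev[, c(1L, seq_len(nc - 1L))]
  slope <- sqrt(dx^2 + dy^2)
  water <- values == class_code("w")
  dwat <- chebyshev_distance_to(water)
  dwat[is.infinite(dwat)] <- sqrt(nr^2 + nc^2)
  prot <- matrix(0, nr, nc)
  for (i in seq_len(3L)) {
    r0 <- sample.int(nr, 1L)
    c0 <- sample.int(nc, 1L)
    prot[r0:min(nr, r0 + nr %/% 6L), c0:min(nc, c0 + nc %/% 6L)] <- 1
  }
  predictors <- list(
    elevation = elev,
    slope_3 = max_filter(slope, 1L),
    slope_9 = max_filter(slope, 4L),
    slope_27 = max_filter(slope, 13L),
    cti_3 = smooth_field(nr, nc, n_bumps = 3L, base = 6),
    cti_9 = smooth_field(nr, nc, n_bumps = 3L, base = 6),
    cti_27 = smooth_field(nr, nc, n_bumps = 3L, base = 6),
    dist_water = dwat * cell_size,
    protected = prot,
    t1_class = values * 1
  )
  for (cl in LU_LABELS) {
    for (w in c(3L, 9L, 27L)) {
      predictors[[sprintf("pct_%s_%d", cl, w)]] <-
        compute_focal_percent(grid, cl, w)
    }
  }
  list(grid = grid, counties = counties, predictors = predictors)
}

#' Plant known transition patches between two dates
#'
#' Builds a time-2 grid from a time-1 grid by planting connected change
#' patches with known sizes, and returns the exact truth table of what
#' was planted, so recovery tests never re-derive truth from the code
#' paths under test. Patches of the same transition are kept at Chebyshev
#' distance >= 2 from one another so they never merge under
#' 8-connectivity; growth is confined to donor-class cells of one county.
#'
#' @param t1 a [lu_grid()].
#' @param counties a [county_partition()].
#' @param change data.frame with columns `county, donor, target,
#'   n_patches` and either `fixed_size` (every patch that size) or
#'   `nb_size, nb_mu` (sizes drawn as NB + 1).
#' @param seed RNG seed.
#' @return list with `t1`, `t2` ([lu_grid()]), `truth` (data.frame
#'   `county, donor, target, patch_id, size` of realized patches).
#' @export
generate_reference_pair <- function(t1, counties, change, seed = 1L) {
  check_alignment(t1, counties)
  bad <- !is_allowed(change$donor, change$target) |
    change$donor == change$target
  if (any(bad)) stop("change recipe contains disallowed transitions")
  nr <- nrow(t1$values)
  nc <- ncol(t1$values)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t2v <- t1$values
  keymat <- list()  # per transition key: matrix of patch ids
  truth <- list()
  for (i in seq_len(nrow(change))) {
    rw <- change[i, ]
    key <- transition_key(rw$donor, rw$target)
    if (is.null(keymat[[key]])) keymat[[key]] <- matrix(0L, nr, nc)
    km <- keymat[[key]]
    donor_code <- class_code(rw$donor)
    in_county <- !is.na(counties$labels) & counties$labels == rw$county
    in_county[is.na(in_county)] <- FALSE
    next_id <- max(km) + 1L
    for (p in seq_len(rw$n_patches)) {
      want <- if (!is.null(rw$fixed_size) && !is.na(rw$fixed_size)) {
        as.integer(rw$fixed_size)
      } else {
        stats::rnbinom(1L, size = rw$nb_size, mu = rw$nb_mu) + 1L
      }
      ok_cell <- function(idx) {
        nb <- neighbors8(idx, nr, nc)
        all(km[nb] == 0L | km[nb] == next_id)
      }
      free <- which(in_county & t1$values == donor_code & t2v == t1$values &
                      km == 0L)
      free <- free[vapply(free, ok_cell, TRUE)]
      if (!length(free)) break
      seed_cell <- sample_vec(free, 1L)
      patch <- seed_cell
      km[seed_cell] <- next_id
      while (length(patch) < want) {
        cand <- unique(unlist(lapply(patch, neighbors8, nr = nr, nc = nc)))
        keep <- in_county[cand] & !is.na(t1$values[cand]) &
          t1$values[cand] == donor_code &
          t2v[cand] == t1$values[cand] & km[cand] == 0L
        cand <- cand[which(keep)]
        cand <- cand[vapply(cand, ok_cell, TRUE)]
        if (!length(cand)) break
        new <- sample_vec(cand, 1L)
        km[new] <- next_id
        patch <- c(patch, new)
      }
      t2v[patch] <- class_code(rw$target)
      truth[[length(truth) + 1L]] <- data.frame(
        county = rw$county, donor = rw$donor, target = rw$target,
        patch_id = next_id, size = length(patch), stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
    keymat[[key]] <- km
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(county = character(), donor = character(),
               target = character(), patch_id = integer(), size = integer())
  list(t1 = t1,
       t2 = lu_grid(t2v, cell_size = t1$cell_size, origin = t1$origin),
       truth = truth_df)
}

#' Generate feasible quota tables from a landscape
#'
#' Sets each county's quota to `round(intensity * donor-class cell
#' count)` per allowed non-self transition, then rescales any donor whose
#' total outgoing quota would exceed 80% of its supply, guaranteeing a
#' feasibility margin.
#'
#' @param t1 a [lu_grid()].
#' @param counties a [county_partition()].
#' @param intensity named fractions in `[0, 1)` keyed by transition key
#'   (e.g. `c("f->d" = 0.1)`), or a single unnamed fraction applied to
#'   every allowed non-self transition.
#' @return data.frame `county, donor, target, cells`.
#' @export
generate_quotas <- function(t1, counties, intensity) {
  if (is.null(names(intensity))) {
    intensity <- stats::setNames(rep(intensity, length(allowed_keys())),
                                 allowed_keys())
  }
  if (any(intensity < 0 | intensity >= 1)) stop("intensities must be in [0, 1)")
  ks <- split_key(names(intensity))
  if (!all(is_allowed(ks$donor, ks$target)) || any(ks$donor == ks$target)) {
    stop("intensity keys must be allowed non-self transitions")
  }
  rows <- list()
  for (cid in counties$county_ids) {
    in_county <- !is.na(counties$labels) & counties$labels == cid
    supply <- stats::setNames(
      vapply(LU_LABELS, function(cl) {
        sum(t1$values[in_county] == class_code(cl), na.rm = TRUE)
      }, 0), LU_LABELS)
    q <- floor(intensity * supply[ks$donor] + 0.5)
    for (m in unique(ks$donor)) {
      tot <- sum(q[ks$donor == m])
      cap <- floor(0.8 * supply[m])
      if (tot > cap && tot > 0) {
        q[ks$donor == m] <- floor(q[ks$donor == m] * cap / tot)
      }
    }
    rows[[cid]] <- data.frame(county = cid, donor = ks$donor,
                              target = ks$target, cells = as.integer(q),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
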