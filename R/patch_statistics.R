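# Observed transition patches and per-(county, transition) patch-size
# models. Patch sizes are modelled with a negative binomial shifted to
# support >= 1; counties with no observed patches fall back to size-1
# patches.

# Two-pass union-find connected-component labelling of a logical matrix.
# connectivity 8 joins diagonal neighbours (the default: the allocator's
# square windows produce diagonal adjacency); 4 is available for
# sensitivity checks.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (col in seq_len(nc)) {
    for (row in seq_len(nr)) {
      if (!mask[row, col]) next
      nb <- integer(0)
      if (row > 1L && mask[row - 1L, col]) nb <- c(nb, labels[row - 1L, col])
      if (col > 1L && mask[row, col - 1L]) nb <- c(nb, labels[row, col - 1L])
      if (connectivity == 8L && col > 1L) {
        if (row > 1L && mask[row - 1L, col - 1L]) {
          nb <- c(nb, labels[row - 1L, col - 1L])
        }
        if (row < nr && mask[row + 1L, col - 1L]) {
          nb <- c(nb, labels[row + 1L, col - 1L])
        }
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[row, col] <- nxt
      } else {
        roots <- vapply(nb, find, 0L)
        keep <- min(roots)
        labels[row, col] <- keep
        for (rt in roots) parent[rt] <- keep
      }
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, 0L)
  compact <- match(roots, sort(unique(roots)))
  pos <- which(labels > 0L)
  labels[pos] <- compact[labels[pos]]
  labels
}

#' Extract observed transition patches
#'
#' Finds, for each county and each allowed donor-to-target pair with
#' donor != target, the connected components (8-connectivity by default)
#' of cells that changed from donor to target between two aligned grids.
#' Components are county-scoped: change straddling a county line is split.
#' Disallowed changes are counted and reported in the `ignored` attribute
#' but not tabulated.
#'
#' @param t1,t2 aligned [lu_grid()]s.
#' @param counties a [county_partition()].
#' @param connectivity 8 (default) or 4.
#' @return data.frame `county, donor, target, patch_id, size`; attribute
#'   `ignored` = count of changed cells on disallowed pairs.
#' @export
extract_transition_patches <- function(t1, t2, counties, connectivity = 8L) {
  if (!identical(dim(t1$values), dim(t2$values))) {
    stop("t1 and t2 have different shapes")
  }
  check_alignment(t1, counties)
  changed <- !is.na(t1$values) & !is.na(t2$values) & t1$values != t2$values
  idx <- which(changed)
  ignored <- 0L
  rows <- list()
  if (length(idx)) {
    d <- class_label(t1$values[idx])
    tg <- class_label(t2$values[idx])
    ok <- is_allowed(d, tg)
    ignored <- sum(!ok)
    combos <- unique(data.frame(county = counties$labels[idx[ok]],
                                donor = d[ok], target = tg[ok],
                                stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combos))) {
      cc <- combos[i, ]
      mask <- changed &
        t1$values == class_code(cc$donor) &
        t2$values == class_code(cc$target) &
        !is.na(counties$labels) & counties$labels == cc$county
      mask[is.na(mask)] <- FALSE
      lab <- label_components(mask, connectivity)
      if (max(lab) == 0L) next
      sizes <- tabulate(lab[lab > 0L])
      rows[[length(rows) + 1L]] <- data.frame(
        county = cc$county, donor = cc$donor, target = cc$target,
        patch_id = seq_along(sizes), size = sizes,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(county = character(), donor = character(),
               target = character(), patch_id = integer(), size = integer(),
               stringsAsFactors = FALSE)
  attr(out, "ignored") <- ignored
  out
}

#' Fit a patch-size distribution
#'
#' Fits a negative binomial to observed patch sizes shifted by -1 (so size
#' 1 carries positive mass), after appending a single size-1
#' pseudo-observation (configurable; applied to every table so that
#' counties with sparse observations still admit small patches). An empty
#' multiset yields the fallback model whose samples are always 1.
#' Underdispersed samples (variance <= mean after shifting) get a Poisson
#' fit; an all-equal sample becomes a point mass. Maximum likelihood with
#' method-of-moments initialization.
#'
#' @param sizes integer vector of patch sizes (cells, >= 1).
#' @param county,transition identifiers stored on the model.
#' @param add_pseudo append the size-1 pseudo-observation (default TRUE).
#' @return an object of class `patch_size_model`.
#' @export
fit_patch_distribution <- function(sizes, county = NA_character_,
                                   transition = NA_character_,
                                   add_pseudo = TRUE) {
  if (length(sizes) && any(sizes < 1 | sizes != round(sizes))) {
    stop("patch sizes must be positive integers")
  }
  mk <- function(dist, params, fallback = FALSE, n_obs = length(sizes)) {
    structure(list(county = county, transition = transition,
                   dist = dist, params = params,
                   fitted_on = n_obs, fallback = fallback),
              class = "patch_size_model")
  }
  if (!length(sizes)) {
    return(mk("fallback", list(), fallback = TRUE, n_obs = 0L))
  }
  if (add_pseudo) sizes <- c(sizes, 1L)
  x <- as.numeric(sizes) - 1
  mu <- mean(x)
  v <- stats::var(x)
  if (length(unique(x)) == 1L) {
    return(mk("point", list(value = unique(sizes))))
  }
  if (v <= mu || mu == 0) {
    return(mk("poisson", list(lambda = mu)))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "negative binomial")),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$estimate["size"]) &&
      fit$estimate["size"] > 0) {
    size <- unname(fit$estimate["size"])
    mu_hat <- unname(fit$estimate["mu"])
  } else {
    size <- mu^2 / (v - mu)  # method of moments
    mu_hat <- mu
  }
  mk("nbinom", list(size = size, mu = mu_hat,
                    prob = size / (size + mu_hat)))
}

#' @export
print.patch_size_model <- function(x, ...) {
  cat(sprintf("<patch_size_model> %s %s: %s, fitted on %d patch(es)\n",
              x$county, x$transition, x$dist, x$fitted_on))
  invisible(x)
}

#' Mean patch size implied by a model
#'
#' Mean of the fitted distribution on the original (>= 1) support, before
#' odd-rounding.
#'
#' @param model a `patch_size_model`.
#' @return numeric scalar.
#' @export
patch_model_mean <- function(model) {
  switch(model$dist,
         fallback = 1,
         point = model$params$value,
         poisson = model$params$lambda + 1,
         nbinom = model$params$mu + 1)
}

#' Sample a patch size
#'
#' Draws from the fitted distribution (shifted back to support >= 1); even
#' draws are adjusted upward by one so every returned size is odd, which
#' gives the allocator a centered square window of radius (k-1)/2.
#'
#' @param model a `patch_size_model`.
#' @param n_draws number of sizes to draw.
#' @return integer vector of odd sizes >= 1.
#' @export
sample_patch_size <- function(model, n_draws = 1L) {
  raw <- switch(model$dist,
                fallback = rep(1L, n_draws),
                point = rep(as.integer(model$params$value), n_draws),
                poisson = stats::rpois(n_draws, model$params$lambda) + 1L,
                nbinom = stats::rnbinom(n_draws, size = model$params$size,
                                        mu = model$params$mu) + 1L)
  even <- raw %% 2L == 0L
  raw[even] <- raw[even] + 1L
  raw
}

#' Fit patch-size models for every (county, transition) table
#'
#' @param patches output of [extract_transition_patches()].
#' @param counties optional [county_partition()]; when given, every
#'   (county, allowed non-self transition) combination receives a model,
#'   using the fallback for unobserved combinations.
#' @param add_pseudo passed to [fit_patch_distribution()].
#' @return named list of `patch_size_model` keyed `"<county>|<donor>-><target>"`.
#' @export
fit_patch_models <- function(patches, counties = NULL, add_pseudo = TRUE) {
  out <- list()
  if (nrow(patches)) {
    by <- split(patches$size,
                paste0(patches$county, "|",
                       transition_key(patches$donor, patches$target)))
    for (key in names(by)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      out[[key]] <- fit_patch_distribution(by[[key]], county = parts[1],
                                           transition = parts[2],
                                           add_pseudo = add_pseudo)
    }
  }
  if (!is.null(counties)) {
    for (cid in counties$county_ids) {
      for (tk in allowed_keys()) {
        key <- paste0(cid, "|", tk)
        if (is.null(out[[key]])) {
          out[[key]] <- fit_patch_distribution(integer(), county = cid,
                                               transition = tk)
        }
      }
    }
  }
  out
}

#' Write fitted patch models to JSON
#'
#' @param models list from [fit_patch_models()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_patch_models <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(county = m$county, transition = m$transition, dist = m$dist,
         params = m$params, fitted_on = m$fitted_on, fallback = m$fallback)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted patch models from JSON
#'
#' @param path JSON written by [write_patch_models()].
#' @return named list of `patch_size_model`.
#' @export
read_patch_models <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- lapply(recs, function(r) {
    structure(list(county = r$county, transition = r$transition,
                   dist = r$dist, params = lapply(r$params, as.numeric),
                   fitted_on = r$fitted_on, fallback = isTRUE(r$fallback)),
              class = "patch_size_model")
  })
  stats::setNames(out, names(recs))
}
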