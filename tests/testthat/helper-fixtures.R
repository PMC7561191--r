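# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (double loops, BFS) and share no code with the
# implementation paths they check.

grid_from_rows <- function(rows, cell_size = 90) {
  chars <- strsplit(rows, "")
  m <- t(vapply(chars, function(x) x, character(nchar(rows[1]))))
  m[m == "."] <- NA_character_
  lu_grid(matrix(m, nrow = length(rows)), cell_size = cell_size)
}

single_county <- function(grid, id = "c1") {
  labels <- matrix(id, nrow(grid$values), ncol(grid$values))
  labels[is.na(grid$values)] <- NA_character_
  county_partition(labels)
}

# constant-probability stack: every allowed non-self transition gets the
# given probability everywhere (before donor masking)
uniform_stack <- function(t1, p = 0.5, keys = allowed_keys()) {
  dims <- dim(t1$values)
  layers <- lapply(keys, function(k) matrix(p, dims[1], dims[2]))
  names(layers) <- keys
  probability_stack(layers, t1)
}

random_grid <- function(nr, nc, seed, p_bg = 0.1,
                        classes = c("d", "f", "a", "w", "o")) {
  set.seed(seed)
  m <- matrix(sample(classes, nr * nc, replace = TRUE), nr, nc)
  m[matrix(runif(nr * nc) < p_bg, nr, nc)] <- NA_character_
  lu_grid(m)
}

# brute-force focal percent: explicit double loop over cells and windows
oracle_focal_percent <- function(grid, class, window) {
  code <- seedalloc::class_code(class)
  r <- (window - 1) / 2
  v <- grid$values
  nr <- nrow(v)
  nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (row in seq_len(nr)) {
    for (col in seq_len(nc)) {
      if (is.na(v[row, col])) next
      hits <- 0L
      tot <- 0L
      for (rr in max(1, row - r):min(nr, row + r)) {
        for (cc in max(1, col - r):min(nc, col + r)) {
          if (!is.na(v[rr, cc])) {
            tot <- tot + 1L
            if (v[rr, cc] == code) hits <- hits + 1L
          }
        }
      }
      out[row, col] <- 100 * hits / tot
    }
  }
  out
}

# BFS flood-fill patch sizes per (county, donor, target); independent of
# the union-find labelling used by the package
oracle_patch_sizes <- function(t1, t2, counties, connectivity = 8) {
  v1 <- t1$values
  v2 <- t2$values
  nr <- nrow(v1)
  nc <- ncol(v1)
  seen <- matrix(FALSE, nr, nc)
  res <- list()
  for (row in seq_len(nr)) {
    for (col in seq_len(nc)) {
      if (seen[row, col] || is.na(v1[row, col]) || is.na(v2[row, col])) next
      if (v1[row, col] == v2[row, col]) next
      donor <- class_label(v1[row, col])
      target <- class_label(v2[row, col])
      if (!is_allowed(donor, target)) {
        seen[row, col] <- TRUE
        next
      }
      cid <- counties$labels[row, col]
      queue <- list(c(row, col))
      seen[row, col] <- TRUE
      size <- 0L
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        size <- size + 1L
        for (dr in -1:1) {
          for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            if (connectivity == 4 && abs(dr) + abs(dc) == 2) next
            r2 <- cur[1] + dr
            c2 <- cur[2] + dc
            if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
            if (seen[r2, c2]) next
            if (is.na(v1[r2, c2]) || is.na(v2[r2, c2])) next
            if (v1[r2, c2] != class_code(donor)) next
            if (v2[r2, c2] != class_code(target)) next
            if (is.na(counties$labels[r2, c2]) ||
                counties$labels[r2, c2] != cid) next
            seen[r2, c2] <- TRUE
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
      key <- paste(cid, donor, target, sep = "|")
      res[[key]] <- c(res[[key]], size)
    }
  }
  res
}

# brute-force fragmentation tally over forest cells, one window
oracle_frag_tally <- function(grid, counties, window) {
  pf <- oracle_focal_percent(grid, "f", window)
  v <- grid$values
  out <- list()
  for (row in seq_len(nrow(v))) {
    for (col in seq_len(ncol(v))) {
      if (is.na(v[row, col]) || v[row, col] != class_code("f")) next
      p <- pf[row, col]
      cls <- if (p >= 90) "Interior" else if (p >= 60) "Dominant" else
        if (p >= 40) "Transitional" else if (p >= 10) "Patchy" else "Rare"
      rg <- counties$region_of[counties$labels[row, col]]
      key <- paste(window, rg, cls, sep = "|")
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
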