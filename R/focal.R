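# Focal (moving-window) statistics on land-use grids.

# Sliding-window sum of a numeric matrix over (2r+1)x(2r+1) windows clipped
# at the matrix edge, via a padded summed-area table. O(cells), exact for
# integer contents.
box_sum <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  colcs <- if (nr == 1L) m else apply(m, 2L, cumsum)
  sat <- if (nc == 1L) colcs else t(apply(colcs, 1L, cumsum))
  cs <- matrix(0, nr + 1L, nc + 1L)
  cs[-1L, -1L] <- sat
  r1 <- pmax(seq_len(nr) - r, 1L)
  r2 <- pmin(seq_len(nr) + r, nr)
  c1 <- pmax(seq_len(nc) - r, 1L)
  c2 <- pmin(seq_len(nc) + r, nc)
  cs[r2 + 1L, c2 + 1L, drop = FALSE] - cs[r1, c2 + 1L, drop = FALSE] -
    cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
}

#' Percent of a land-use class in a centered focal window
#'
#' For each non-background cell, the percentage of the given class among
#' the non-background cells of the centered `window` x `window` square.
#' Windows are clipped at the grid edge and at the study-area boundary:
#' only in-study-area cells enter the denominator (no zero padding), so a
#' cell at the border is scored against its real neighbourhood. Water
#' cells count in the denominator; they are part of the landscape.
#'
#' @param grid an [lu_grid()].
#' @param class class letter (e.g. `"f"` for Forest).
#' @param window odd window edge length in cells (1, 3, 9, 27, ...).
#' @return numeric matrix of percents in `[0, 100]`; `NA` on background.
#' @export
compute_focal_percent <- function(grid, class, window = 3L) {
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be an odd positive integer")
  }
  code <- class_code(class)
  r <- (window - 1L) %/% 2L
  inside <- !is.na(grid$values)
  hits <- (inside & grid$values == code) * 1
  denom <- box_sum(inside * 1, r)
  num <- box_sum(hits, r)
  out <- 100 * num / pmax(denom, 1)
  out[!inside] <- NA_real_
  out
}
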