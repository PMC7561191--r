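# Core data model: categorical land-use grids, county partitions, the
# allowed-transition table and county quota ledgers.

#' Land-use class codes
#'
#' The package works with five land-use classes plus a background state.
#' Classes are stored internally as integers 1..5; background cells are
#' `NA`. The single-letter labels `d` (Developed), `f` (Forest),
#' `a` (Agriculture), `w` (Water) and `o` (Other) are used throughout the
#' user-facing interface.
#'
#' @format A named integer vector mapping letter label to internal code.
#' @export
LU_CLASSES <- c(d = 1L, f = 2L, a = 3L, w = 4L, o = 5L)

#' @rdname LU_CLASSES
#' @export
LU_LABELS <- names(LU_CLASSES)

#' Convert class letters to internal codes
#'
#' @param x character vector of class letters (`d`, `f`, `a`, `w`, `o`).
#' @return integer vector of internal codes.
#' @export
class_code <- function(x) {
  out <- unname(LU_CLASSES[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(match(x, LU_LABELS))])
    stop("unknown land-use class label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Convert internal codes to class letters
#'
#' Background (`NA`) codes map to `NA`.
#'
#' @param x integer vector of internal codes.
#' @return character vector of class letters.
#' @export
class_label <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok & (x < 1L | x > 5L))) {
    stop("unknown land-use class code(s): ",
         paste(unique(x[ok & (x < 1L | x > 5L)]), collapse = ", "))
  }
  out[ok] <- LU_LABELS[x[ok]]
  out
}

#' Construct a land-use grid
#'
#' A land-use grid is an integer matrix of class codes with `NA` marking
#' background (out-of-study-area) cells, plus the cell size in meters and
#' the map coordinates of the upper-left corner. Cell addressing is 0-based
#' `(row, col)` with row 0 at the top, shared by every module.
#'
#' @param values integer matrix of class codes (1..5, `NA` = background),
#'   or a character matrix of class letters.
#' @param cell_size cell edge length in meters (default 90).
#' @param origin numeric length-2, map x/y of the upper-left corner.
#' @return an object of class `lu_grid`.
#' @export
lu_grid <- function(values, cell_size = 90, origin = c(0, 0)) {
  if (is.character(values)) {
    dims <- dim(values)
    values <- matrix(ifelse(is.na(values), NA_integer_, class_code_safe(values)),
                     nrow = dims[1], ncol = dims[2])
  }
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & (values < 1L | values > 5L)
  if (any(bad)) {
    stop("unknown land-use class value(s): ",
         paste(unique(values[bad]), collapse = ", "))
  }
  structure(
    list(values = values, cell_size = cell_size, origin = as.numeric(origin)),
    class = "lu_grid"
  )
}

class_code_safe <- function(x) {
  out <- unname(LU_CLASSES[x])
  if (any(is.na(out) & !is.na(x))) {
    stop("unknown land-use class label(s): ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  }
  out
}

#' @export
print.lu_grid <- function(x, ...) {
  counts <- class_counts(x)
  cat(sprintf("<lu_grid> %d x %d cells, %.0f m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat("  counts:", paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
      sprintf("background=%d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lu_grid <- function(x) dim(x$values)

#' Per-class cell counts of a grid
#'
#' @param grid an `lu_grid`.
#' @return named integer vector over the five class letters (background
#'   excluded).
#' @export
class_counts <- function(grid) {
  tab <- tabulate(grid$values[!is.na(grid$values)], nbins = 5L)
  names(tab) <- LU_LABELS
  tab
}

# ---------------------------------------------------------------------------
# ASCII-grid raster I/O. Single band, integer codes, explicit no-data value.

#' Read a land-use grid from an ESRI ASCII raster
#'
#' The no-data value maps to background; any remaining value outside the
#' class-code set raises a format error naming the value.
#'
#' @param path path to an ASCII grid (`ncols/nrows/xllcorner/yllcorner/
#'   cellsize/NODATA_value` header followed by rows of integers).
#' @return an `lu_grid`.
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("ASCII grid body has ", length(vals), " values; expected ",
         hdr$nrows * hdr$ncols)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  bad <- !is.na(m) & !(m %in% 1:5)
  if (any(bad)) {
    stop("unknown land-use class value(s) in ", path, ": ",
         paste(unique(m[bad]), collapse = ", "))
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  lu_grid(m, cell_size = hdr$cellsize,
          origin = c(xll, yll + hdr$nrows * hdr$cellsize))
}

#' Write a land-use grid to an ESRI ASCII raster
#'
#' @param grid an `lu_grid`.
#' @param path output path.
#' @param nodata no-data value written for background cells.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999L) {
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2] - nrow(m) * grid$cell_size),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# County partition

#' Construct a county partition
#'
#' Aligns a matrix of county identifiers to a land-use grid. Every
#' non-background cell must belong to exactly one county. Counties may be
#' assigned to model groupings (shared transition models) and to reporting
#' regions.
#'
#' @param labels matrix of county identifiers (character or integer; `NA` on
#'   background cells).
#' @param grouping_of named vector mapping county id to grouping id
#'   (optional; defaults to one grouping).
#' @param region_of named vector mapping county id to region id (optional;
#'   defaults to one region).
#' @return an object of class `county_partition`.
#' @export
county_partition <- function(labels, grouping_of = NULL, region_of = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  labels <- matrix(as.character(labels), nrow = nrow(labels))
  ids <- sort(unique(labels[!is.na(labels)]))
  if (is.null(grouping_of)) {
    grouping_of <- stats::setNames(rep("g1", length(ids)), ids)
  }
  if (is.null(region_of)) {
    region_of <- stats::setNames(rep("r1", length(ids)), ids)
  }
  if (!all(ids %in% names(grouping_of))) {
    stop("grouping_of is missing counties: ",
         paste(setdiff(ids, names(grouping_of)), collapse = ", "))
  }
  if (!all(ids %in% names(region_of))) {
    stop("region_of is missing counties: ",
         paste(setdiff(ids, names(region_of)), collapse = ", "))
  }
  structure(
    list(labels = labels, county_ids = ids,
         grouping_of = grouping_of[ids], region_of = region_of[ids]),
    class = "county_partition"
  )
}

#' @export
print.county_partition <- function(x, ...) {
  cat(sprintf("<county_partition> %d counties, %d groupings, %d regions\n",
              length(x$county_ids), length(unique(x$grouping_of)),
              length(unique(x$region_of))))
  invisible(x)
}

check_alignment <- function(grid, counties) {
  if (!identical(dim(grid$values), dim(counties$labels))) {
    stop("grid and county partition shapes differ")
  }
  orphan <- !is.na(grid$values) & is.na(counties$labels)
  if (any(orphan)) {
    stop(sum(orphan), " non-background cell(s) have no county")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Allowed transitions

# Row = time-1 (donor), col = time-2 (target). Developed is terminal; Water
# exchanges with nothing; Forest/Agriculture/Other may convert among
# themselves and to Developed.
ALLOWED_MATRIX <- local({
  m <- matrix(FALSE, 5, 5, dimnames = list(LU_LABELS, LU_LABELS))
  diag(m) <- TRUE
  for (donor in c("f", "a", "o")) {
    m[donor, c("d", "f", "a", "o")] <- TRUE
  }
  m
})

#' Transition keys
#'
#' Transitions are addressed with string keys `"<donor>-><target>"`, e.g.
#' `"f->d"` for Forest to Developed. `transition_key()` builds keys,
#' `split_key()` inverts them.
#'
#' @param donor,target class letters.
#' @return character key(s).
#' @export
transition_key <- function(donor, target) {
  if (!length(donor) && !length(target)) return(character(0))
  paste0(donor, "->", target)
}

#' @rdname transition_key
#' @param key character key(s) of the form `"f->d"`.
#' @return `split_key()`: a list with `donor` and `target` character vectors.
#' @export
split_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)
  list(donor = vapply(parts, `[`, "", 1L),
       target = vapply(parts, `[`, "", 2L))
}

#' Is a land-use transition allowed?
#'
#' The allowed set: every class may persist; Forest, Agriculture and Other
#' may convert to Developed or to one another; Developed never converts to
#' anything else; Water neither gains from nor loses to any other class.
#'
#' @param donor,target class letters (vectorized).
#' @return logical vector.
#' @export
is_allowed <- function(donor, target) {
  if (anyNA(donor) || anyNA(target)) stop("background has no transitions")
  if (!all(donor %in% LU_LABELS) || !all(target %in% LU_LABELS)) {
    stop("unknown class label")
  }
  ALLOWED_MATRIX[cbind(donor, target)]
}

#' All allowed transition keys
#'
#' @param include_self include self-transitions (default `FALSE`).
#' @return character vector of keys.
#' @export
allowed_keys <- function(include_self = FALSE) {
  idx <- which(ALLOWED_MATRIX, arr.ind = TRUE)
  keys <- transition_key(LU_LABELS[idx[, 1]], LU_LABELS[idx[, 2]])
  if (!include_self) {
    keys <- keys[LU_LABELS[idx[, 1]] != LU_LABELS[idx[, 2]]]
  }
  sort(keys)
}

# ---------------------------------------------------------------------------
# Quota ledger

#' Construct a county quota ledger
#'
#' A ledger tracks, for one county, the remaining gross transition quota
#' (in cells) for each allowed donor-to-target pair, the frozen initial
#' quota, and any shortfall recorded when allocation abandons a target
#' class. Ledgers have reference semantics (environments) because the
#' allocator decrements them in place.
#'
#' @param county county identifier.
#' @param quotas named integer vector keyed by transition key, e.g.
#'   `c("f->d" = 40)`. Self-transition keys are accepted and ignored.
#' @return an object of class `quota_ledger`.
#' @export
quota_ledger <- function(county, quotas = integer()) {
  if (length(quotas)) {
    ks <- split_key(names(quotas))
    self <- ks$donor == ks$target
    if (any(self)) quotas <- quotas[!self]
  }
  if (length(quotas)) {
    ks <- split_key(names(quotas))
    ok <- is_allowed(ks$donor, ks$target)
    if (!all(ok)) {
      stop("disallowed transition quota(s) for county ", county, ": ",
           paste(names(quotas)[!ok], collapse = ", "))
    }
    if (any(quotas < 0) || any(quotas != round(quotas))) {
      stop("quotas must be non-negative integers")
    }
  }
  full <- stats::setNames(integer(length(allowed_keys())), allowed_keys())
  full[names(quotas)] <- as.integer(quotas)
  e <- new.env(parent = emptyenv())
  e$county <- county
  e$initial <- full
  e$remaining <- full
  e$shortfall <- stats::setNames(integer(length(full)), names(full))
  class(e) <- "quota_ledger"
  e
}

#' @export
print.quota_ledger <- function(x, ...) {
  act <- x$initial[x$initial > 0]
  cat(sprintf("<quota_ledger> county %s: %d active transition(s)\n",
              x$county, length(act)))
  for (k in names(act)) {
    cat(sprintf("  %s: %d remaining of %d (shortfall %d)\n",
                k, x$remaining[k], x$initial[k], x$shortfall[k]))
  }
  invisible(x)
}

ledger_decrement <- function(ledger, key) {
  if (ledger$remaining[key] <= 0L) stop("quota exhausted for ", key)
  ledger$remaining[key] <- ledger$remaining[key] - 1L
  invisible(ledger)
}

ledger_record_shortfall <- function(ledger, key, cells) {
  ledger$shortfall[key] <- ledger$shortfall[key] + as.integer(cells)
  invisible(ledger)
}

#' Converted cells implied by a ledger
#'
#' @param ledger a `quota_ledger`.
#' @return named integer vector, `initial - remaining` per key.
#' @export
ledger_converted <- function(ledger) ledger$initial - ledger$remaining

#' Build quota ledgers from a long table
#'
#' @param table data.frame with columns `county`, `donor`, `target`, `cells`.
#'   Self-transition rows are ignored (they consume no allocation); rows
#'   with disallowed pairs raise a validation error listing the offending
#'   rows.
#' @param counties optional character vector of county ids that must all
#'   receive a ledger (counties absent from the table get all-zero quotas).
#' @return named list of `quota_ledger`, keyed by county id.
#' @export
build_quota_ledgers <- function(table, counties = NULL) {
  req <- c("county", "donor", "target", "cells")
  if (!all(req %in% names(table))) {
    stop("quota table needs columns: ", paste(req, collapse = ", "))
  }
  table$county <- as.character(table$county)
  nonself <- table$donor != table$target
  chk <- table[nonself, , drop = FALSE]
  if (nrow(chk)) {
    ok <- is_allowed(chk$donor, chk$target)
    if (!all(ok)) {
      bad <- chk[!ok, , drop = FALSE]
      stop("disallowed transition(s) in quota table: ",
           paste(sprintf("%s %s->%s", bad$county, bad$donor, bad$target),
                 collapse = "; "))
    }
  }
  ids <- union(unique(table$county), counties)
  out <- lapply(ids, function(cid) {
    rows <- table[table$county == cid & nonself, , drop = FALSE]
    q <- stats::setNames(rows$cells, transition_key(rows$donor, rows$target))
    if (anyDuplicated(names(q))) {
      q <- tapply(q, names(q), sum)
      q <- stats::setNames(as.integer(q), names(q))
    }
    quota_ledger(cid, q)
  })
  stats::setNames(out, ids)
}

#' Read a quota CSV
#'
#' @param path CSV with header `county,donor,target,cells`.
#' @return data.frame suitable for [build_quota_ledgers()].
#' @export
read_quota_table <- function(path) {
  utils::read.csv(path, colClasses = c(county = "character",
                                       donor = "character",
                                       target = "character",
                                       cells = "integer"))
}

#' Convert hectares to whole cells
#'
#' Quotas are specified in cells; this helper converts areas given in
#' hectares using the grid's cell size, rounding half away from zero.
#'
#' @param hectares numeric vector of areas.
#' @param cell_size cell edge in meters.
#' @return integer vector of cell counts.
#' @export
hectares_to_cells <- function(hectares, cell_size = 90) {
  cell_ha <- cell_size^2 / 1e4
  as.integer(floor(hectares / cell_ha + 0.5))
}
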