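#' Read point records from CSV
#'
#' Expects columns `species_tag` (`focal` / `nonfocal`), `date` (ISO-8601)
#' and either `cell_id` or `lon` + `lat`. Records without a parseable date,
#' or with neither a cell id nor both coordinates, are eliminated; the
#' `read_report` attribute tallies them.
#'
#' @param path CSV file path.
#' @return data frame of records with `date` parsed to `Date`, plus a
#'   `read_report` attribute (`n_input`, `n_kept`, `n_bad_date`,
#'   `n_no_location`).
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, colClasses = "character")
  stopifnot("species_tag" %in% names(rec), "date" %in% names(rec))
  n_in <- nrow(rec)
  d <- as.Date(rec$date, format = "%Y-%m-%d")
  bad_date <- is.na(d)
  has_id <- if ("cell_id" %in% names(rec)) !is.na(rec$cell_id) & rec$cell_id != ""
            else rep(FALSE, n_in)
  has_xy <- if (all(c("lon", "lat") %in% names(rec)))
    is.finite(suppressWarnings(as.numeric(rec$lon))) &
      is.finite(suppressWarnings(as.numeric(rec$lat)))
  else rep(FALSE, n_in)
  no_loc <- !has_id & !has_xy
  keep <- !bad_date & !no_loc
  out <- rec[keep, , drop = FALSE]
  out$date <- d[keep]
  if ("lon" %in% names(out)) out$lon <- as.numeric(out$lon)
  if ("lat" %in% names(out)) out$lat <- as.numeric(out$lat)
  rownames(out) <- NULL
  attr(out, "read_report") <- list(n_input = n_in, n_kept = sum(keep),
                                   n_bad_date = sum(bad_date),
                                   n_no_location = sum(no_loc & !bad_date))
  out
}

#' Assign point records to grid cells
#'
#' Records may come with a `cell_id` already set (kept as-is after checking it
#' exists) or with decimal-degree/projected coordinates `lon`, `lat`, which
#' are mapped to the lattice cell containing the point. Cells are half-open:
#' the west and south edges belong to the cell, the east and north edges do
#' not, so every in-grid point maps to exactly one cell. Records outside the
#' grid, or with malformed coordinates, are dropped and tallied in the
#' `assignment_report` attribute.
#'
#' @param records data frame with columns `species_tag`, `date` and either
#'   `cell_id` or `lon` + `lat` (per record: `cell_id` wins when non-missing).
#' @param grid an [lattice_grid()] / [read_grid()] object with geometry
#'   (`origin`, `cellsize`) when coordinate records are present.
#' @return The assigned records (with `cell_id` filled in), with an
#'   `assignment_report` attribute: a list with counts `n_input`,
#'   `n_assigned`, `n_outside`, `n_bad_coord`.
#' @export
assign_to_grid <- function(records, grid) {
  stopifnot(inherits(grid, "occu_grid"), is.data.frame(records))
  rec <- records
  n_in <- nrow(rec)
  has_id <- if ("cell_id" %in% names(rec)) !is.na(rec$cell_id) & rec$cell_id != "" else rep(FALSE, n_in)
  cell <- rep(NA_character_, n_in)
  if (any(has_id)) {
    ids <- as.character(rec$cell_id[has_id])
    unknown <- setdiff(unique(ids), grid$cell_ids)
    if (length(unknown))
      stop("unknown cell_id in records: ", paste(utils::head(unknown, 5), collapse = ", "))
    cell[has_id] <- ids
  }
  n_bad <- 0L; n_out <- 0L
  need <- which(!has_id)
  if (length(need)) {
    if (!all(c("lon", "lat") %in% names(rec)))
      stop("records without cell_id need lon and lat columns")
    if (is.null(grid$origin))
      stop("grid has no geometry; cannot assign coordinate records")
    lon <- suppressWarnings(as.numeric(rec$lon[need]))
    lat <- suppressWarnings(as.numeric(rec$lat[need]))
    bad <- !is.finite(lon) | !is.finite(lat)
    n_bad <- sum(bad)
    cc <- floor((lon - grid$origin[1]) / grid$cellsize) + 1
    rr <- floor((lat - grid$origin[2]) / grid$cellsize) + 1
    inside <- !bad & cc >= 1 & cc <= grid$ncol & rr >= 1 & rr <= grid$nrow
    n_out <- sum(!bad & !inside)
    idx <- (rr[inside] - 1) * grid$ncol + cc[inside]
    cell[need[inside]] <- grid$cell_ids[idx]
  }
  keep <- !is.na(cell)
  out <- rec[keep, , drop = FALSE]
  out$cell_id <- cell[keep]
  rownames(out) <- NULL
  attr(out, "assignment_report") <- list(
    n_input = n_in, n_assigned = sum(keep), n_outside = n_out, n_bad_coord = n_bad
  )
  out
}

#' Weekly survey index within a season
#'
#' Seasons run 1 June to 30 September (122 days) and are divided into 18
#' consecutive weeks counted from 1 June; the final week holds only 3 days.
#' Dates outside the season return `NA`.
#'
#' @param date a `Date` vector (or anything `as.Date` accepts).
#' @return integer vector of 0-based week indices in `0:17`, `NA` when out of
#'   season.
#' @examples
#' week_index(as.Date(c("2020-06-01", "2020-06-08", "2020-09-30", "2020-10-01")))
#' @export
week_index <- function(date) {
  d <- as.Date(date)
  yr <- as.integer(format(d, "%Y"))
  start <- as.Date(sprintf("%d-06-01", yr))
  days <- as.integer(d - start)
  w <- days %/% 7L
  w[days < 0L | days > 121L] <- NA_integer_
  w
}

#' Low-level detection-history constructor
#'
#' Builds an `occu_history` from a coded lattice. Most users should call
#' [build_history()]; this constructor exists for simulated or hand-built
#' instances (e.g. small enumerable test cases with fewer than 18 weeks).
#'
#' @param y integer array `cells x years x weeks` with values 1 (focal
#'   detected), 0 (congener detected, focal not), `NA` (no records).
#' @param count integer matrix `cells x years` of congener (non-focal) record
#'   totals.
#' @param years ordered season labels.
#' @param cell_ids cell identifiers matching the grid.
#' @return An object of class `occu_history` with elements `y`, `count`,
#'   `surveyed` (logical `cells x years`), `years`, `n_weeks`, `cell_ids`.
#' @export
occu_history <- function(y, count, years, cell_ids) {
  stopifnot(length(dim(y)) == 3, nrow(count) == dim(y)[1], ncol(count) == dim(y)[2],
            length(years) == dim(y)[2], length(cell_ids) == dim(y)[1])
  if (any(!is.na(y) & !(y %in% c(0L, 1L)))) stop("y must be 1, 0 or NA")
  if (any(count < 0)) stop("count must be nonnegative")
  storage.mode(y) <- "integer"
  storage.mode(count) <- "integer"
  surveyed <- apply(!is.na(y), c(1, 2), any)
  structure(list(y = y, count = count, surveyed = surveyed, years = years,
                 n_weeks = dim(y)[3], cell_ids = as.character(cell_ids)),
            class = "occu_history")
}

#' Build the weekly detection history from assigned records
#'
#' Applies the nondetection-inference coding rule per (cell, year, week):
#' 1 when at least one focal record maps there; 0 when at least one non-focal
#' (congener) record but no focal record maps there; `NA` when no record of
#' either stream maps there. The per cell-year effort covariate `count` is
#' the seasonal total of non-focal records (focal records are excluded).
#'
#' @param focal,nonfocal data frames of cell-assigned records with columns
#'   `cell_id` and `date` (see [assign_to_grid()]).
#' @param grid an `occu_grid`.
#' @param years ordered, consecutive season labels (calendar years).
#' @return An `occu_history` (18 weekly occasions per season). Out-of-season
#'   records and records from years outside `years` are excluded; their
#'   tallies are kept in the `dropped` attribute.
#' @export
build_history <- function(focal, nonfocal, grid, years) {
  stopifnot(inherits(grid, "occu_grid"))
  if ((is.null(focal) || nrow(focal) == 0) && (is.null(nonfocal) || nrow(nonfocal) == 0))
    stop("no observation data")
  if (length(years) > 1 && any(diff(as.integer(years)) != 1L))
    stop("years must be consecutive")
  n <- grid$n; T <- length(years); J <- 18L
  y <- array(NA_integer_, dim = c(n, T, J))
  count <- matrix(0L, n, T)
  dropped <- c(out_of_season = 0L, out_of_years = 0L)

  map <- function(rec) {
    if (is.null(rec) || nrow(rec) == 0)
      return(list(i = integer(0), t = integer(0), j = integer(0), dropped = c(0L, 0L)))
    i <- match(as.character(rec$cell_id), grid$cell_ids)
    if (anyNA(i)) stop("record cell_id not in grid")
    d <- as.Date(rec$date)
    t <- match(as.integer(format(d, "%Y")), as.integer(years))
    w <- week_index(d)
    oy <- is.na(t)
    os <- !oy & is.na(w)
    keep <- !oy & !os
    list(i = i[keep], t = t[keep], j = w[keep] + 1L,
         dropped = c(sum(os), sum(oy)))
  }
  nf <- map(nonfocal); fo <- map(focal)
  dropped <- dropped + nf$dropped + fo$dropped
  if (length(nf$i)) {
    y[cbind(nf$i, nf$t, nf$j)] <- 0L
    for (k in seq_along(nf$i)) count[nf$i[k], nf$t[k]] <- count[nf$i[k], nf$t[k]] + 1L
  }
  if (length(fo$i)) y[cbind(fo$i, fo$t, fo$j)] <- 1L
  h <- occu_history(y, count, years, grid$cell_ids)
  attr(h, "dropped") <- as.list(dropped)
  h
}

#' Write / read a detection history as tidy CSV tables
#'
#' `write_history` writes two files under `dir`: `history.csv` (cell_id,
#' year, week, y; non-missing entries only) and `effort.csv` (cell_id, year,
#' count). `read_history` reconstructs the `occu_history` (given the grid, so
#' that never-surveyed cells are restored as all-missing rows).
#'
#' @param history an `occu_history`.
#' @param dir output directory (created if needed).
#' @param grid an `occu_grid`.
#' @param years season labels (defaults to those found in the files).
#' @param n_weeks weekly occasions per season.
#' @return `write_history`: the directory, invisibly. `read_history`: an
#'   `occu_history`.
#' @export
write_history <- function(history, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- which(!is.na(history$y), arr.ind = TRUE)
  utils::write.csv(data.frame(
    cell_id = history$cell_ids[obs[, 1]],
    year = history$years[obs[, 2]],
    week = obs[, 3],
    y = history$y[obs]
  ), file.path(dir, "history.csv"), row.names = FALSE)
  ct <- which(history$count >= 0, arr.ind = TRUE)
  utils::write.csv(data.frame(
    cell_id = history$cell_ids[ct[, 1]],
    year = history$years[ct[, 2]],
    count = history$count[ct]
  ), file.path(dir, "effort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_history
#' @export
read_history <- function(dir, grid, years = NULL, n_weeks = 18L) {
  hy <- utils::read.csv(file.path(dir, "history.csv"))
  ef <- utils::read.csv(file.path(dir, "effort.csv"))
  if (is.null(years)) years <- sort(unique(c(hy$year, ef$year)))
  n <- grid$n; T <- length(years)
  y <- array(NA_integer_, dim = c(n, T, n_weeks))
  i <- match(as.character(hy$cell_id), grid$cell_ids)
  t <- match(hy$year, years)
  if (anyNA(i) || anyNA(t)) stop("history.csv references unknown cell or year")
  y[cbind(i, t, hy$week)] <- as.integer(hy$y)
  count <- matrix(0L, n, T)
  ie <- match(as.character(ef$cell_id), grid$cell_ids)
  te <- match(ef$year, years)
  count[cbind(ie, te)] <- as.integer(ef$count)
  occu_history(y, count, years, grid$cell_ids)
}

#' @export
print.occu_history <- function(x, ...) {
  cat(sprintf("detection history: %d cells x %d seasons x %d weeks\n",
              dim(x$y)[1], dim(x$y)[2], x$n_weeks))
  cat(sprintf("  surveyed cell-years: %d; detections (y=1): %d; nondetections (y=0): %d\n",
              sum(x$surveyed), sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE)))
  invisible(x)
}
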