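#' Grid definitions for occupancy analysis
#'
#' An `occu_grid` describes the spatial unit of inference: a set of cells,
#' their Moore (8-neighbor) adjacency, and a binary conservation-unit
#' indicator per cell. Cells may optionally carry a rectangular lattice
#' geometry (origin + cell size) so that point records with coordinates can
#' be assigned to cells.
#'
#' @param nrow,ncol lattice dimensions (cells).
#' @param cu_cols integer vector of lattice columns belonging to conservation
#'   unit 1 (indicator 1); default is the western (left) half.
#' @param origin numeric length-2, coordinates of the south-west corner of
#'   cell (row 1, col 1).
#' @param cellsize side length of each (square) cell, in the same units as
#'   the coordinates that will be assigned.
#'
#' @return An object of class `occu_grid`: a list with elements `cell_ids`
#'   (character), `n`, `adj` (list of integer neighbor indices), `cu`
#'   (integer 0/1), `row`, `col`, `nrow`, `ncol`, `origin`, `cellsize`.
#' @examples
#' g <- lattice_grid(3, 3)
#' lengths(g$adj)  # corner cells have 3 neighbors, the center has 8
#' @export
lattice_grid <- function(nrow, ncol, cu_cols = seq_len(max(1L, ncol %/% 2L)),
                         origin = c(0, 0), cellsize = 1) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0, length(origin) == 2)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  n <- nrow * ncol
  row <- rep(seq_len(nrow), each = ncol)
  col <- rep(seq_len(ncol), times = nrow)
  idx <- function(r, c) (r - 1L) * ncol + c
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; c <- col[i]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= nrow && cc >= 1L && cc <= ncol)
        nb <- c(nb, idx(rr, cc))
    }
    adj[[i]] <- sort(nb)
  }
  g <- structure(list(
    cell_ids = as.character(seq_len(n)),
    n = n, adj = adj,
    cu = as.integer(col %in% cu_cols),
    row = row, col = col, nrow = nrow, ncol = ncol,
    origin = as.numeric(origin), cellsize = as.numeric(cellsize)
  ), class = "occu_grid")
  validate_grid(g)
  g
}

#' Read a grid from attribute and adjacency tables
#'
#' The attribute table must have columns `cell_id` and `cu`, and optionally
#' `row` and `col` (lattice coordinates). If no adjacency table is supplied
#' and `row`/`col` are present, Moore adjacency is derived from the lattice
#' coordinates; otherwise the adjacency table must list one edge per line
#' (`cell_id`, `neighbor_id`; undirected, either or both directions).
#'
#' @param attributes a data frame or path to a CSV file.
#' @param adjacency optional data frame or CSV path of edges.
#' @return An `occu_grid` (without point-assignment geometry unless `row`,
#'   `col` are present, in which case unit cells at origin (0,0) are assumed).
#' @export
read_grid <- function(attributes, adjacency = NULL) {
  at <- if (is.character(attributes)) utils::read.csv(attributes) else as.data.frame(attributes)
  stopifnot(all(c("cell_id", "cu") %in% names(at)))
  ids <- as.character(at$cell_id)
  if (anyDuplicated(ids)) stop("duplicated cell_id in grid attributes")
  n <- length(ids)
  cu <- as.integer(at$cu)
  if (!all(cu %in% c(0L, 1L))) stop("cu must be 0 or 1 for every cell")
  has_rc <- all(c("row", "col") %in% names(at))
  adj <- NULL
  if (is.null(adjacency)) {
    if (!has_rc) stop("need either an adjacency table or row/col lattice coordinates")
    key <- paste(at$row, at$col)
    pos <- match(key, key)  # identity; used for lookup below
    lut <- stats::setNames(seq_len(n), key)
    adj <- lapply(seq_len(n), function(i) {
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        j <- lut[paste(at$row[i] + dr, at$col[i] + dc)]
        if (!is.na(j)) nb <- c(nb, unname(j))
      }
      sort(nb)
    })
  } else {
    ed <- if (is.character(adjacency)) utils::read.csv(adjacency) else as.data.frame(adjacency)
    stopifnot(all(c("cell_id", "neighbor_id") %in% names(ed)))
    a <- match(as.character(ed$cell_id), ids)
    b <- match(as.character(ed$neighbor_id), ids)
    if (anyNA(a) || anyNA(b)) stop("adjacency references unknown cell_id")
    adj <- vector("list", n)
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  g <- structure(list(
    cell_ids = ids, n = n, adj = adj, cu = cu,
    row = if (has_rc) as.integer(at$row) else NULL,
    col = if (has_rc) as.integer(at$col) else NULL,
    nrow = if (has_rc) as.integer(max(at$row)) else NULL,
    ncol = if (has_rc) as.integer(max(at$col)) else NULL,
    origin = if (has_rc) c(0, 0) else NULL,
    cellsize = if (has_rc) 1 else NULL
  ), class = "occu_grid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  n <- g$n
  for (i in seq_len(n)) {
    nb <- g$adj[[i]]
    if (i %in% nb) stop("self-adjacency at cell ", g$cell_ids[i])
    if (length(nb) > 8L) stop("more than 8 neighbors at cell ", g$cell_ids[i])
    for (j in nb) if (!(i %in% g$adj[[j]]))
      stop("asymmetric adjacency between cells ", g$cell_ids[i], " and ", g$cell_ids[j])
  }
  invisible(g)
}

#' @export
print.occu_grid <- function(x, ...) {
  cat("occupancy grid:", x$n, "cells")
  if (!is.null(x$nrow)) cat(sprintf(" (%d x %d lattice)", x$nrow, x$ncol))
  cat(",", sum(x$cu), "in conservation unit 1\n")
  invisible(x)
}
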