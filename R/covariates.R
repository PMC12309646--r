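#' Standardize a covariate to mean zero, variance one
#'
#' Centers by the mean and scales by the root-mean-square deviation about the
#' mean (the 1/n "population" standard deviation), so a two-point input
#' `(0, 2)` maps to `(-1, 1)`. The transform is invertible through the stored
#' `center`/`scale` attributes.
#'
#' @param x numeric vector with at least 2 distinct finite values.
#' @return `x` standardized, with attributes `center` and `scale`.
#' @seealso `unstandardize` for the inverse transform.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x[is.finite(x)])) < 2) stop("zero variance: cannot standardize")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  structure((x - m) / s, center = m, scale = s)
}

#' Invert a standardization
#' @param z output of `standardize` (or any numeric) to map back.
#' @param center,scale the transform; default taken from `z`'s attributes.
#' @return numeric on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"), scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

#' Seasonal drought index from monthly values
#'
#' Collapses monthly Palmer Drought Severity Index values to one seasonal
#' value per cell-year by averaging May, June and July (the window in which
#' resource availability drives colony development later in the season).
#'
#' @param monthly data frame with columns `cell_id`, `year`, `month`, `pdsi`.
#' @return data frame `cell_id`, `year`, `pdsi` (May-July mean). Errors,
#'   naming the cell-year, when any of the three months is absent.
#' @export
seasonal_pdsi <- function(monthly) {
  stopifnot(all(c("cell_id", "year", "month", "pdsi") %in% names(monthly)))
  m <- monthly[monthly$month %in% 5:7, ]
  key <- interaction(m$cell_id, m$year, drop = TRUE)
  nm <- tapply(m$month, key, function(v) length(unique(v)))
  if (any(nm < 3)) {
    bad <- names(nm)[which(nm < 3)[1]]
    stop("missing May-July months for cell-year ", bad)
  }
  agg <- stats::aggregate(pdsi ~ cell_id + year, data = m, FUN = mean)
  agg[order(agg$cell_id, agg$year), , drop = FALSE]
}

#' Screen covariates for high pairwise correlation
#'
#' Returns the connected components of the graph whose edges join columns
#' with `|r| >` the threshold (0.9 in the usual screen). The caller decides
#' the remedy, e.g. summing developed-land subclasses into one covariate.
#'
#' @param x numeric matrix or data frame of candidate columns.
#' @param threshold absolute-correlation threshold.
#' @return list of character vectors (components of 2+ columns); empty list
#'   when nothing exceeds the threshold.
#' @export
correlation_screen <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant column: ", paste(colnames(x)[sds == 0], collapse = ", "))
  r <- abs(stats::cor(x))
  p <- ncol(x)
  comp <- seq_len(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (r[i, j] > threshold) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  nms <- colnames(x); if (is.null(nms)) nms <- paste0("V", seq_len(p))
  out <- split(nms, comp)
  unname(out[vapply(out, length, 1L) >= 2])
}

#' Low-level covariate-set constructor
#'
#' Assembles an `occu_covariates` object from already-standardized fields.
#' Most users should call [covariate_set()], which standardizes raw inputs.
#'
#' @param herb_s,dev_s,hay_s standardized per-cell land-cover covariates.
#' @param cu per-cell 0/1 conservation-unit indicator (enters models raw).
#' @param pdsi_s standardized per cell x year drought index matrix.
#' @param years season labels.
#' @param scaling named list of `c(center, scale)` pairs used.
#' @param raw optional list of raw fields.
#' @export
occu_covariates <- function(herb_s, dev_s, hay_s, cu, pdsi_s, years,
                            scaling = list(), raw = list()) {
  n <- length(herb_s)
  stopifnot(length(dev_s) == n, length(hay_s) == n, length(cu) == n,
            nrow(pdsi_s) == n, ncol(pdsi_s) == length(years),
            all(cu %in% c(0L, 1L)))
  structure(list(herb_s = as.numeric(herb_s), dev_s = as.numeric(dev_s),
                 hay_s = as.numeric(hay_s), cu = as.integer(cu),
                 pdsi_s = unname(as.matrix(pdsi_s)), years = years,
                 scaling = scaling, raw = raw),
            class = "occu_covariates")
}

#' Assemble the standardized covariate set
#'
#' Land-cover proportions (grassland/herbaceous, developed, pasture/hay) are
#' per-cell and standardized across cells; the seasonal drought index is per
#' cell-year and standardized pooled across all cell-years (one mean/sd), so
#' between-year drought contrast is preserved. The conservation-unit
#' indicator stays on its 0/1 scale.
#'
#' @param grid an `occu_grid` (supplies `cu` and the cell ordering).
#' @param herb,dev,hay per-cell proportions in `[0, 1]`, ordered as
#'   `grid$cell_ids`.
#' @param pdsi per cell x year matrix of seasonal drought values (see
#'   [seasonal_pdsi()]), or a data frame `cell_id`, `year`, `pdsi`.
#' @param years ordered season labels.
#' @return An `occu_covariates` object.
#' @export
covariate_set <- function(grid, herb, dev, hay, pdsi, years) {
  stopifnot(inherits(grid, "occu_grid"))
  for (v in list(herb = herb, dev = dev, hay = hay)) {
    if (any(v < -1e-9 | v > 1 + 1e-9)) stop("land-cover proportions must lie in [0, 1]")
  }
  if (is.data.frame(pdsi)) {
    P <- matrix(NA_real_, grid$n, length(years))
    i <- match(as.character(pdsi$cell_id), grid$cell_ids)
    t <- match(pdsi$year, years)
    if (anyNA(i) || anyNA(t)) stop("pdsi table references unknown cell or year")
    P[cbind(i, t)] <- pdsi$pdsi
    pdsi <- P
  }
  pdsi <- as.matrix(pdsi)
  if (anyNA(pdsi)) stop("PDSI must be defined for every cell-year")
  hs <- standardize(herb); ds <- standardize(dev); ys <- standardize(hay)
  ps <- standardize(as.numeric(pdsi))
  occu_covariates(
    herb_s = hs, dev_s = ds, hay_s = ys, cu = grid$cu,
    pdsi_s = matrix(as.numeric(ps), grid$n, length(years)), years = years,
    scaling = list(herb = c(attr(hs, "center"), attr(hs, "scale")),
                   dev = c(attr(ds, "center"), attr(ds, "scale")),
                   hay = c(attr(ys, "center"), attr(ys, "scale")),
                   pdsi = c(attr(ps, "center"), attr(ps, "scale"))),
    raw = list(herb = herb, dev = dev, hay = hay, pdsi = pdsi)
  )
}

#' Read land-cover class proportions and map them to model covariates
#'
#' @param path CSV with columns `cell_id`, `class`, `proportion`.
#' @param grid an `occu_grid`.
#' @param mapping named list of class-name vectors summed into each
#'   covariate, e.g. `list(herb = "grassland_herbaceous",
#'   dev = c("dev_open", "dev_low", "dev_medium"), hay = "pasture_hay")`.
#' @return data frame with one row per cell (ordered as the grid) and one
#'   column per mapping entry.
#' @export
read_landcover <- function(path, grid,
                           mapping = list(herb = "grassland_herbaceous",
                                          dev = c("dev_open", "dev_low", "dev_medium"),
                                          hay = "pasture_hay")) {
  lc <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "class", "proportion") %in% names(lc)))
  out <- data.frame(cell_id = grid$cell_ids)
  for (nm in names(mapping)) {
    sel <- lc[lc$class %in% mapping[[nm]], ]
    agg <- tapply(sel$proportion, as.character(sel$cell_id), sum)
    v <- as.numeric(agg[grid$cell_ids])
    v[is.na(v)] <- 0
    out[[nm]] <- v
  }
  out
}

#' Standardized seasonal effort covariate
#'
#' Standardizes the per cell-year congener count over surveyed cell-years
#' (the only entries that reach the detection likelihood). Unsurveyed
#' cell-years get the standardization mean (0), used for prediction only.
#' Degenerate inputs (fewer than two distinct surveyed counts) fall back to
#' an all-zero covariate so effect of effort drops out.
#'
#' @param history an `occu_history`.
#' @return numeric matrix `cells x years` with `center`/`scale` attributes.
#' @export
effort_std <- function(history) {
  cnt <- history$count
  sv <- history$surveyed
  out <- matrix(0, nrow(cnt), ncol(cnt))
  vals <- cnt[sv]
  if (length(unique(vals)) >= 2) {
    z <- standardize(vals)
    out[sv] <- as.numeric(z)
    attr(out, "center") <- attr(z, "center")
    attr(out, "scale") <- attr(z, "scale")
  } else {
    attr(out, "center") <- if (length(vals)) mean(vals) else 0
    attr(out, "scale") <- 1
  }
  out
}
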