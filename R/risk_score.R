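## Gridded agricultural herbicide risk scoring (EPRIP-style indicator):
## per crop x herbicide pair in a grid cell,
##   S   = VDT * AR / 100                         (soil load)
##   PEC = (S / 4500) * (integral of C(t)) / 100  (predicted env. conc.)
##   PNEC = LC50 / 1000                           (assessment factor 1000)
##   RQ  = PEC / PNEC
## and per cell the risk point RP = log10(sum RQ), classed
## negligible (RP <= 0), low (0 < RP <= 1), medium (1 < RP <= 3),
## high (RP > 3). C(t) is modelled as single first-order decay with rate
## ln(2)/DT50; the constants 4500 and 100 are retained verbatim from the
## source indicator, so PEC and PNEC are in model units and only their
## ratio is interpretable.

#' Integrated residual fraction under first-order decay
#'
#' \eqn{\int_0^T e^{-\lambda t} dt = (1 - e^{-\lambda T})/\lambda} with
#' \eqn{\lambda = \ln 2 / DT50}. Units: days.
#'
#' @param DT50 soil half-life in days, > 0. Vectorised.
#' @param horizon_days integration horizon T in days, > 0 (default 365).
#' @return integral in days.
#' @export
residual_integral <- function(DT50, horizon_days = 365) {
  if (any(!is.finite(DT50)) || any(DT50 <= 0) ||
      any(!is.finite(horizon_days)) || any(horizon_days <= 0))
    stop("DT50 and horizon must be finite and > 0")
  lambda <- log(2) / DT50
  (1 - exp(-lambda * horizon_days)) / lambda
}

#' Soil load of a herbicide application
#'
#' S = VDT * AR / 100.
#'
#' @param VDT soil-coverage percentage of the crop, in [0, 100]. Vectorised.
#' @param AR application rate of the herbicide on the crop, >= 0.
#' @return soil load S (same units as AR).
#' @export
soil_load <- function(VDT, AR) {
  if (any(VDT < 0) || any(VDT > 100)) stop("VDT must lie in [0, 100]")
  if (any(AR < 0)) stop("application rates must be >= 0")
  VDT * AR / 100
}

#' Predicted environmental concentration
#'
#' PEC = (S / 4500) * (integral / 100), in model units.
#'
#' @param S soil load from \code{\link{soil_load}}. Vectorised.
#' @param integral integrated residual fraction from
#'   \code{\link{residual_integral}}.
#' @return PEC in model units.
#' @export
pec <- function(S, integral) {
  if (any(S < 0) || any(integral < 0)) stop("inputs must be >= 0")
  (S / 4500) * (integral / 100)
}

#' Predicted no-effect concentration
#'
#' PNEC = LC50 / 1000 (assessment factor 1000).
#'
#' @param LC50 median lethal concentration, > 0. Vectorised.
#' @return PNEC.
#' @export
pnec <- function(LC50) {
  if (any(!is.finite(LC50)) || any(LC50 <= 0)) stop("LC50 must be > 0")
  LC50 / 1000
}

#' Classify a risk point
#'
#' @param rp numeric risk point(s); -Inf allowed (zero total RQ).
#' @return factor with levels negligible, low, medium, high.
#' @export
classify_rp <- function(rp) {
  cls <- ifelse(rp <= 0, "negligible",
         ifelse(rp <= 1, "low",
         ifelse(rp <= 3, "medium", "high")))
  factor(cls, levels = c("negligible", "low", "medium", "high"))
}

#' Risk points for grid cells
#'
#' Computes the full risk chain for every (crop, herbicide) application pair
#' in a cell table and aggregates to one risk point per cell. For each pair
#' the risk quotient is PEC/PNEC; by default the more conservative of the
#' soil (earthworm LC50) and water (fish LC50) compartments is used.
#'
#' @param cells data.frame with columns \code{cell_id, region, area_km2,
#'   crop, herbicide, AR, VDT} (one row per application pair; a cell with no
#'   applications may appear with AR = 0).
#' @param props data.frame with columns \code{herbicide, DT50_days,
#'   LC50_earthworm, LC50_fish} (optionally \code{DT90_days}, carried but
#'   unused under first-order decay).
#' @param horizon_days integration horizon (default 365).
#' @param compartment "max" (default), "soil" or "water".
#' @return list with \code{cells}: data.frame \code{cell_id, region,
#'   area_km2, sum_RQ, RP, class}; and \code{pairs}: per-pair RQ breakdown.
#' @export
risk_point <- function(cells, props, horizon_days = 365,
                       compartment = c("max", "soil", "water")) {
  compartment <- match.arg(compartment)
  stopifnot(is.data.frame(cells), is.data.frame(props))
  need <- c("cell_id", "region", "area_km2", "crop", "herbicide", "AR", "VDT")
  if (!all(need %in% names(cells)))
    stop("cell table lacks columns: ",
         paste(setdiff(need, names(cells)), collapse = ", "))
  needp <- c("herbicide", "DT50_days", "LC50_earthworm", "LC50_fish")
  if (!all(needp %in% names(props)))
    stop("properties table lacks columns: ",
         paste(setdiff(needp, names(props)), collapse = ", "))
  idx <- match(cells$herbicide, props$herbicide)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no properties for herbicide '", cells$herbicide[bad],
         "' (crop '", cells$crop[bad], "', cell ", cells$cell_id[bad], ")")
  }
  s <- soil_load(cells$VDT, cells$AR)
  integ <- residual_integral(props$DT50_days[idx], horizon_days)
  pe <- pec(s, integ)
  rq_soil <- pe / pnec(props$LC50_earthworm[idx])
  rq_water <- pe / pnec(props$LC50_fish[idx])
  rq <- switch(compartment,
    max = pmax(rq_soil, rq_water),
    soil = rq_soil,
    water = rq_water)
  pairs <- data.frame(cell_id = cells$cell_id, crop = cells$crop,
                      herbicide = cells$herbicide, S = s, PEC = pe,
                      RQ_soil = rq_soil, RQ_water = rq_water, RQ = rq)
  agg <- stats::aggregate(rq, by = list(cell_id = cells$cell_id), FUN = sum)
  names(agg)[2] <- "sum_RQ"
  meta <- unique(cells[, c("cell_id", "region", "area_km2")])
  if (anyDuplicated(meta$cell_id))
    stop("inconsistent region/area across rows of the same cell")
  out <- merge(meta, agg, by = "cell_id", sort = FALSE)
  out$RP <- ifelse(out$sum_RQ > 0, log10(out$sum_RQ), -Inf)
  out$class <- classify_rp(out$RP)
  list(cells = out, pairs = pairs)
}

#' Regional risk-map summary
#'
#' Area-weighted fraction of agricultural land in each risk class, per
#' region. Cells with zero agricultural area are excluded from the
#' denominators.
#'
#' @param results the \code{cells} data.frame from \code{\link{risk_point}}
#'   (or any data.frame with \code{cell_id, region, area_km2, class}).
#' @return data.frame: \code{region, area_km2, frac_negligible, frac_low,
#'   frac_medium, frac_high} (fractions sum to 1 per region).
#' @export
summarize_risk_map <- function(results) {
  need <- c("cell_id", "region", "area_km2", "class")
  if (!all(need %in% names(results)))
    stop("results lack columns: ",
         paste(setdiff(need, names(results)), collapse = ", "))
  res <- results[results$area_km2 > 0, , drop = FALSE]
  if (nrow(res) == 0L) stop("no cells with positive agricultural area")
  lv <- c("negligible", "low", "medium", "high")
  out <- lapply(split(res, res$region), function(r) {
    tot <- sum(r$area_km2)
    fr <- vapply(lv, function(cl) sum(r$area_km2[r$class == cl]) / tot, 1)
    data.frame(area_km2 = tot, frac_negligible = fr[1], frac_low = fr[2],
               frac_medium = fr[3], frac_high = fr[4])
  })
  out <- do.call(rbind, out)
  out <- cbind(region = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Read grid-cell and herbicide-properties tables
#'
#' Cell table: \code{cell_id,region,area_km2,crop,herbicide,AR,VDT}.
#' Properties: \code{herbicide,DT50_days,DT90_days,LC50_earthworm,LC50_fish}.
#' @param path file path.
#' @return data.frame.
#' @export
read_cells <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname read_cells
#' @export
read_props <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
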