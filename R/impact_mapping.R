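## Station-level impact mapping: residues -> TEQ -> community inhibition,
## with regional summaries, exceedance fractions, chronological trend tests
## and the carbon-loss arithmetic for the global extrapolation.

#' Column names of a wide survey table that are not herbicide concentrations
#' @keywords internal
SURVEY_META_COLS <- c("station_id", "region", "lat", "lon", "year")

#' Read / write a wide-format survey table
#'
#' Canonical survey format: one row per station with columns
#' \code{station_id,region,lat,lon,year} followed by one column per herbicide
#' holding concentrations in nmol/L (0 = below LOQ / not detected).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_survey(df)
}

#' @rdname read_survey
#' @param survey survey data.frame.
#' @export
write_survey <- function(survey, path) {
  validate_survey(survey)
  utils::write.csv(survey, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_survey <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(SURVEY_META_COLS, names(df))
  if (length(missing))
    stop("survey table lacks required columns: ", paste(missing, collapse = ", "))
  herb <- setdiff(names(df), SURVEY_META_COLS)
  if (length(herb) == 0L) stop("survey table has no herbicide columns")
  for (h in herb) {
    v <- df[[h]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("herbicide column '", h, "' must be numeric, finite and >= 0")
  }
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("latitude/longitude out of range")
  df
}

#' Herbicide columns of a survey table
#' @param survey survey data.frame.
#' @return character vector of herbicide column names.
#' @export
survey_herbicides <- function(survey) setdiff(names(survey), SURVEY_META_COLS)

#' Per-station TEQ and community inhibition
#'
#' Converts each station's residue mixture to its equi-effective atrazine
#' concentration (full concentration-addition solve) and maps it through the
#' community curve to a primary-productivity inhibition percentage.
#'
#' @param survey wide survey data.frame (see \code{\link{read_survey}}).
#' @param db a \code{\link{curve_db}} covering every herbicide column.
#' @param curve a \code{\link{build_community_curve}} object.
#' @return the survey meta columns plus \code{teq} (nmol/L),
#'   \code{inhibition} (percent) and \code{saturated} (logical).
#' @export
station_inhibition <- function(survey, db, curve = build_community_curve()) {
  survey <- validate_survey(survey)
  herb <- survey_herbicides(survey)
  unknown <- setdiff(herb, names(db$curves))
  if (length(unknown)) {
    bad <- survey$station_id[rowSums(survey[, unknown, drop = FALSE] > 0) > 0]
    stop("herbicide(s) not in curve database: ",
         paste(unknown, collapse = ", "),
         if (length(bad)) paste0(" (first affected station: ", bad[[1]], ")") else "")
  }
  teq <- numeric(nrow(survey))
  sat <- logical(nrow(survey))
  for (i in seq_len(nrow(survey))) {
    smp <- as.numeric(survey[i, herb])
    names(smp) <- herb
    tq <- teq_atrazine(smp, db)
    teq[i] <- as.numeric(tq)
    sat[i] <- isTRUE(attr(tq, "saturated"))
  }
  out <- survey[, SURVEY_META_COLS]
  out$teq <- teq
  out$inhibition <- predict(curve, teq)
  out$saturated <- sat
  out
}

#' Exceedance counts and fractions
#'
#' How many stations have inhibition strictly greater than each threshold.
#'
#' @param inhibitions numeric vector of inhibition percentages.
#' @param thresholds percent thresholds, sorted ascending (default 5, 10, 25).
#' @return data.frame with columns \code{threshold}, \code{count},
#'   \code{fraction}.
#' @export
exceedance <- function(inhibitions, thresholds = c(5, 10, 25)) {
  stopifnot(is.numeric(inhibitions), is.numeric(thresholds))
  if (length(inhibitions) == 0L) stop("no inhibition values supplied")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted strictly ascending")
  counts <- vapply(thresholds, function(th) sum(inhibitions > th), integer(1))
  data.frame(threshold = thresholds, count = counts,
             fraction = counts / length(inhibitions))
}

#' Regional summaries with bootstrap CI of the median
#'
#' Per-region median, quartiles (linear interpolation between order
#' statistics, R quantile type 7) and maximum of a station-level statistic,
#' with a seeded percentile-bootstrap 95\% confidence interval of the median.
#'
#' @param regions character/factor vector of region labels.
#' @param values numeric vector, same length.
#' @param B number of bootstrap resamples (default 2000).
#' @param seed integer seed (default 1).
#' @param conf confidence level (default 0.95).
#' @return data.frame, one row per region: \code{region}, \code{n},
#'   \code{median}, \code{q1}, \code{q3}, \code{max}, \code{ci_lo},
#'   \code{ci_hi}, \code{degenerate} (TRUE when n = 1).
#' @export
summarize_region <- function(regions, values, B = 2000L, seed = 1L,
                             conf = 0.95) {
  stopifnot(length(regions) == length(values), is.numeric(values))
  if (length(values) == 0L) stop("no data")
  alpha <- (1 - conf) / 2
  res <- lapply(split(values, regions), function(v) {
    n <- length(v)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    meds <- withr_seed(seed, {
      vapply(seq_len(B), function(b)
        stats::median(v[sample.int(n, n, replace = TRUE)]), numeric(1))
    })
    ci <- stats::quantile(meds, c(alpha, 1 - alpha), type = 7, names = FALSE)
    data.frame(n = n, median = q[2], q1 = q[1], q3 = q[3], max = max(v),
               ci_lo = ci[1], ci_hi = ci[2], degenerate = n == 1L)
  })
  out <- do.call(rbind, res)
  out <- cbind(region = names(res), out)
  rownames(out) <- NULL
  out
}

## run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One-way ANOVA across chronological stages
#'
#' Splits the survey years into stages and tests, per region, whether the
#' stage means of a station statistic differ, using explicit between/within
#' sums of squares: F = (SSB/(k-1)) / (SSW/(N-k)), p from the F distribution.
#' Regions with fewer than 2 populated stages, or fewer than 2 stations in
#' every populated stage, are returned flagged (\code{ok = FALSE}) rather
#' than raising an error.
#'
#' @param years integer vector of sampling years.
#' @param values numeric station statistic (e.g. total concentration).
#' @param regions region labels (optional; a single pooled test if NULL).
#' @param stages list of c(start, end) year pairs, default the three
#'   chronological stages 1990-2000, 2001-2011, 2012-2022.
#' @return data.frame: \code{region}, \code{F}, \code{p}, \code{df1},
#'   \code{df2}, \code{ok}.
#' @export
chronology_anova <- function(years, values, regions = NULL,
                             stages = list(c(1990, 2000), c(2001, 2011),
                                           c(2012, 2022))) {
  stopifnot(length(years) == length(values))
  if (is.null(regions)) regions <- rep("all", length(years))
  stage_of <- function(y) {
    for (i in seq_along(stages))
      if (y >= stages[[i]][1] && y <= stages[[i]][2]) return(i)
    NA_integer_
  }
  st <- vapply(years, stage_of, integer(1))
  res <- lapply(split(seq_along(values), regions), function(idx) {
    v <- values[idx]; s <- st[idx]
    keep <- !is.na(s)
    v <- v[keep]; s <- s[keep]
    tab <- table(s)
    if (length(tab) < 2L || sum(tab >= 2L) < 2L || length(v) - length(tab) < 1L)
      return(data.frame(F = NA_real_, p = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_, ok = FALSE))
    groups <- split(v, s)
    grand <- mean(v)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
    df1 <- length(groups) - 1L
    df2 <- length(v) - length(groups)
    f <- if (ssw == 0) {
      if (ssb == 0) 0 else Inf
    } else (ssb / df1) / (ssw / df2)
    p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
    data.frame(F = f, p = p, df1 = df1, df2 = df2, ok = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(region = names(res), out)
  rownames(out) <- NULL
  out
}

#' Projected carbon-fixation loss from coastal productivity inhibition
#'
#' Desk arithmetic for the global extrapolation: if coastal waters contribute
#' a share \code{coastal_share} of global marine primary production
#' \code{global_pp} (tonnes C per year) and herbicides depress coastal
#' productivity by \code{inhibition} (fraction), the annual carbon-fixation
#' loss is \code{inhibition * coastal_share * global_pp}.
#'
#' @param global_pp global marine primary production, t C/yr (vectorised;
#'   default the 3e10-7e10 literature range).
#' @param coastal_share coastal fraction of global production (default 0.25).
#' @param inhibition productivity inhibition fraction (default 0.05).
#' @return carbon loss in t C/yr, same length as \code{global_pp}.
#' @export
carbon_loss <- function(global_pp = c(3e10, 7e10), coastal_share = 0.25,
                        inhibition = 0.05) {
  stopifnot(is.numeric(global_pp), all(global_pp > 0),
            coastal_share > 0, coastal_share <= 1,
            inhibition >= 0, inhibition <= 1)
  inhibition * coastal_share * global_pp
}
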