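## Dilution method (Landry-Hassett): seawater incubated at graded dilutions
## D with particle-free water. Phytoplankton biomass follows
## P_t = P_0 exp((mu - D g) t), so the apparent growth rate
## k(D) = ln(P_t/P_0)/t is linear in D: intercept mu (intrinsic growth),
## negative slope g (micro-zooplankton grazing mortality). Net growth rate
## NGR = mu - g.

#' Apparent growth rate of one incubation
#'
#' k = ln(Pt/P0) / t, in per day.
#'
#' @param P0 initial biomass (chlorophyll units), > 0. Vectorised.
#' @param Pt final biomass, > 0.
#' @param t incubation duration in days, > 0.
#' @return apparent growth rate(s), d^-1.
#' @export
apparent_growth <- function(P0, Pt, t) {
  if (any(!is.finite(P0)) || any(P0 <= 0) ||
      any(!is.finite(Pt)) || any(Pt <= 0) ||
      any(!is.finite(t)) || any(t <= 0))
    stop("P0, Pt and t must all be finite and > 0")
  log(Pt / P0) / t
}

#' Estimate growth and grazing rates from a dilution series
#'
#' Ordinary least squares of the apparent growth rate on the dilution
#' fraction. Replicates enter as individual points. mu is the intercept,
#' g the negative of the slope, NGR = mu - g. A negative estimated grazing
#' rate ("inverse grazing") is reported as-is and flagged.
#'
#' @param series data.frame with columns \code{dilution} (in (0, 1]),
#'   \code{P0}, \code{Pt}, \code{t_days}; optional \code{replicate} and
#'   \code{size_class} (ignored here; see
#'   \code{\link{estimate_rates_by_class}}).
#' @return object of class \code{rate_estimates}: list with \code{mu},
#'   \code{g}, \code{ngr}, \code{se_mu}, \code{se_g}, \code{r_squared},
#'   \code{n}, \code{inverse_grazing}.
#' @export
estimate_rates <- function(series) {
  series <- validate_dilution(series)
  k <- apparent_growth(series$P0, series$Pt, series$t_days)
  d <- series$dilution
  fit <- stats::lm(k ~ d)
  cf <- stats::coef(fit)
  ## noiseless series give an exact fit; summary.lm warns about it, which is
  ## expected for simulated data
  sm <- suppressWarnings(summary(fit))
  mu <- unname(cf[1])
  g <- unname(-cf[2])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((k - mean(k))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(mu = mu, g = g, ngr = mu - g,
                 se_mu = unname(sm$coefficients[1, 2]),
                 se_g = unname(sm$coefficients[2, 2]),
                 r_squared = r2, n = length(k),
                 inverse_grazing = g < 0),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("<rate_estimates: mu = %.4g, g = %.4g, NGR = %.4g (r2 = %.4g, n = %d)%s>\n",
              x$mu, x$g, x$ngr, x$r_squared, x$n,
              if (isTRUE(x$inverse_grazing)) " [inverse grazing]" else ""))
  invisible(x)
}

validate_dilution <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("dilution", "P0", "Pt", "t_days") %in% names(series)))
  d <- series$dilution
  if (any(!is.finite(d)) || any(d <= 0) || any(d > 1))
    stop("dilution fractions must lie in (0, 1]")
  if (length(unique(d)) < 2L)
    stop("need >= 2 distinct dilution levels (singular design)")
  if (any(series$P0 <= 0) || any(series$Pt <= 0) || any(series$t_days <= 0))
    stop("P0, Pt and t_days must be > 0")
  series
}

#' Per-size-class rate estimates
#'
#' Applies \code{\link{estimate_rates}} within each level of
#' \code{size_class} and returns a tidy table matching the package's
#' delimited-text output schema.
#'
#' @param series data.frame as in \code{\link{estimate_rates}}, with a
#'   \code{size_class} column.
#' @return data.frame: \code{size_class, mu, g, ngr, se_mu, se_g, r2}.
#' @export
estimate_rates_by_class <- function(series) {
  stopifnot("size_class" %in% names(series))
  res <- lapply(split(series, series$size_class), function(s) {
    e <- estimate_rates(s)
    data.frame(mu = e$mu, g = e$g, ngr = e$ngr,
               se_mu = e$se_mu, se_g = e$se_g, r2 = e$r_squared)
  })
  out <- do.call(rbind, res)
  out <- cbind(size_class = names(res), out)
  rownames(out) <- NULL
  out
}

#' Simulate a dilution series
#'
#' Generates incubation outcomes from the exponential dilution model
#' \code{Pt = P0 * exp((mu - D g) t)}, with optional multiplicative
#' lognormal measurement noise on Pt (chlorophyll readings are positive and
#' right-skewed). Deterministic under a fixed seed.
#'
#' @param mu intrinsic growth rate, d^-1.
#' @param g grazing mortality rate, d^-1.
#' @param t incubation duration in days (default 1: 24 h incubation).
#' @param dilutions dilution fractions in (0, 1]; default the five standard
#'   target dilutions 100/80/60/40/20\%.
#' @param P0 initial biomass (default 1).
#' @param reps replicates per dilution level (default 3).
#' @param noise_sd standard deviation of the log-scale noise (0 = noiseless).
#' @param seed integer seed (used only when noise_sd > 0).
#' @param size_class label carried into the output (default "nano").
#' @return data.frame: \code{size_class, dilution, replicate, P0, Pt,
#'   t_days}.
#' @export
simulate_series <- function(mu, g, t = 1, dilutions = c(1, 0.8, 0.6, 0.4, 0.2),
                            P0 = 1, reps = 3L, noise_sd = 0, seed = 1L,
                            size_class = "nano") {
  stopifnot(is.finite(mu), is.finite(g), t > 0, P0 > 0, reps >= 1,
            noise_sd >= 0)
  if (length(dilutions) == 0L) stop("empty dilution set")
  if (any(dilutions <= 0) || any(dilutions > 1))
    stop("dilution fractions must lie in (0, 1]")
  d <- rep(dilutions, each = reps)
  pt <- P0 * exp((mu - d * g) * t)
  if (noise_sd > 0)
    pt <- withr_seed(seed, pt * stats::rlnorm(length(pt), 0, noise_sd))
  data.frame(size_class = size_class, dilution = d,
             replicate = rep(seq_len(reps), times = length(dilutions)),
             P0 = P0, Pt = pt, t_days = t)
}

#' Read / write dilution-series tables
#'
#' Delimited text with header
#' \code{size_class,dilution,replicate,P0,Pt,t_days}.
#' @param path file path.
#' @return data.frame.
#' @export
read_dilution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dilution(df)
}

#' @rdname read_dilution
#' @param series dilution-series data.frame.
#' @export
write_dilution <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
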