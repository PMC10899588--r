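#' Construct a sigmoid concentration-response model
#'
#' A fitted (or hypothesised) concentration-response curve for a single
#' substance or for the phytoplankton community. Two families are supported,
#' both parameterised on the log10 concentration scale:
#' \describe{
#'   \item{logistic}{\eqn{E(c) = \theta_{max} / (1 + \exp(-(\alpha + \beta \log_{10} c)))}}
#'   \item{weibull}{\eqn{E(c) = \theta_{max} (1 - \exp(-\exp(\alpha + \beta \log_{10} c)))}}
#' }
#' Both are strictly increasing in concentration for \code{beta > 0}, tend to
#' 0 as concentration tends to 0 and to \code{theta_max} as concentration
#' grows without bound.
#'
#' @param family "logistic" or "weibull".
#' @param theta_max maximal effect fraction, in (0, 1].
#' @param alpha location parameter on the log10-concentration scale.
#' @param beta slope parameter, must be > 0.
#' @return an object of class \code{response_model}.
#' @examples
#' m <- response_model("logistic", theta_max = 1, alpha = -1, beta = 1)
#' effect_at(m, 10)   # 0.5: alpha + beta*log10(10) = 0 is the midpoint
#' ecx(m, 0.5)        # 10
#' @export
response_model <- function(family = c("logistic", "weibull"),
                           theta_max, alpha, beta) {
  family <- match.arg(family)
  stopifnot(is.numeric(theta_max), length(theta_max) == 1L,
            is.finite(theta_max), theta_max > 0, theta_max <= 1,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0) stop("'beta' must be > 0 (monotone increasing curve)")
  structure(list(family = family, theta_max = theta_max,
                 alpha = alpha, beta = beta),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model: %s>\n  theta_max = %g, alpha = %g, beta = %g\n  EC50 = %g\n",
              x$family, x$theta_max, x$alpha, x$beta, ecx(x, x$theta_max / 2)))
  invisible(x)
}

#' Predicted effect at a concentration
#'
#' Evaluates a \code{\link{response_model}} at one or more concentrations.
#' The limit at concentration 0 is handled explicitly and returns 0.
#'
#' @param model a \code{response_model}.
#' @param concentration numeric vector of concentrations (nmol/L), all >= 0.
#' @return inhibition fraction(s) in [0, theta_max).
#' @export
effect_at <- function(model, concentration) {
  stopifnot(inherits(model, "response_model"), is.numeric(concentration))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0")
  out <- numeric(length(concentration))
  pos <- concentration > 0
  if (any(pos)) {
    z <- model$alpha + model$beta * log10(concentration[pos])
    out[pos] <- switch(model$family,
      logistic = model$theta_max * stats::plogis(z),
      weibull  = model$theta_max * (1 - exp(-exp(z))))
  }
  out
}

#' Effect concentration (ECx): invert a response model
#'
#' Closed-form inversion of the logistic or Weibull curve at effect level
#' \code{x}. \code{effect_at(model, ecx(model, x))} equals \code{x} to
#' relative tolerance 1e-9 by construction.
#'
#' @param model a \code{response_model}.
#' @param x effect fraction(s), each strictly between 0 and
#'   \code{model$theta_max}.
#' @return concentration(s) in nmol/L.
#' @export
ecx <- function(model, x) {
  stopifnot(inherits(model, "response_model"), is.numeric(x))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= model$theta_max))
    stop(sprintf("effect level must lie strictly between 0 and theta_max = %g",
                 model$theta_max))
  p <- x / model$theta_max
  z <- switch(model$family,
    logistic = stats::qlogis(p),
    weibull  = log(-log(1 - p)))
  10^((z - model$alpha) / model$beta)
}

## ---- fitting ---------------------------------------------------------------

#' Fit a concentration-response model by nonlinear least squares
#'
#' Fits one model family to inhibition data in effect space. Responses are
#' expected to be inhibition fractions relative to the control (zero
#' concentration rows are excluded from the fit; they carry no information
#' once responses are control-normalised). Because sigmoid least-squares
#' surfaces are multimodal, the optimiser is seeded from the best point of a
#' coarse grid over (theta_max, alpha, beta) and refined with box-constrained
#' quasi-Newton iterations.
#'
#' @param data data.frame with columns \code{concentration} (nmol/L, >= 0)
#'   and \code{response} (inhibition fraction). A \code{replicate} column is
#'   allowed and ignored by the fit.
#' @param family "logistic" or "weibull".
#' @return an object of class \code{drc_fit} with elements \code{model}
#'   (a \code{response_model}, or NULL if not converged), \code{rss},
#'   \code{aic}, \code{n_points} and \code{converged}.
#' @export
fit_model <- function(data, family = c("logistic", "weibull")) {
  family <- match.arg(family)
  data <- validate_plate_points(data)
  fitdat <- data[data$concentration > 0, , drop = FALSE]
  if (length(unique(fitdat$concentration)) < 4L)
    stop("need >= 4 distinct nonzero concentrations to fit a 3-parameter curve")

  y <- fitdat$response
  lc <- log10(fitdat$concentration)
  n <- length(y)

  ## degenerate flat data: no identifiable curve
  if (diff(range(y)) < 0.01)
    return(new_drc_fit(NULL, rss = sum((y - mean(y))^2),
                       aic = NA_real_, n_points = n, converged = FALSE))

  obj <- function(par) {
    m <- list(family = family, theta_max = par[1], alpha = par[2], beta = par[3])
    z <- m$alpha + m$beta * lc
    mu <- switch(family,
      logistic = m$theta_max * stats::plogis(z),
      weibull  = m$theta_max * (1 - exp(-exp(z))))
    sum((y - mu)^2)
  }

  ## coarse grid seed
  grid <- expand.grid(theta_max = c(0.6, 0.8, 1.0),
                      alpha = seq(-6, 6, by = 0.5),
                      beta = c(0.5, 1, 2, 4))
  gvals <- apply(grid, 1L, obj)
  start <- as.numeric(grid[which.min(gvals), ])

  lower <- c(1e-3, -30, 1e-3)
  upper <- c(1, 30, 50)
  opt <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500L, factr = 1e4)),
    error = function(e) NULL)
  ## polish with Nelder-Mead from the L-BFGS-B solution (cheap insurance
  ## against premature line-search termination on flat valleys)
  if (!is.null(opt)) {
    opt2 <- tryCatch(stats::optim(opt$par, function(p) {
      p <- pmin(pmax(p, lower), upper); obj(p)
    }, control = list(maxit = 2000L, reltol = 1e-14)), error = function(e) NULL)
    if (!is.null(opt2) && opt2$value < opt$value) {
      opt2$par <- pmin(pmax(opt2$par, lower), upper)
      opt <- opt2
    }
  }
  if (is.null(opt) || !is.finite(opt$value))
    return(new_drc_fit(NULL, rss = NA_real_, aic = NA_real_,
                       n_points = n, converged = FALSE))

  par <- opt$par
  model <- response_model(family, theta_max = par[1], alpha = par[2], beta = par[3])
  rss <- opt$value
  k <- 3L
  aic <- n * log(max(rss, 1e-300) / n) + 2 * (k + 1)
  new_drc_fit(model, rss = rss, aic = aic, n_points = n, converged = TRUE)
}

new_drc_fit <- function(model, rss, aic, n_points, converged) {
  structure(list(model = model, rss = rss, aic = aic,
                 n_points = n_points, converged = converged),
            class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<drc_fit: %s, rss = %.4g, aic = %.4g, n = %d>\n",
                x$model$family, x$rss, x$aic, x$n_points))
  } else {
    cat(sprintf("<drc_fit: NOT CONVERGED, n = %d>\n", x$n_points))
  }
  invisible(x)
}

validate_plate_points <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  conc <- data$concentration
  resp <- data$response
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  if (any(!is.finite(resp)))
    stop("responses must be finite")
  if (any(resp < -0.1) || any(resp > 1.1))
    stop("responses outside [-0.1, 1.1] look like data errors; check normalisation")
  data
}

#' Fit both model families and keep the best by AIC
#'
#' Fits every requested family with \code{\link{fit_model}} and returns the
#' converged fit with the lowest AIC. Ties (AIC difference below 1e-9) are
#' broken toward the logistic family.
#'
#' @param data as in \code{\link{fit_model}}.
#' @param families character vector of families to try.
#' @return a \code{drc_fit}.
#' @export
select_best <- function(data, families = c("logistic", "weibull")) {
  fits <- lapply(families, function(f) fit_model(data, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no model family converged on these data")
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ## stable tie-break: logistic wins exact/near ties because families
  ## are ordered and which.min takes the first minimum
  ord <- order(match(names(fits), c("logistic", "weibull")))
  fits <- fits[ord]; aics <- aics[ord]
  fits[[which.min(round(aics / 1e-9) * 1e-9)]]
}
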