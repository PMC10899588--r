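## Concentration-addition (CA) mixture toxicity and toxic-equivalence
## normalisation. Under CA, a mixture sits at effect level x* when the toxic
## units sum to one:
##
##   sum_i c_i / ECx_i(x*) = 1
##
## where c_i is the concentration of component i and ECx_i(x) its effect
## concentration at level x. The equi-effective concentration of the
## reference substance (atrazine) is then ECx_ref(x*): the TEQ.

#' Toxic units of a mixture at a chosen effect level
#'
#' TU_i = c_i / ECx_i(x). Components with zero concentration get TU 0.
#'
#' @param sample named numeric vector of concentrations (nmol/L, >= 0);
#'   names are herbicide identifiers resolvable in \code{db}.
#' @param db a \code{\link{curve_db}}.
#' @param x effect fraction, 0 < x < min theta_max over components present.
#' @return named numeric vector of toxic units.
#' @export
toxic_units <- function(sample, db, x = 0.5) {
  sample <- validate_mixture(sample, db)
  if (length(sample) == 0L) return(stats::setNames(numeric(0), character(0)))
  tu <- vapply(names(sample), function(h) {
    ci <- sample[[h]]
    if (ci == 0) return(0)
    ci / ecx(db$curves[[h]], x)
  }, numeric(1))
  tu
}

validate_mixture <- function(sample, db) {
  stopifnot(is.numeric(sample))
  if (length(sample) && is.null(names(sample)))
    stop("mixture sample must be a named vector of concentrations")
  if (any(!is.finite(sample)) || any(sample < 0))
    stop("concentrations must be finite and >= 0")
  missing <- setdiff(names(sample), names(db$curves))
  if (length(missing))
    stop("herbicides absent from the curve database: ",
         paste(missing, collapse = ", "))
  sample
}

#' Mixture effect level under concentration addition
#'
#' Solves \eqn{\sum_i c_i / ECx_i(x^*) = 1} for the effect level \eqn{x^*} by
#' bisection on \eqn{x \in (10^{-8}, \min_i \theta_{max,i} - 10^{-8})} to an
#' absolute tolerance of 1e-10. The toxic-unit sum is strictly decreasing in
#' x (ECx increases with x), so the root is unique. If even at the upper end
#' of the bracket the toxic units exceed one, the mixture effect lies in the
#' saturation zone above some component's maximal effect; the upper bracket
#' value is returned with attribute \code{saturated = TRUE} and a warning.
#'
#' @inheritParams toxic_units
#' @return effect fraction x* (0 for the all-zero sample), with attribute
#'   \code{saturated} (logical).
#' @export
mixture_effect_ca <- function(sample, db) {
  sample <- validate_mixture(sample, db)
  active <- sample[sample > 0]
  if (length(active) == 0L) return(structure(0, saturated = FALSE))
  tmax <- min(vapply(names(active), function(h) db$curves[[h]]$theta_max, 1))
  lo <- 1e-8
  hi <- tmax - 1e-8
  tu_sum <- function(x) sum(toxic_units(active, db, x))
  if (tu_sum(hi) > 1) {
    warning("mixture effect exceeds the attainable maximum of a component; ",
            "returning the saturation bound")
    return(structure(hi, saturated = TRUE))
  }
  ## tu_sum(lo) > 1 whenever any c_i > 0 and lo is small enough; guard anyway
  if (tu_sum(lo) < 1) return(structure(lo, saturated = FALSE))
  ## bisect to absolute tolerance 1e-10, then keep halving until the
  ## bracket is also relatively tight: at small effect levels the
  ## toxic-unit sum is steep in x and absolute tolerance alone would
  ## leave a visible residual in sum(TU) - 1
  iter <- 0L
  while ((hi - lo > 1e-10 || (hi - lo) > 1e-12 * lo) && iter < 200L) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # double resolution exhausted
    if (tu_sum(mid) > 1) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  structure((lo + hi) / 2, saturated = FALSE)
}

#' Equi-effective atrazine concentration (TEQ) of a mixture
#'
#' TEQ = ECx of the reference curve at the mixture's CA effect level. A
#' sample containing only the reference substance at concentration c has
#' TEQ c (self-consistency of concentration addition).
#'
#' @inheritParams toxic_units
#' @return TEQ in nmol/L (0 for the all-zero sample); attribute
#'   \code{saturated} propagated from \code{\link{mixture_effect_ca}}.
#' @export
teq_atrazine <- function(sample, db) {
  x <- mixture_effect_ca(sample, db)
  if (x == 0) return(structure(0, saturated = FALSE))
  structure(ecx(db$curves[[db$reference]], as.numeric(x)),
            saturated = attr(x, "saturated"))
}

#' Fixed-ratio TEF approximation of the TEQ
#'
#' \eqn{\sum_i c_i \cdot EC50_{ref} / EC50_i}: each component is weighted by
#' its EC50-based toxic equivalency factor. Exact (equal to
#' \code{\link{teq_atrazine}}) when every curve is a parallel shift of the
#' reference on the log-concentration scale; an approximation otherwise.
#'
#' @inheritParams toxic_units
#' @return approximate TEQ in nmol/L.
#' @export
teq_tef_approx <- function(sample, db) {
  sample <- validate_mixture(sample, db)
  if (length(sample) == 0L) return(0)
  ref <- db$curves[[db$reference]]
  ec50_ref <- ecx(ref, ref$theta_max / 2)
  sum(vapply(names(sample), function(h) {
    ci <- sample[[h]]
    if (ci == 0) return(0)
    m <- db$curves[[h]]
    ci * ec50_ref / ecx(m, m$theta_max / 2)
  }, numeric(1)))
}
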