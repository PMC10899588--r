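## Community-level inhibition curve. The community concentration-response
## relationship is defined by its printed calibration anchors: atrazine at
## 5.1, 11.9 and 35.2 nmol/L inhibits community chlorophyll-a by 5%, 10% and
## 25%. The curve is the monotone shape-preserving interpolant through the
## anchors in (log10 concentration, logit inhibition-fraction) space --
## exact at every anchor, strictly monotone, logit-linear beyond the outer
## anchors, with predictions clamped to [0, 99.9]%.

#' Default community-curve anchors
#'
#' Atrazine concentrations (nmol/L) and the community chlorophyll-a
#' inhibition they produce (percent).
#' @return data.frame with columns \code{conc} and \code{inhibition}.
#' @export
default_anchors <- function() {
  data.frame(conc = c(5.1, 11.9, 35.2), inhibition = c(5, 10, 25))
}

#' Build the community inhibition curve from anchors
#'
#' @param anchors data.frame with columns \code{conc} (nmol/L, > 0, strictly
#'   increasing) and \code{inhibition} (percent in (0, 100), strictly
#'   increasing). At least two anchors.
#' @return object of class \code{community_curve}.
#' @export
build_community_curve <- function(anchors = default_anchors()) {
  stopifnot(is.data.frame(anchors),
            all(c("conc", "inhibition") %in% names(anchors)))
  conc <- anchors$conc
  inh <- anchors$inhibition
  if (length(conc) < 2L) stop("need at least 2 anchors")
  if (any(!is.finite(conc)) || any(conc <= 0) ||
      any(!is.finite(inh)) || any(inh <= 0) || any(inh >= 100))
    stop("anchor concentrations must be > 0 and inhibitions in (0, 100)%")
  if (any(diff(conc) <= 0) || any(diff(inh) <= 0))
    stop("anchors must be strictly increasing in both concentration and inhibition")
  x <- log10(conc)
  y <- stats::qlogis(inh / 100)
  if (length(x) == 2L) {
    slope <- diff(y) / diff(x)
    fwd <- function(xx) y[1] + slope * (xx - x[1])
    slopes <- c(slope, slope)
  } else {
    sp <- stats::splinefun(x, y, method = "monoH.FC")
    slopes <- c(sp(x[1], deriv = 1L), sp(x[length(x)], deriv = 1L))
    fwd <- function(xx) {
      out <- sp(xx)
      lo <- xx < x[1]
      hi <- xx > x[length(x)]
      out[lo] <- y[1] + slopes[1] * (xx[lo] - x[1])
      out[hi] <- y[length(y)] + slopes[2] * (xx[hi] - x[length(x)])
      out
    }
  }
  structure(list(anchors = data.frame(conc = conc, inhibition = inh),
                 x = x, y = y, fwd = fwd, slopes = slopes),
            class = "community_curve")
}

#' @export
print.community_curve <- function(x, ...) {
  cat("<community_curve>\n  anchors:\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Predict community inhibition from an atrazine-equivalent concentration
#'
#' @param object a \code{community_curve}.
#' @param conc numeric vector of TEQ concentrations (nmol/L, >= 0).
#' @param ... unused.
#' @return inhibition percentages in [0, 99.9]. Concentration 0 maps to 0.
#' @export
predict.community_curve <- function(object, conc, ...) {
  stopifnot(is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  out <- numeric(length(conc))
  pos <- conc > 0
  if (any(pos)) {
    inh <- 100 * stats::plogis(object$fwd(log10(conc[pos])))
    out[pos] <- pmin(pmax(inh, 0), 99.9)
  }
  ## exact anchor reproduction regardless of interpolant round-off
  m <- match(conc, object$anchors$conc)
  hit <- !is.na(m)
  out[hit] <- object$anchors$inhibition[m[hit]]
  out
}

#' Invert the community curve: concentration producing a given inhibition
#'
#' @param curve a \code{community_curve}.
#' @param inhibition percent in (0, 99.9), vectorised.
#' @return TEQ concentration(s) in nmol/L.
#' @export
community_curve_invert <- function(curve, inhibition) {
  stopifnot(inherits(curve, "community_curve"), is.numeric(inhibition))
  if (any(!is.finite(inhibition)) || any(inhibition <= 0) || any(inhibition >= 99.9))
    stop("inhibition must lie in (0, 99.9) percent")
  vapply(inhibition, function(p) {
    i <- match(p, curve$anchors$inhibition)
    if (!is.na(i)) return(curve$anchors$conc[i])  # anchors exact
    ytarg <- stats::qlogis(p / 100)
    g <- function(xx) curve$fwd(xx) - ytarg
    ## monotone in x; expand a bracket around the anchor range
    lo <- curve$x[1] - 1; hi <- curve$x[length(curve$x)] + 1
    while (g(lo) > 0) lo <- lo - 1
    while (g(hi) < 0) hi <- hi + 1
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-13)
    10^r$root
  }, numeric(1))
}
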