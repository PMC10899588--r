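## Curve database: a named collection of fitted concentration-response
## curves plus the reference substance used for toxic-equivalence
## normalisation. Persisted as versioned tab-delimited text.

CURVE_DB_SCHEMA <- "herbimpact_curve_db v1"

#' Build a herbicide curve database
#'
#' @param curves named list; each element a \code{response_model} or a
#'   \code{drc_fit} (converged). Names are herbicide identifiers and must be
#'   unique.
#' @param reference name of the reference substance (default "atrazine");
#'   must be present in \code{curves}.
#' @return object of class \code{curve_db}: list with \code{curves} (named
#'   list of \code{response_model}), \code{stats} (data.frame of rss/aic,
#'   NA where unknown) and \code{reference}.
#' @export
curve_db <- function(curves, reference = "atrazine") {
  stopifnot(is.list(curves), length(names(curves)) == length(curves))
  if (anyDuplicated(names(curves)))
    stop("duplicate herbicide names in curve database: ",
         paste(unique(names(curves)[duplicated(names(curves))]), collapse = ", "))
  models <- lapply(curves, function(cv) {
    if (inherits(cv, "drc_fit")) {
      if (!isTRUE(cv$converged)) stop("cannot store a non-converged fit")
      cv$model
    } else if (inherits(cv, "response_model")) cv
    else stop("curves must be response_model or drc_fit objects")
  })
  stats <- data.frame(
    herbicide = names(curves),
    rss = vapply(curves, function(cv) if (inherits(cv, "drc_fit")) cv$rss else NA_real_, 1),
    aic = vapply(curves, function(cv) if (inherits(cv, "drc_fit")) cv$aic else NA_real_, 1),
    row.names = NULL)
  if (length(models) && !reference %in% names(models))
    stop("reference substance '", reference, "' not present in curves")
  structure(list(curves = models, stats = stats, reference = reference),
            class = "curve_db")
}

#' @export
print.curve_db <- function(x, ...) {
  cat(sprintf("<curve_db: %d curves, reference = %s>\n",
              length(x$curves), x$reference))
  invisible(x)
}

#' Write a curve database to disk
#'
#' Tab-delimited text with a schema-version header line. Numeric fields are
#' written with 17 significant digits so that a write/read round trip
#' reproduces parameters bitwise.
#'
#' @param db a \code{curve_db}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
curve_db_write <- function(db, path) {
  stopifnot(inherits(db, "curve_db"))
  fmt <- function(v) sprintf("%.17g", v)
  rows <- vapply(names(db$curves), function(h) {
    m <- db$curves[[h]]
    s <- db$stats[db$stats$herbicide == h, , drop = FALSE]
    paste(h, m$family, fmt(m$theta_max), fmt(m$alpha), fmt(m$beta),
          fmt(s$rss), fmt(s$aic), sep = "\t")
  }, character(1))
  lines <- c(paste0("# ", CURVE_DB_SCHEMA),
             paste0("# reference\t", db$reference),
             paste("herbicide", "family", "theta_max", "alpha", "beta",
                   "rss", "aic", sep = "\t"),
             rows)
  writeLines(lines, path)
  invisible(path)
}

#' Read a curve database from disk
#'
#' @param path file written by \code{\link{curve_db_write}}.
#' @return a \code{curve_db}.
#' @export
curve_db_read <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(lines[[1]], paste0("# ", CURVE_DB_SCHEMA)))
    stop("not a recognised curve database (missing schema tag '",
         CURVE_DB_SCHEMA, "')")
  ref <- sub("^# reference\t", "", lines[[2]])
  num <- function(s, what, h) {
    if (identical(s, "NA")) return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop("non-numeric ", what, " '", s, "' for herbicide '", h, "'")
    v
  }
  body <- lines[-(1:3)]
  curves <- list()
  stats_rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 7L) stop("malformed curve database row: ", ln)
    h <- f[[1]]; fam <- f[[2]]
    if (!fam %in% c("logistic", "weibull"))
      stop("unknown model family tag '", fam, "' for herbicide '", h, "'")
    if (h %in% names(curves))
      stop("duplicate herbicide names in curve database: ", h)
    curves[[h]] <- response_model(fam, num(f[[3]], "theta_max", h),
                                  num(f[[4]], "alpha", h),
                                  num(f[[5]], "beta", h))
    stats_rows[[h]] <- c(num(f[[6]], "rss", h), num(f[[7]], "aic", h))
  }
  db <- curve_db(curves, reference = ref)
  if (length(stats_rows)) {
    db$stats$rss <- vapply(stats_rows, `[[`, 1, 1L)
    db$stats$aic <- vapply(stats_rows, `[[`, 1, 2L)
  }
  db
}
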