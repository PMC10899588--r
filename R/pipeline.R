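## Pipeline entry points tying the stages together over the delimited-text
## interchange formats. Each function reads its inputs, runs one stage, and
## writes its outputs; together they reproduce the end-to-end analysis:
## simulate -> fit curves -> map impact (+ dilution and risk side chains).

#' Derive per-stage seeds from one reproducibility seed
#'
#' One user-facing seed fans out to independent, documented per-stage seeds:
#' \code{(seed + 7919 * k) mod (2^31 - 1)} for stage index k (7919 is the
#' 1000th prime; the modulus keeps seeds in R's integer range).
#'
#' @param seed integer master seed.
#' @return named integer vector with elements survey, plate, dilution, grid,
#'   bootstrap.
#' @export
derive_seeds <- function(seed) {
  stages <- c("survey", "plate", "dilution", "grid", "bootstrap")
  s <- (as.numeric(seed) + 7919 * seq_along(stages)) %% (2^31 - 1)
  stats::setNames(as.integer(s), stages)
}

#' Fit per-herbicide curves from a plate table and write the curve database
#'
#' @param plate_file CSV plate table (schema of \code{\link{read_plate}}).
#' @param out_db output path for the curve database.
#' @param reference reference substance name (default "atrazine").
#' @return the \code{\link{curve_db}}, invisibly.
#' @export
pipeline_fit_curves <- function(plate_file, out_db, reference = "atrazine") {
  plate <- read_plate(plate_file)
  fits <- lapply(split(plate, plate$herbicide), select_best)
  db <- curve_db(fits, reference = reference)
  curve_db_write(db, out_db)
  invisible(db)
}

#' Map survey residues to TEQ and inhibition; write station, regional and
#' exceedance reports
#'
#' @param survey_file CSV survey table (schema of \code{\link{read_survey}}).
#' @param db_file curve-database file.
#' @param out_dir output directory (created if needed). Writes
#'   \code{stations.csv}, \code{regions.csv}, \code{exceedance.csv} and
#'   \code{anova.csv}.
#' @param anchors community-curve anchors (default the calibration anchors).
#' @param thresholds exceedance thresholds in percent.
#' @param B bootstrap resamples for regional CIs.
#' @param seed seed for the bootstrap.
#' @return list of the four result data.frames, invisibly.
#' @export
pipeline_map_impact <- function(survey_file, db_file, out_dir,
                                anchors = default_anchors(),
                                thresholds = c(5, 10, 25),
                                B = 2000L, seed = 1L) {
  survey <- read_survey(survey_file)
  db <- curve_db_read(db_file)
  curve <- build_community_curve(anchors)
  stations <- station_inhibition(survey, db, curve)
  regions <- summarize_region(stations$region, stations$inhibition,
                              B = B, seed = seed)
  exc <- exceedance(stations$inhibition, thresholds)
  totals <- rowSums(survey[, survey_herbicides(survey), drop = FALSE])
  anova <- chronology_anova(survey$year, totals, survey$region)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(stations, file.path(out_dir, "stations.csv"), row.names = FALSE)
  utils::write.csv(regions, file.path(out_dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(exc, file.path(out_dir, "exceedance.csv"), row.names = FALSE)
  utils::write.csv(anova, file.path(out_dir, "anova.csv"), row.names = FALSE)
  invisible(list(stations = stations, regions = regions,
                 exceedance = exc, anova = anova))
}

#' Estimate growth/grazing rates per size class from a dilution table
#'
#' @param series_file CSV dilution table (schema of
#'   \code{\link{read_dilution}}).
#' @param out_file output CSV (\code{size_class,mu,g,ngr,se_mu,se_g,r2}).
#' @return the estimates data.frame, invisibly.
#' @export
pipeline_dilution <- function(series_file, out_file) {
  series <- read_dilution(series_file)
  est <- if ("size_class" %in% names(series))
    estimate_rates_by_class(series)
  else {
    e <- estimate_rates(series)
    data.frame(size_class = "all", mu = e$mu, g = e$g, ngr = e$ngr,
               se_mu = e$se_mu, se_g = e$se_g, r2 = e$r_squared)
  }
  utils::write.csv(est, out_file, row.names = FALSE)
  invisible(est)
}

#' Score grid cells and write per-cell and per-region risk tables
#'
#' @param cell_file CSV cell table.
#' @param props_file CSV properties table.
#' @param out_file output CSV of per-cell results
#'   (\code{cell_id,region,sum_RQ,RP,class}); a companion
#'   \code{<out_file>_regions.csv} carries the area-weighted class fractions.
#' @param horizon_days integration horizon (default 365).
#' @param compartment "max", "soil" or "water".
#' @return list(cells, regions), invisibly.
#' @export
pipeline_risk <- function(cell_file, props_file, out_file,
                          horizon_days = 365, compartment = "max") {
  cells <- read_cells(cell_file)
  props <- read_props(props_file)
  res <- risk_point(cells, props, horizon_days, compartment)
  reg <- summarize_risk_map(res$cells)
  utils::write.csv(res$cells, out_file, row.names = FALSE)
  utils::write.csv(reg, paste0(sub("\\.csv$", "", out_file), "_regions.csv"),
                   row.names = FALSE)
  invisible(list(cells = res$cells, regions = reg))
}

#' Run the synthetic-data generators from a config
#'
#' @param config either a YAML file path or a list with optional entries
#'   \code{seed} (master seed, default 1), \code{teq_q3} (if set, the survey
#'   is TEQ-calibrated to this third quartile), \code{plate_noise_sd},
#'   \code{dilution} (list of mu/g per size class) and \code{n_cells}.
#' @param out_dir output directory; writes \code{survey.csv},
#'   \code{plate.csv}, \code{dilution.csv}, \code{cells.csv},
#'   \code{props.csv} and \code{curves.db}.
#' @return character vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config = list(), out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  seeds <- derive_seeds(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  db <- default_curve_db()
  curve_db_write(db, file.path(out_dir, "curves.db"))

  survey <- gen_survey(survey_spec(), seed = seeds[["survey"]])
  if (!is.null(config$teq_q3))
    survey <- calibrate_survey_teq(survey, db, target_q3 = config$teq_q3)
  write_survey(survey, file.path(out_dir, "survey.csv"))

  noise <- if (is.null(config$plate_noise_sd)) 0.02 else config$plate_noise_sd
  plates <- do.call(rbind, lapply(seq_along(db$curves), function(i) {
    gen_plate(db$curves[[i]], noise_sd = noise,
              seed = seeds[["plate"]] + i, herbicide = names(db$curves)[i])
  }))
  write_plate(plates, file.path(out_dir, "plate.csv"))

  dil_cfg <- config$dilution
  if (is.null(dil_cfg))
    dil_cfg <- list(micro = list(mu = 0.65, g = 0.40),
                    nano = list(mu = 0.74, g = 0.50),
                    pico = list(mu = 1.14, g = 0.60))
  dil <- do.call(rbind, lapply(names(dil_cfg), function(sc) {
    simulate_series(mu = dil_cfg[[sc]]$mu, g = dil_cfg[[sc]]$g,
                    noise_sd = if (is.null(dil_cfg[[sc]]$noise_sd)) 0
                               else dil_cfg[[sc]]$noise_sd,
                    seed = seeds[["dilution"]] + match(sc, names(dil_cfg)),
                    size_class = sc)
  }))
  write_dilution(dil, file.path(out_dir, "dilution.csv"))

  n_cells <- if (is.null(config$n_cells)) 1000L else as.integer(config$n_cells)
  grid <- gen_grid(n_cells = n_cells, seed = seeds[["grid"]])
  utils::write.csv(grid$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(grid$props, file.path(out_dir, "props.csv"), row.names = FALSE)

  invisible(file.path(out_dir, c("curves.db", "survey.csv", "plate.csv",
                                 "dilution.csv", "cells.csv", "props.csv")))
}
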