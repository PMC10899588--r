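# Shared fixture builders and independent oracles.

# logistic model with a given EC50 and slope (theta_max = 1)
logistic_ec50 <- function(ec50, beta = 1) {
  response_model("logistic", theta_max = 1, alpha = -beta * log10(ec50),
                 beta = beta)
}

# two-curve database where the second curve is a parallel shift of the
# reference with the given potency ratio
parallel_db <- function(ratio = 16, beta = 1) {
  curve_db(list(
    atrazine = logistic_ec50(10, beta),
    terbutryn = logistic_ec50(10 / ratio, beta)), reference = "atrazine")
}

# noiseless plate data.frame in fit_model's schema
plate_from <- function(model, conc, reps = 1, noise_sd = 0, seed = 1) {
  pl <- gen_plate(model, concentrations = conc, reps = reps,
                  noise_sd = noise_sd, seed = seed)
  names(pl)[names(pl) == "concentration_nmol_L"] <- "concentration"
  pl
}

# brute-force grid-search oracle for the least-squares sigmoid fit:
# dense grid over (theta_max, alpha, beta), returns the best rss found
grid_search_rss <- function(data, family,
                            theta = seq(0.5, 1, by = 0.05),
                            alpha = seq(-6, 6, by = 0.05),
                            beta = seq(0.3, 4, by = 0.05)) {
  d <- data[data$concentration > 0, ]
  lc <- log10(d$concentration)
  y <- d$response
  best <- Inf
  for (th in theta) for (b in beta) {
    z <- outer(alpha, b * lc, `+`)
    mu <- switch(family,
      logistic = th * stats::plogis(z),
      weibull  = th * (1 - exp(-exp(z))))
    rss <- rowSums((matrix(y, nrow(mu), length(y), byrow = TRUE) - mu)^2)
    best <- min(best, min(rss))
  }
  best
}

# brute-force CA effect solver: scan a fine effect grid and refine
brute_ca_effect <- function(sample, db, n_grid = 20000) {
  tmax <- min(vapply(names(sample)[sample > 0],
                     function(h) db$curves[[h]]$theta_max, 1))
  xs <- seq(1e-8, tmax - 1e-8, length.out = n_grid)
  tu <- vapply(xs, function(x) sum(toxic_units(sample, db, x)), 1)
  i <- which.min(abs(tu - 1))
  lo <- xs[max(1, i - 1)]; hi <- xs[min(n_grid, i + 1)]
  stats::uniroot(function(x) sum(toxic_units(sample, db, x)) - 1,
                 c(lo, hi), tol = 1e-14)$root
}
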