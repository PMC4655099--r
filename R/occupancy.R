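#' MCMC configuration for the occupancy-detection model
#'
#' @param n_chains Number of MCMC chains.
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burnin Iterations discarded as burn-in (per chain).
#' @param thin Thinning interval applied after burn-in.
#' @param n_adapt Adaptation iterations (sampler tuning, discarded).
#' @param seed Integer seed. Chain `k` uses RNG seed `seed + k - 1`;
#'   identical configuration and data give bit-identical draws.
#' @param list_length Detection-effort specification: `"log"` uses a
#'   continuous `log(L)` term with one coefficient; `"categorical"` uses
#'   dummy effects for lists of 2-3 and >= 4 species (singleton lists as
#'   reference).
#' @param rhat_threshold Potential scale reduction factor above which a
#'   convergence warning is raised.
#' @param monitor_z Also monitor the latent occupancy states `z` (memory
#'   heavy; mainly for model checking).
#' @return A list of class `occu_config`.
#' @export
occu_config <- function(n_chains = 3, n_iter = 20000, n_burnin = 10000,
                        thin = 5, n_adapt = 1000, seed = 1,
                        list_length = c("log", "categorical"),
                        rhat_threshold = 1.1, monitor_z = FALSE) {
  list_length <- match.arg(list_length)
  if (n_burnin < 0 || n_iter <= n_burnin) {
    abort("Need `n_iter` > `n_burnin` >= 0.")
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, n_adapt = n_adapt, seed = seed,
                 list_length = list_length, rhat_threshold = rhat_threshold,
                 monitor_z = monitor_z),
            class = "occu_config")
}

occu_model_string <- function(list_length) {
  p_term <- switch(list_length,
    log = "c[year[v]] + d * logL[v]",
    categorical = "c[year[v]] + d2 * cat2[v] + d4 * cat4[v]")
  d_priors <- switch(list_length,
    log = "  d ~ dnorm(0, 0.01)\n",
    categorical = "  d2 ~ dnorm(0, 0.01)\n  d4 ~ dnorm(0, 0.01)\n")
  paste0("model {\n",
    "  sigma_b ~ dunif(0, 5)\n",
    "  tau_b <- pow(sigma_b, -2)\n",
    "  for (i in 1:n_site) { b[i] ~ dnorm(0, tau_b) }\n",
    "  for (t in 1:n_year) {\n",
    "    a[t] ~ dnorm(0, 0.01)\n",
    "    c[t] ~ dnorm(0, 0.01)\n",
    "    for (i in 1:n_site) {\n",
    "      logit(psi[i, t]) <- a[t] + b[i]\n",
    "      z[i, t] ~ dbern(psi[i, t])\n",
    "    }\n",
    "    psi_fs[t] <- sum(z[1:n_site, t]) / n_site\n",
    "  }\n",
    d_priors,
    "  for (v in 1:n_visit) {\n",
    "    logit(p[v]) <- ", p_term, "\n",
    "    y[v] ~ dbern(z[site[v], year[v]] * p[v])\n",
    "  }\n",
    "}\n")
}

#' Fit the Bayesian occupancy-detection model for one species
#'
#' Two hierarchically coupled sub-models are fitted by MCMC. The state model
#' governs true presence/absence of the focal species at each site in each
#' year: `z[i,t] ~ Bernoulli(psi[i,t])` with `logit psi[i,t] = a[t] + b[i]`,
#' independent vague-normal year effects `a[t] ~ N(0, 10^2)` and exchangeable
#' site effects `b[i] ~ N(0, sigma_b)`, `sigma_b ~ U(0, 5)`. The observation
#' model, conditional on the state, governs detection on each visit:
#' `y[v] ~ Bernoulli(z[i(v),t(v)] * p[v])` with
#' `logit p[v] = c[t(v)] + d * log(L[v])`, where `L` is the visit list
#' length (recording-effort proxy); year-specific detection intercepts
#' `c[t]` and the list-length coefficient `d` get `N(0, 10^2)` priors. A
#' categorical list-length form (1 / 2-3 / 4+) is available via
#' [occu_config()].
#'
#' Annual occupancy is the derived finite-sample quantity
#' `psi_fs[t] = sum_i z[i,t] / n_site` over all modelled sites, and the
#' within-draw OLS slope of `psi_fs` on calendar year is the species trend
#' `s`, so both inherit full posterior uncertainty. Years inside the span
#' with no visits anywhere still receive `a[t]` (and hence occupancy) draws,
#' informed only by the prior; they are flagged in the result.
#'
#' @param visits A `visit_table` (normally after [filter_sites()]).
#' @param species Focal species identifier; must have at least one detection.
#' @param config An [occu_config()].
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `occu_fit`: list with `species`, `years`,
#'   `sites`, `psi` (draws x years matrix of annual occupancy), `slope`
#'   (per-draw trend), `params` (draws x parameter matrix with a `chain`
#'   attribute column), `rhat` (tibble), `prior_only_years`, `n_detections`,
#'   `config`. Use [tidy()], [glance()], [trend_draws()],
#'   [annual_occupancy()].
#' @export
fit_occupancy <- function(visits, species, config = occu_config(),
                          quiet = TRUE) {
  y <- detection_history(visits, species)
  if (sum(y) == 0) {
    abort(paste0("Species '", species, "' was never detected; cannot fit."))
  }
  sites <- sort(unique(visits$site))
  years <- seq(min(visits$year), max(visits$year))
  site_idx <- match(visits$site, sites)
  year_idx <- match(visits$year, years)
  visited_years <- unique(visits$year)
  prior_only_years <- setdiff(years, visited_years)

  dat <- list(n_site = length(sites), n_year = length(years),
              n_visit = nrow(visits), site = site_idx, year = year_idx,
              y = y)
  if (config$list_length == "log") {
    dat$logL <- log(visits$list_length)
    monitors <- c("a", "c", "d", "sigma_b", "psi_fs")
    scalar_pars <- c("a", "c", "d", "sigma_b")
  } else {
    dat$cat2 <- as.integer(visits$list_length %in% 2:3)
    dat$cat4 <- as.integer(visits$list_length >= 4)
    monitors <- c("a", "c", "d2", "d4", "sigma_b", "psi_fs")
    scalar_pars <- c("a", "c", "d2", "d4", "sigma_b")
  }
  if (config$monitor_z) monitors <- c(monitors, "z")

  inits <- lapply(seq_len(config$n_chains), function(k) {
    list(z = matrix(1L, dat$n_site, dat$n_year),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + k - 1L)
  })
  jm <- rjags::jags.model(textConnection(occu_model_string(config$list_length)),
                          data = dat, inits = inits,
                          n.chains = config$n_chains,
                          n.adapt = config$n_adapt, quiet = quiet)
  if (config$n_burnin > 0) {
    stats::update(jm, config$n_burnin, progress.bar = "none")
  }
  samp <- rjags::coda.samples(jm, monitors,
                              n.iter = config$n_iter - config$n_burnin,
                              thin = config$thin,
                              progress.bar = if (quiet) "none" else "text")
  m <- do.call(rbind, lapply(samp, as.matrix))
  chain <- rep(seq_along(samp), each = nrow(samp[[1]]))

  psi_cols <- grep("^psi_fs\\[", colnames(m))
  ord <- order(as.integer(sub("^psi_fs\\[(\\d+)\\]$", "\\1",
                              colnames(m)[psi_cols])))
  psi <- m[, psi_cols[ord], drop = FALSE]
  colnames(psi) <- years
  slope <- as.numeric(trend_slope(psi, years))

  par_cols <- setdiff(seq_len(ncol(m)), psi_cols)
  z_cols <- grep("^z\\[", colnames(m))
  par_cols <- setdiff(par_cols, z_cols)
  params <- m[, par_cols, drop = FALSE]

  rhat <- occu_rhat(samp, scalar_pars)
  bad <- rhat$parameter[!is.na(rhat$rhat) & rhat$rhat > config$rhat_threshold]
  if (length(bad) > 0) {
    warn(paste0("Convergence warning for '", species, "': Rhat > ",
                config$rhat_threshold, " for ",
                paste(head(bad, 10), collapse = ", "),
                if (length(bad) > 10) " ..." else "", "."))
  }

  z_draws <- NULL
  if (config$monitor_z && length(z_cols) > 0) {
    z_draws <- m[, z_cols, drop = FALSE]
  }
  structure(list(species = species, years = years, sites = sites,
                 psi = psi, slope = slope, params = params, chain = chain,
                 z = z_draws,
                 visit_index = tibble(visit_id = visits$visit_id,
                                      site_idx = site_idx,
                                      year_idx = year_idx, y = y),
                 rhat = rhat, prior_only_years = prior_only_years,
                 n_detections = sum(y), config = config),
            class = "occu_fit")
}

occu_rhat <- function(samp, scalar_pars) {
  keep <- grep(paste0("^(", paste(scalar_pars, collapse = "|"),
                      ")(\\[|$)"), coda::varnames(samp), value = TRUE)
  sub <- samp[, keep, drop = FALSE]
  if (length(samp) < 2) {
    return(tibble(parameter = keep, rhat = NA_real_))
  }
  gd <- tryCatch(coda::gelman.diag(sub, multivariate = FALSE,
                                   autoburnin = FALSE),
                 error = function(e) NULL)
  if (is.null(gd)) return(tibble(parameter = keep, rhat = NA_real_))
  tibble(parameter = rownames(gd$psrf), rhat = gd$psrf[, 1])
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Occupancy-detection model fit (MCMC)\n")
  cat("  species:     ", x$species, "\n")
  cat("  sites:       ", length(x$sites), "  years: ", min(x$years), "-",
      max(x$years), "\n", sep = "")
  cat("  detections:  ", x$n_detections, "\n")
  cat("  draws:       ", nrow(x$psi), " (", x$config$n_chains, " chains)\n",
      sep = "")
  cat("  trend slope: ", signif(mean(x$slope), 4), " [",
      signif(quantile(x$slope, 0.025), 4), ", ",
      signif(quantile(x$slope, 0.975), 4), "]\n", sep = "")
  invisible(x)
}

#' Annual occupancy from latent states or a fitted model
#'
#' For a single posterior draw of the latent state matrix, annual occupancy
#' is the proportion of modelled sites occupied in each year -- all retained
#' sites count, visited that year or not. For a fitted model, the posterior
#' of that quantity is summarised per year.
#'
#' @param x A site x year 0/1 matrix (one posterior draw of `z`), or an
#'   `occu_fit`.
#' @param ... Unused.
#' @return For a matrix: a named numeric vector of per-year occupied
#'   proportions. For an `occu_fit`: a tibble `year`, `mean`, `sd`,
#'   `lower`, `upper` (2.5/97.5 percentiles), `prior_only`.
#' @export
annual_occupancy <- function(x, ...) UseMethod("annual_occupancy")

#' @rdname annual_occupancy
#' @export
annual_occupancy.matrix <- function(x, ...) {
  if (!all(x %in% c(0, 1))) abort("Latent states must be 0/1.")
  colMeans(x)
}

#' @rdname annual_occupancy
#' @export
annual_occupancy.occu_fit <- function(x, ...) {
  tibble(
    year = x$years,
    mean = unname(colMeans(x$psi)),
    sd = unname(apply(x$psi, 2, sd)),
    lower = unname(apply(x$psi, 2, quantile, 0.025)),
    upper = unname(apply(x$psi, 2, quantile, 0.975)),
    prior_only = x$years %in% x$prior_only_years
  )
}

#' Ordinary least-squares trend slope of annual occupancy
#'
#' The species trend is the OLS slope of annual occupancy on calendar year.
#' Computed within each posterior draw, the slope inherits the posterior
#' uncertainty of the occupancy series.
#'
#' @param psi A numeric vector (one series) or a draws x years matrix.
#' @param years Calendar years, same length as the series.
#' @return The slope (per year), scalar or one per draw.
#' @examples
#' trend_slope(c(0.1, 0.12, 0.14), 2000:2002)
#' @export
trend_slope <- function(psi, years) {
  if (is.matrix(psi)) {
    if (ncol(psi) != length(years)) abort("ncol(psi) must equal length(years).")
    if (length(years) < 2) abort("Need at least 2 years to fit a trend.")
    w <- years - mean(years)
    return(as.numeric(psi %*% (w / sum(w^2))))
  }
  if (length(psi) != length(years)) abort("Lengths of psi and years differ.")
  if (length(years) < 2) abort("Need at least 2 years to fit a trend.")
  w <- years - mean(years)
  sum(w * (psi - mean(psi))) / sum(w^2)
}

#' Posterior trend draws of one or more fitted species
#'
#' @param fits An `occu_fit` or a list of them.
#' @return A tibble `species`, `chain`, `draw`, `slope` (one row per
#'   retained posterior draw).
#' @export
trend_draws <- function(fits) {
  if (inherits(fits, "occu_fit")) fits <- list(fits)
  bind_rows(lapply(fits, function(f) {
    tibble(species = f$species, chain = f$chain,
           draw = seq_along(f$slope), slope = f$slope)
  }))
}

#' Summarise posterior trend distributions per species
#'
#' Gives the posterior mean, standard deviation and 2.5/97.5 percentiles of
#' each species' trend slope, plus the interval-based classification: a
#' species is `increasing` when the 2.5 percentile of its slope exceeds
#' zero, `declining` when the 97.5 percentile is below zero, and
#' `uncertain` when the interval bridges zero.
#'
#' @param x A tibble with columns `species` and `slope` (one row per draw,
#'   e.g. from [trend_draws()]), or an `occu_fit`, or a list of `occu_fit`s.
#' @return A tibble of class `trend_summary`: `species`, `mean`, `sd`,
#'   `lower`, `upper`, `n_draws`, `classification`.
#' @export
summarize_trends <- function(x) {
  if (inherits(x, "occu_fit") || (is.list(x) && !is.data.frame(x))) {
    x <- trend_draws(x)
  }
  if (!all(c("species", "slope") %in% names(x))) {
    abort("Need columns `species` and `slope`.")
  }
  out <- x %>%
    group_by(.data$species) %>%
    summarise(mean = mean(.data$slope), sd = sd(.data$slope),
              lower = unname(quantile(.data$slope, 0.025)),
              upper = unname(quantile(.data$slope, 0.975)),
              n_draws = n(), .groups = "drop") %>%
    mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd),
           classification = dplyr::case_when(
             .data$lower > 0 ~ "increasing",
             .data$upper < 0 ~ "declining",
             TRUE ~ "uncertain"
           ))
  class(out) <- c("trend_summary", class(out))
  out
}

#' @export
tidy.occu_fit <- function(x, ...) {
  summ <- function(v, term) {
    tibble(term = term, estimate = mean(v), std.error = sd(v),
           conf.low = quantile(v, 0.025), conf.high = quantile(v, 0.975))
  }
  bind_rows(
    bind_rows(lapply(colnames(x$params), function(p)
      summ(x$params[, p], p))),
    bind_rows(lapply(seq_along(x$years), function(t)
      summ(x$psi[, t], paste0("psi_fs[", x$years[t], "]")))),
    summ(x$slope, "trend_slope")
  )
}

#' @export
glance.occu_fit <- function(x, ...) {
  tibble(species = x$species, n_sites = length(x$sites),
         n_years = length(x$years), n_detections = x$n_detections,
         n_draws = nrow(x$psi), n_chains = x$config$n_chains,
         max_rhat = suppressWarnings(max(x$rhat$rhat, na.rm = TRUE)),
         slope_mean = mean(x$slope),
         slope_lower = quantile(x$slope, 0.025),
         slope_upper = quantile(x$slope, 0.975))
}
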