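#' Simulate opportunistic occurrence records with known ground truth
#'
#' Generates a record set shaped like a recording-scheme extract: focal
#' species with specified annual occupancy trajectories, imperfect visit-level
#' detection that depends on list length, and background recording effort that
#' can grow over the study window (emulating the dramatic growth of
#' volunteer recording). Ground truth (occupancy states, detection
#' parameters, realized visits, true trend slopes) is returned alongside the
#' records so every downstream stage can be validated.
#'
#' The generative process, per year `t` and site `i`:
#' * focal occupancy states `z[s,i,t] ~ Bernoulli(psi[s,i,t])`, with
#'   `logit psi[s,i,t] = logit(psi[s,t]) + b[s,i]`, site effects
#'   `b[s,i] ~ N(0, site_sd)`; states are independent across years
#'   (one-year closure, no colonization dynamics);
#' * visits per site-year from the effort model (Poisson or fixed count);
#' * per visit, a list length `L >= 1` (number of species the recorder
#'   tallies) from a zero-truncated Poisson whose mean may drift linearly
#'   across years -- a visit only exists because somebody recorded
#'   something, and recording effort typically grows over the window;
#' * focal species `s`, if present (`z = 1`), is detected with probability
#'   `p = plogis(c[s] + d[s] * log(L))`, or with constant probability `p`
#'   when `detection$p` is given; a detected focal occupies one of the `L`
#'   list slots, and species from a background pool fill the remainder, so
#'   the observed list length of the emitted records equals `L` (the focal
#'   counts towards its own list);
#' * records are emitted for the background fill and for focal detections
#'   only (non-detections leave no record).
#'
#' @param n_species Number of focal species.
#' @param n_sites Number of sites (1 km cells).
#' @param years Integer vector of contiguous study years.
#' @param psi Either a `n_species x length(years)` matrix of annual occupancy
#'   probabilities, or `NULL` to build linear trajectories from `psi_start`
#'   to `psi_end`.
#' @param psi_start,psi_end Per-species start/end occupancy (recycled);
#'   used when `psi` is `NULL`.
#' @param site_sd Standard deviation (logit scale) of per-species site
#'   effects; 0 gives site-homogeneous occupancy.
#' @param detection List: either `p` (constant detection probability in
#'   `[0,1]`), or `c` (logit-scale intercept) and `d` (list-length
#'   coefficient on `log L`), each length 1 or `n_species`.
#' @param effort List with `visits_per_site_year` (scalar or per-year vector
#'   of means), `fixed` (`TRUE` = exactly that many visits, `FALSE` =
#'   Poisson counts), `list_mean_start`, `list_mean_end` (zero-truncated
#'   Poisson mean of the visit list length in the first/last year; linear
#'   in between) and `n_background` (background species pool size; 0
#'   disables background species entirely, so only focal detections are
#'   emitted and the detection covariate is constant).
#' @param seed Integer seed; the full output is reproducible from the
#'   arguments plus this seed.
#' @return A list of class `sim_records`:
#'   * `records`: tibble `species`, `date`, `site` (focal + background);
#'   * `truth`: list with `psi` (species x year matrix of mean occupancy),
#'     `z` (species x site x year array), `psi_bar_realized` (species x year
#'     realized occupied proportion), `slope_true` (OLS slope of expected
#'     annual occupancy on year, per species), `visits` (tibble with the
#'     generated visits incl. list length `L`), `detections` (species x
#'     visit 0/1 matrix), `detection` (parameters), `params`, `seed`;
#'   * `species`: focal species ids; `background_species`: pool ids.
#' @examples
#' sim <- simulate_records(n_species = 2, n_sites = 10, years = 2000:2004,
#'                         seed = 1)
#' head(sim$records)
#' sim$truth$slope_true
#' @export
simulate_records <- function(n_species = 36, n_sites = 100,
                             years = 1980:2012,
                             psi = NULL, psi_start = 0.4, psi_end = 0.4,
                             site_sd = 0,
                             detection = list(c = qlogis(0.4), d = 0.5),
                             effort = list(visits_per_site_year = 2,
                                           fixed = FALSE,
                                           list_mean_start = 3,
                                           list_mean_end = 3,
                                           n_background = 60),
                             seed = 1) {
  if (any(diff(years) != 1)) abort("`years` must be contiguous.")
  n_years <- length(years)
  eff <- utils::modifyList(list(visits_per_site_year = 2, fixed = FALSE,
                                list_mean_start = 3, list_mean_end = 3,
                                n_background = 60), effort)
  if (is.null(psi)) {
    psi_start <- rep_len(psi_start, n_species)
    psi_end <- rep_len(psi_end, n_species)
    psi <- t(vapply(seq_len(n_species), function(s)
      seq(psi_start[s], psi_end[s], length.out = n_years), numeric(n_years)))
    psi <- matrix(psi, nrow = n_species)
  }
  if (!all(dim(psi) == c(n_species, n_years))) {
    abort("`psi` must be an n_species x length(years) matrix.")
  }
  if (any(psi < 0 | psi > 1)) abort("Occupancy probabilities must be in [0, 1].")
  p_const <- detection$p
  if (!is.null(p_const) && any(p_const < 0 | p_const > 1)) {
    abort("`detection$p` must be in [0, 1].")
  }
  det_c <- rep_len(if (is.null(detection$c)) qlogis(0.4) else detection$c,
                   n_species)
  det_d <- rep_len(if (is.null(detection$d)) 0 else detection$d, n_species)
  if (!is.null(p_const)) p_const <- rep_len(p_const, n_species)
  vpsy <- rep_len(eff$visits_per_site_year, n_years)
  if (any(vpsy < 0)) abort("`visits_per_site_year` must be non-negative.")
  if (eff$n_background < 0) abort("`n_background` must be >= 0.")

  species <- sprintf("species_%02d", seq_len(n_species))
  bg_pool <- if (eff$n_background > 0) {
    sprintf("background_%03d", seq_len(eff$n_background))
  } else character(0)
  sites <- sprintf("site_%04d", seq_len(n_sites))

  withr::local_seed(seed)

  # latent occupancy
  b_site <- matrix(rnorm(n_species * n_sites, 0, site_sd), n_species, n_sites)
  z <- array(0L, dim = c(n_species, n_sites, n_years))
  psi_site_mean <- matrix(0, n_species, n_years) # E[psi] averaged over sites
  for (t in seq_len(n_years)) {
    pr <- plogis(qlogis(psi[, t]) + b_site)        # species x site
    pr[psi[, t] == 0, ] <- 0
    pr[psi[, t] == 1, ] <- 1
    z[, , t] <- matrix(rbinom(length(pr), 1L, pr), n_species, n_sites)
    psi_site_mean[, t] <- rowMeans(pr)
  }

  # visits per site-year
  list_mean <- seq(eff$list_mean_start, eff$list_mean_end,
                   length.out = n_years)
  vis <- list()
  k <- 0L
  for (t in seq_len(n_years)) {
    nv <- if (isTRUE(eff$fixed)) rep(as.integer(round(vpsy[t])), n_sites)
          else rpois(n_sites, vpsy[t])
    for (i in which(nv > 0)) {
      days <- sample(91:273, nv[i])  # within the flight season, distinct dates
      k <- k + 1L
      vis[[k]] <- tibble(site_idx = i, year_idx = t, day = days)
    }
  }
  if (length(vis) == 0) {
    visits <- tibble(site_idx = integer(), year_idx = integer(), day = integer())
  } else {
    visits <- bind_rows(vis)
  }
  n_vis <- nrow(visits)

  # list length per visit (zero-truncated Poisson, mean drifting over years);
  # with no background pool the covariate degenerates to a constant (L = 1)
  if (eff$n_background > 0 && n_vis > 0) {
    L <- rztpois(n_vis, list_mean[visits$year_idx])
    L <- pmin(L, eff$n_background)
  } else {
    L <- rep(1L, max(n_vis, 0))
  }
  visits$L <- L

  # focal detections: p depends on the log list length of the visit
  rec <- list(); rk <- 0L
  det_mat <- matrix(0L, n_species, max(n_vis, 1))
  if (n_vis > 0) {
    logL <- log(L)
    for (s in seq_len(n_species)) {
      zs <- z[s, , , drop = TRUE]
      zs <- matrix(zs, n_sites, n_years)
      present <- zs[cbind(visits$site_idx, visits$year_idx)] == 1L
      p <- if (!is.null(p_const)) rep(p_const[s], n_vis)
           else plogis(det_c[s] + det_d[s] * logL)
      y <- integer(n_vis)
      y[present] <- rbinom(sum(present), 1L, p[present])
      det_mat[s, seq_len(n_vis)] <- y
      if (any(y == 1L)) {
        rk <- rk + 1L
        rec[[rk]] <- tibble(species = species[s],
                            v = which(y == 1L))
      }
    }
    # detected focals occupy list slots; the background pool fills the rest,
    # so the emitted records reproduce L exactly (unless more focals than
    # slots were detected, in which case the list simply overflows)
    if (eff$n_background > 0) {
      n_det <- colSums(det_mat[, seq_len(n_vis), drop = FALSE])
      n_bg <- pmax(0L, L - n_det)
      bg_rows <- visits[rep(seq_len(n_vis), n_bg),
                        c("site_idx", "year_idx", "day")]
      bg_rows$species <- unlist(lapply(seq_len(n_vis), function(v) {
        if (n_bg[v] > 0) sample(bg_pool, n_bg[v]) else character(0)
      }), use.names = FALSE)
    }
  }

  date_of <- function(year_idx, day) {
    as.Date(paste0(years[year_idx], "-01-01")) + (day - 1)
  }
  records <- tibble(species = character(), date = as.Date(character()),
                    site = character())
  if (rk > 0) {
    foc <- bind_rows(rec)
    records <- tibble(
      species = foc$species,
      date = date_of(visits$year_idx[foc$v], visits$day[foc$v]),
      site = sites[visits$site_idx[foc$v]]
    )
  }
  if (n_vis > 0 && eff$n_background > 0 && nrow(bg_rows) > 0) {
    records <- bind_rows(records, tibble(
      species = bg_rows$species,
      date = date_of(bg_rows$year_idx, bg_rows$day),
      site = sites[bg_rows$site_idx]
    ))
  }
  records <- arrange(records, .data$species, .data$site, .data$date)

  psi_bar_realized <- t(apply(z, 1, function(m) colMeans(matrix(m, n_sites))))
  psi_bar_realized <- matrix(psi_bar_realized, n_species, n_years,
                             dimnames = list(species, years))
  slope_true <- apply(psi_site_mean, 1, trend_slope, years = years)

  truth <- list(
    psi = matrix(psi, n_species, n_years, dimnames = list(species, years)),
    psi_expected = matrix(psi_site_mean, n_species, n_years,
                          dimnames = list(species, years)),
    z = z,
    psi_bar_realized = psi_bar_realized,
    slope_true = setNames(slope_true, species),
    visits = mutate(visits,
                    site = sites[.data$site_idx],
                    year = years[.data$year_idx],
                    date = date_of(.data$year_idx, .data$day)),
    detections = matrix(det_mat[, seq_len(max(n_vis, 0)), drop = FALSE],
                        n_species, n_vis, dimnames = list(species, NULL)),
    detection = list(c = det_c, d = det_d, p = p_const),
    params = list(n_species = n_species, n_sites = n_sites, years = years,
                  site_sd = site_sd, effort = eff),
    seed = seed
  )
  structure(list(records = records, truth = truth, species = species,
                 background_species = bg_pool, sites = sites),
            class = "sim_records")
}

# zero-truncated Poisson via inverse-cdf conditioning (exact, vectorized)
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  u <- runif(n)
  p0 <- exp(-lambda)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

#' Simulate a trait system with planted effects on species trends
#'
#' Builds a synthetic trait table for the tips of a taxonomy tree, assigns
#' each species a "true" occurrence-trend slope as a linear function of the
#' traits plus phylogenetically correlated noise, and emits per-species
#' pseudo-posterior draws around those slopes. This exercises the
#' comparative stage (design encoding, PGLS, posterior resampling) with a
#' known answer, independently of the occupancy stage.
#'
#' True slopes follow `slope = X beta + e`, `e ~ MVN(0, noise_sd^2 * C(lambda_true))`
#' where `C` is the tree correlation (covariance scaled to unit diagonal)
#' after the Pagel's lambda transform. Pseudo-posterior draws add independent
#' `N(0, draw_sd^2)` noise, mimicking per-species posterior uncertainty in
#' trend estimates.
#'
#' @param tree A rooted `phylo` with branch lengths (e.g. [taxonomy_tree()]).
#' @param effects Named numeric vector of planted effects keyed by design
#'   column names (see [build_design()]); unnamed columns get effect 0.
#' @param lambda_true Pagel's lambda of the residual noise, in `[0, 1]`.
#' @param noise_sd SD of the residual slope noise.
#' @param intercept Baseline slope (design intercept coefficient).
#' @param n_draws Pseudo-posterior draws per species.
#' @param draw_sd SD of the per-species posterior noise.
#' @param traits Optional trait tibble to use instead of generating one.
#' @param seed Integer seed.
#' @return List with `traits` (tibble of the seven traits), `design`
#'   (matrix), `slope_true` (named vector), `draws` (tibble `species`,
#'   `draw`, `slope`), `effects_used` (full named vector), `params`.
#' @export
simulate_trait_system <- function(tree, effects = c(habitat_breadth = 0.005),
                                  lambda_true = 0, noise_sd = 0.002,
                                  intercept = 0, n_draws = 100,
                                  draw_sd = 0.001, traits = NULL, seed = 1) {
  if (lambda_true < 0 || lambda_true > 1) abort("`lambda_true` must be in [0, 1].")
  if (!all(is.finite(effects))) abort("`effects` must be finite.")
  sp <- tree$tip.label
  n <- length(sp)
  withr::local_seed(seed)
  if (is.null(traits)) {
    traits <- tibble(
      species = sp,
      status = sample(names(status_codes()), n, replace = TRUE),
      region = sample(c("southern", "northern", "oceanic", "widespread"), n,
                      replace = TRUE),
      thorax_length = round(rnorm(n, 20, 4), 1),
      flight_period = pmax(1, pmin(8, round(rnorm(n, 4, 1.2)))),
      habitat_breadth = sample(1:6, n, replace = TRUE),
      breeding_habitat = sample(c("lentic", "lotic", "both"), n,
                                replace = TRUE, prob = c(0.5, 0.3, 0.2)),
      overwintering = sample(c("eggs", "larvae", "both"), n,
                             replace = TRUE, prob = c(0.3, 0.55, 0.15))
    )
  }
  X <- build_design(traits, species_order = sp)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- intercept
  known <- intersect(names(effects), names(beta))
  if (length(known) < length(effects)) {
    warn(paste0("Effects for absent design columns ignored: ",
                paste(setdiff(names(effects), known), collapse = ", ")))
  }
  beta[known] <- effects[known]

  V <- tree_vcv(tree)[sp, sp]
  C <- V / max(diag(V))
  Sigma <- noise_sd^2 * lambda_transform(C, lambda_true)
  e <- as.numeric(MASS::mvrnorm(1, mu = rep(0, n), Sigma = Sigma))
  slope_true <- setNames(as.numeric(X %*% beta) + e, sp)

  draws <- tidyr::expand_grid(species = sp, draw = seq_len(n_draws)) %>%
    mutate(slope = slope_true[.data$species] +
             rnorm(dplyr::n(), 0, draw_sd))
  list(traits = traits, design = X, slope_true = slope_true, draws = draws,
       effects_used = beta,
       params = list(lambda_true = lambda_true, noise_sd = noise_sd,
                     draw_sd = draw_sd, n_draws = n_draws, seed = seed))
}
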