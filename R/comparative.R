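#' Ordinal coding of species distribution status
#'
#' Distribution status is an ordinal measure of range size and enters the
#' trait model as a continuous term, coded symmetrically around zero:
#' very rare = -1.5, rare = -1, scarce = -0.5, local = 0.5, widespread = 1,
#' very widespread = 1.5.
#'
#' @return Named numeric vector of the six codes.
#' @export
status_codes <- function() {
  c("very rare" = -1.5, "rare" = -1, "scarce" = -0.5,
    "local" = 0.5, "widespread" = 1, "very widespread" = 1.5)
}

#' @rdname status_codes
#' @param status Character vector of status labels.
#' @return For `encode_status()`: the numeric codes.
#' @examples
#' encode_status(c("local", "very rare"))
#' @export
encode_status <- function(status) {
  codes <- status_codes()
  bad <- !(status %in% names(codes))
  if (any(bad)) {
    abort(paste0("Unknown status label(s): ",
                 paste(unique(status[bad]), collapse = ", "), "."))
  }
  unname(codes[status])
}

trait_spec <- function() {
  list(
    continuous = c("status", "thorax_length", "flight_period",
                   "habitat_breadth"),
    categorical = list(
      region = list(levels = c("southern", "northern", "oceanic",
                               "widespread"), prefix = "region"),
      breeding_habitat = list(levels = c("lentic", "both", "lotic"),
                              prefix = "breeding"),
      overwintering = list(levels = c("eggs", "both", "larvae"),
                           prefix = "overwinter")
    )
  )
}

#' Build the trait design matrix for the comparative analysis
#'
#' Encodes the seven species traits as model columns: an intercept; status
#' (ordinal coding, treated as continuous), thorax length (mm), flight
#' period (months) and habitat breadth (count, 1-6), each centred on zero;
#' and treatment contrasts for the three categorical traits against their
#' reference levels -- region vs `"southern"`, breeding habitat vs
#' `"lentic"`, overwintering stage vs `"eggs"` (reference species carry 0 in
#' all their contrast columns). With all traits included the matrix has 12
#' columns. Zero-variance non-intercept columns (e.g. a contrast level
#' absent from the data) are dropped with a warning to preserve full rank.
#'
#' @param traits Tibble with columns `species`, `status`, `region`,
#'   `thorax_length`, `flight_period`, `habitat_breadth`,
#'   `breeding_habitat`, `overwintering`. Missing values are an error
#'   naming the species and trait.
#' @param species_order Character vector fixing the row order (must match
#'   the trend table and covariance matrix ordering).
#' @param traits_include Which of the seven traits to encode (default all);
#'   useful for reduced synthetic systems.
#' @return A numeric matrix with `species_order` rownames and an attribute
#'   `"dropped"` listing removed constant columns.
#' @export
build_design <- function(traits, species_order = traits$species,
                         traits_include = c("status", "region",
                                            "thorax_length", "flight_period",
                                            "habitat_breadth",
                                            "breeding_habitat",
                                            "overwintering")) {
  traits <- as_tibble(traits)
  spec <- trait_spec()
  cols_needed <- c("species", traits_include)
  if (!all(cols_needed %in% names(traits))) {
    abort(paste0("`traits` is missing column(s): ",
                 paste(setdiff(cols_needed, names(traits)), collapse = ", "), "."))
  }
  missing_sp <- setdiff(species_order, traits$species)
  if (length(missing_sp) > 0) {
    abort(paste0("No trait rows for species: ",
                 paste(head(missing_sp, 5), collapse = ", "), "."))
  }
  traits <- traits[match(species_order, traits$species), ]
  for (tr in traits_include) {
    miss <- is.na(traits[[tr]]) | (is.character(traits[[tr]]) & traits[[tr]] == "")
    if (any(miss)) {
      abort(paste0("Missing trait '", tr, "' for species '",
                   traits$species[which(miss)[1]], "'."))
    }
  }
  n <- length(species_order)
  cols <- list("(Intercept)" = rep(1, n))
  centre <- function(v) v - mean(v)
  for (tr in intersect(spec$continuous, traits_include)) {
    v <- if (tr == "status") encode_status(traits$status)
         else as.numeric(traits[[tr]])
    cols[[tr]] <- centre(v)
  }
  for (tr in intersect(names(spec$categorical), traits_include)) {
    info <- spec$categorical[[tr]]
    v <- as.character(traits[[tr]])
    bad <- !(v %in% info$levels)
    if (any(bad)) {
      abort(paste0("Unknown level '", v[bad][1], "' for trait '", tr, "'."))
    }
    for (lev in info$levels[-1]) { # first level is the reference
      cols[[paste(info$prefix, lev, sep = "_")]] <- as.numeric(v == lev)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- species_order
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col)
    max(col) - min(col) > 0))
  dropped <- colnames(X)[!keep]
  if (length(dropped) > 0) {
    warn(paste0("Dropping constant design column(s): ",
                paste(dropped, collapse = ", "), "."))
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

#' Posterior-resampling PGLS of trait-trend relationships
#'
#' Propagates the posterior uncertainty of species trend estimates into the
#' trait coefficients: in each of `n_iter` iterations one trend value is
#' drawn at random (independently per species) from that species' stored
#' posterior draws, a PGLS model of trend on traits is fitted with Pagel's
#' lambda re-estimated by maximum likelihood, and the coefficients and
#' lambda are recorded. The summary reports, per design term and for
#' lambda, the mean and the empirical 2.5/97.5 percentiles across
#' iterations.
#'
#' Singular fits are retried with fresh draws; more than 1% failed
#' iterations is an error.
#'
#' @param draws Posterior trend draws: tibble `species`, `slope` (one row
#'   per draw, e.g. [trend_draws()]), or a species x draws matrix with
#'   species rownames.
#' @param design Design matrix from [build_design()] (rows = species).
#' @param V Phylogenetic covariance matrix in the same species order.
#' @param n_iter Number of resampling iterations (default 10000).
#' @param seed Integer master seed; results are reproducible given the seed.
#' @return Object of class `comparative_summary`: `summary` tibble (`term`,
#'   `mean`, `lower`, `upper`; lambda as the last row), `coefficients`
#'   (n_iter x terms matrix), `lambda` (vector), `n_iter`, `n_retries`.
#' @export
resample_pgls <- function(draws, design, V, n_iter = 10000, seed = 1) {
  sp <- rownames(design)
  if (is.null(sp)) abort("`design` must carry species rownames.")
  if (is.matrix(draws)) {
    draw_list <- lapply(sp, function(s) {
      if (!s %in% rownames(draws)) abort(paste0("No draws for '", s, "'."))
      as.numeric(draws[s, ])
    })
  } else {
    if (!all(c("species", "slope") %in% names(draws))) {
      abort("`draws` needs columns `species` and `slope`.")
    }
    draw_list <- lapply(sp, function(s) draws$slope[draws$species == s])
  }
  names(draw_list) <- sp
  n_per <- lengths(draw_list)
  if (any(n_per == 0)) {
    abort(paste0("No posterior draws for species: ",
                 paste(sp[n_per == 0], collapse = ", "), "."))
  }
  if (!identical(sp, rownames(V)[seq_along(sp)]) && !is.null(rownames(V))) {
    V <- V[sp, sp]
  }
  if (qr(design)$rank < ncol(design)) abort("Design matrix is singular.")
  prep <- pgls_prep(V)
  cache <- pgls_grid_cache(design, prep)
  p <- ncol(design)
  coefs <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, colnames(design)))
  lambdas <- numeric(n_iter)
  n_retries <- 0L
  max_fail <- ceiling(0.01 * n_iter)

  withr::local_seed(seed)
  draw_mat <- matrix(vapply(draw_list, function(d)
    d[sample.int(length(d), n_iter, replace = TRUE)], numeric(n_iter)),
    nrow = n_iter, dimnames = list(NULL, sp))
  one_fit <- function(y) {
    ml <- pgls_ml_lambda(y, design, prep, cache = cache)
    fit <- pgls_solve_at(y, design, prep, ml$lambda)
    list(beta = as.numeric(fit$beta), lambda = ml$lambda)
  }
  for (it in seq_len(n_iter)) {
    y <- draw_mat[it, ]
    res <- tryCatch(one_fit(y), error = function(e) NULL)
    while (is.null(res)) {
      n_retries <- n_retries + 1L
      if (n_retries > max_fail) {
        abort("More than 1% of resampling iterations failed (singular fits).")
      }
      y <- vapply(draw_list, function(d) d[sample.int(length(d), 1)],
                  numeric(1))
      res <- tryCatch(one_fit(y), error = function(e) NULL)
    }
    coefs[it, ] <- res$beta
    lambdas[it] <- res$lambda
  }
  summary <- bind_rows(
    tibble(term = colnames(coefs),
           mean = unname(colMeans(coefs)),
           lower = unname(apply(coefs, 2, quantile, 0.025)),
           upper = unname(apply(coefs, 2, quantile, 0.975))),
    tibble(term = "lambda", mean = mean(lambdas),
           lower = unname(quantile(lambdas, 0.025)),
           upper = unname(quantile(lambdas, 0.975)))
  )
  structure(list(summary = summary, coefficients = coefs, lambda = lambdas,
                 n_iter = n_iter, n_retries = n_retries),
            class = "comparative_summary")
}

#' @export
print.comparative_summary <- function(x, ...) {
  cat("Posterior-resampling PGLS (", x$n_iter, " iterations, ",
      x$n_retries, " retries)\n", sep = "")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.comparative_summary <- function(x, ...) x$summary

#' @export
glance.comparative_summary <- function(x, ...) {
  tibble(n_iter = x$n_iter, n_retries = x$n_retries,
         n_terms = ncol(x$coefficients),
         lambda_mean = mean(x$lambda))
}

#' Count species by trend classification
#'
#' Tallies how many species have posterior trend intervals entirely above
#' zero (increasing), entirely below zero (declining), or bridging zero
#' (uncertain).
#'
#' @param trend_summary A `trend_summary` tibble from [summarize_trends()].
#' @return A tibble `classification`, `n`, `pct` with one row per category
#'   (zero-count categories included).
#' @export
classify_species <- function(trend_summary) {
  lv <- c("declining", "increasing", "uncertain")
  counts <- table(factor(trend_summary$classification, levels = lv))
  tibble(classification = lv, n = as.integer(counts),
         pct = 100 * as.integer(counts) / nrow(trend_summary))
}
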