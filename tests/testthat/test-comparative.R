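test_that("status labels map to the symmetric ordinal codes", {
  expect_equal(encode_status("local"), 0.5)
  expect_equal(encode_status("very rare"), -1.5)
  expect_equal(encode_status(c("rare", "scarce", "widespread",
                               "very widespread")),
               c(-1, -0.5, 1, 1.5))
  # odd symmetry of the coding
  expect_equal(encode_status("very rare"), -encode_status("very widespread"))
  expect_equal(encode_status("rare"), -encode_status("widespread"))
  expect_equal(encode_status("scarce"), -encode_status("local"))
  expect_error(encode_status("common"), "Unknown status")
})

hand_traits <- function() {
  tibble::tibble(
    species = paste0("sp", 1:5),
    status = c("local", "very rare", "widespread", "scarce", "local"),
    region = c("southern", "northern", "oceanic", "southern", "widespread"),
    thorax_length = c(10, 12, 14, 16, 18),
    flight_period = c(2, 3, 4, 5, 6),
    habitat_breadth = c(1, 2, 3, 4, 5),
    breeding_habitat = c("lentic", "lotic", "both", "lentic", "lentic"),
    overwintering = c("eggs", "larvae", "both", "eggs", "larvae")
  )
}

test_that("build_design matches a hand-enumerated matrix", {
  X <- build_design(hand_traits())
  st <- c(0.5, -1.5, 1, -0.5, 0.5)
  want <- cbind(
    `(Intercept)` = rep(1, 5),
    status = st - mean(st),
    thorax_length = c(10, 12, 14, 16, 18) - 14,
    flight_period = c(2, 3, 4, 5, 6) - 4,
    habitat_breadth = c(1, 2, 3, 4, 5) - 3,
    region_northern = c(0, 1, 0, 0, 0),
    region_oceanic = c(0, 0, 1, 0, 0),
    region_widespread = c(0, 0, 0, 0, 1),
    breeding_both = c(0, 0, 1, 0, 0),
    breeding_lotic = c(0, 1, 0, 0, 0),
    overwinter_both = c(0, 0, 1, 0, 0),
    overwinter_larvae = c(0, 1, 0, 0, 1)
  )
  rownames(want) <- paste0("sp", 1:5)
  expect_equal(X, want, ignore_attr = "dropped")
  expect_equal(ncol(X), 12)
  # continuous columns centred to machine precision
  for (col in c("status", "thorax_length", "flight_period", "habitat_breadth"))
    expect_lt(abs(sum(X[, col])), 1e-10)
  # reference-category species have zeros in all their contrast columns
  ref_row <- X["sp1", c("region_northern", "region_oceanic",
                        "region_widespread", "breeding_both",
                        "breeding_lotic", "overwinter_both",
                        "overwinter_larvae")]
  expect_equal(unname(ref_row), rep(0, 7))
})

test_that("build_design enforces completeness and drops constant columns", {
  tr <- hand_traits()
  tr$habitat_breadth[3] <- NA
  expect_error(build_design(tr), "habitat_breadth.*sp3")

  allref <- hand_traits()
  allref$region <- "southern"
  allref$breeding_habitat <- "lentic"
  allref$overwintering <- "eggs"
  expect_warning(X <- build_design(allref), "constant design column")
  expect_false(any(grepl("region|breeding|overwinter", colnames(X))))
  expect_true(all(c("(Intercept)", "status") %in% colnames(X)))

  expect_error(build_design(hand_traits(), species_order = c("sp1", "spX")),
               "spX")
  bad <- hand_traits(); bad$region[1] <- "arctic"
  expect_error(build_design(bad), "arctic")
})

test_that("zero-variance posteriors collapse the resampling loop", {
  tree <- taxonomy_tree(synthetic_taxonomy(sprintf("sp%02d", 1:12)))
  st <- suppressWarnings(
    simulate_trait_system(tree, effects = c(habitat_breadth = 0.004),
                          noise_sd = 0.001, n_draws = 1, draw_sd = 0,
                          seed = 9))
  V <- tree_vcv(tree)
  rs <- suppressWarnings(
    resample_pgls(st$draws, st$design, V, n_iter = 200, seed = 1))
  # every iteration sees the same response, so intervals have width zero
  expect_equal(rs$summary$upper - rs$summary$lower,
               rep(0, nrow(rs$summary)))
  single <- pgls_fit(st$slope_true[rownames(st$design)], st$design,
                     V[rownames(st$design), rownames(st$design)], "ML")
  expect_equal(rs$summary$mean[match(names(coef(single)), rs$summary$term)],
               unname(coef(single)), tolerance = 1e-10)
  expect_equal(mean(rs$lambda), single$lambda, tolerance = 1e-6)

  # n_iter = 1 equals that one fit
  rs1 <- resample_pgls(st$draws, st$design, V, n_iter = 1, seed = 5)
  expect_equal(unname(rs1$coefficients[1, ]), unname(coef(single)),
               tolerance = 1e-10)
  expect_s3_class(autoplot(rs), "ggplot")
})

test_that("the resampling loop recovers a planted continuous effect", {
  tree <- taxonomy_tree(synthetic_taxonomy(sprintf("sp%02d", 1:36)))
  st <- simulate_trait_system(tree, effects = c(habitat_breadth = 0.005),
                              lambda_true = 0, noise_sd = 5e-4,
                              n_draws = 100, draw_sd = 0.002, seed = 15)
  rs <- resample_pgls(st$draws, st$design, tree_vcv(tree), n_iter = 1000,
                      seed = 16)
  hb <- rs$summary[rs$summary$term == "habitat_breadth", ]
  expect_gt(hb$mean, 0)
  expect_true(hb$lower <= 0.005 && 0.005 <= hb$upper)
  expect_gt(hb$lower, 0)
  expect_equal(rs$n_iter, 1000)
  expect_s3_class(glance(rs), "tbl_df")
})

test_that("intercept-only resampling converges to the GLS-weighted mean", {
  tree <- taxonomy_tree(synthetic_taxonomy(sprintf("sp%02d", 1:12)))
  V <- tree_vcv(tree)
  set.seed(31)
  mu <- rnorm(12, 0.002, 0.003)
  draws <- tidyr::expand_grid(species = sprintf("sp%02d", 1:12),
                              draw = 1:200) |>
    dplyr::mutate(slope = mu[match(species, sprintf("sp%02d", 1:12))] +
                    rnorm(dplyr::n(), 0, 0.0005))
  X <- matrix(1, 12, 1, dimnames = list(sprintf("sp%02d", 1:12),
                                        "(Intercept)"))
  rs_small <- resample_pgls(draws, X, V, n_iter = 2000, seed = 7)
  rs_big <- resample_pgls(draws, X, V, n_iter = 20000, seed = 8)
  m_small <- rs_small$summary$mean[rs_small$summary$term == "(Intercept)"]
  m_big <- rs_big$summary$mean[rs_big$summary$term == "(Intercept)"]
  # Monte-Carlo agreement between iteration counts
  mc_se <- sd(rs_big$coefficients[, 1]) / sqrt(2000)
  expect_lt(abs(m_small - m_big), 4 * mc_se)
  # and agreement with the phylogenetically weighted mean of the
  # per-species posterior means (computed at the typical fitted lambda)
  lam_hat <- mean(rs_big$lambda)
  Vi <- solve(lambda_transform(V, lam_hat))
  mbar <- vapply(sprintf("sp%02d", 1:12), function(s)
    mean(draws$slope[draws$species == s]), numeric(1))
  w_mean <- sum(Vi %*% mbar) / sum(Vi)
  expect_lt(abs(m_big - w_mean), 4 * mc_se + 1e-4)
})

test_that("coefficient summaries are stable under species reordering", {
  tree <- taxonomy_tree(synthetic_taxonomy(sprintf("sp%02d", 1:16)))
  st <- simulate_trait_system(tree, effects = c(habitat_breadth = 0.004),
                              noise_sd = 5e-4, n_draws = 50,
                              draw_sd = 0.001, seed = 41)
  V <- tree_vcv(tree)
  rs_a <- resample_pgls(st$draws, st$design, V, n_iter = 2000, seed = 2)
  perm <- c(9:16, 1:8)
  Xp <- st$design[perm, ]
  rs_b <- resample_pgls(st$draws, Xp, V[rownames(Xp), rownames(Xp)],
                        n_iter = 2000, seed = 2)
  hb_a <- rs_a$summary[rs_a$summary$term == "habitat_breadth", ]
  hb_b <- rs_b$summary[rs_b$summary$term == "habitat_breadth", ]
  mc_se <- sd(rs_a$coefficients[, "habitat_breadth"]) / sqrt(2000)
  expect_lt(abs(hb_a$mean - hb_b$mean), 4 * mc_se)
})

test_that("resampling validates its inputs", {
  tree <- taxonomy_tree(synthetic_taxonomy(c("a", "b", "c", "d")))
  V <- tree_vcv(tree)
  X <- cbind(`(Intercept)` = rep(1, 4), x = c(1, 2, 3, 4),
             x2 = c(2, 4, 6, 8))
  rownames(X) <- c("a", "b", "c", "d")
  draws <- tibble::tibble(species = rep(c("a", "b", "c", "d"), each = 3),
                          slope = rnorm(12))
  expect_error(resample_pgls(draws, X, V, n_iter = 10, seed = 1), "singular")
  expect_error(resample_pgls(draws[draws$species != "a", ],
                             X[, 1:2], V, n_iter = 10, seed = 1),
               "No posterior draws")
})

test_that("classify_species tallies interval-based categories", {
  ts <- tibble::tibble(
    species = paste0("s", 1:6),
    mean = c(-0.01, 0.002, 0.001, 0, 0.03, -0.004),
    sd = 0.001,
    lower = c(-0.02, 0.001, -0.001, -0.01, 0.02, -0.006),
    upper = c(-0.005, 0.003, 0.002, 0.01, 0.04, -0.001),
    n_draws = 100,
    classification = c("declining", "increasing", "uncertain", "uncertain",
                       "increasing", "declining")
  )
  out <- classify_species(ts)
  expect_equal(out$n[out$classification == "declining"], 2L)
  expect_equal(out$n[out$classification == "increasing"], 2L)
  expect_equal(out$n[out$classification == "uncertain"], 2L)
  expect_equal(sum(out$pct), 100)

  # all intervals bridging zero
  allunc <- ts
  allunc$classification <- "uncertain"
  out2 <- classify_species(allunc)
  expect_equal(out2$n[out2$classification != "uncertain"], c(0L, 0L))

  # a synthetic 36-interval table equals hand enumeration
  set.seed(6)
  lo <- rnorm(36, 0, 0.01); hi <- lo + abs(rnorm(36, 0.01, 0.01))
  cls <- ifelse(lo > 0, "increasing", ifelse(hi < 0, "declining", "uncertain"))
  tab <- tibble::tibble(species = paste0("t", 1:36), mean = (lo + hi) / 2,
                        sd = 1, lower = lo, upper = hi, n_draws = 10,
                        classification = cls)
  out3 <- classify_species(tab)
  expect_equal(out3$n[match(c("declining", "increasing", "uncertain"),
                            out3$classification)],
               unname(c(sum(hi < 0), sum(lo > 0),
                        sum(lo <= 0 & hi >= 0))))
})
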