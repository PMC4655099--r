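#' Build a taxonomy-based phylogeny with unit branch lengths
#'
#' When no molecular phylogeny is available, taxonomic ranks stand in for
#' tree structure: one internal node per suborder, family and genus, species
#' as tips, and every branch length set to one. A single root sits above the
#' suborders, so species in different suborders share no branches below the
#' root (covariance zero), and every tip lies at depth four. Monotypic
#' chains (e.g. a family with one genus) are kept as distinct unit branches
#' rather than collapsed, preserving the node-per-rank convention.
#'
#' @param taxonomy A data frame with columns `species`, `genus`, `family`,
#'   `suborder` (one row per species).
#' @return A rooted `phylo` object (ape) with unit branch lengths;
#'   serializable with [ape::write.tree()].
#' @examples
#' tax <- tibble::tibble(
#'   species = c("a_x", "a_y", "b_z"),
#'   genus = c("a", "a", "b"),
#'   family = c("f1", "f1", "f2"),
#'   suborder = c("s1", "s1", "s2")
#' )
#' tr <- taxonomy_tree(tax)
#' ape::write.tree(tr)
#' @export
taxonomy_tree <- function(taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  need <- c("species", "genus", "family", "suborder")
  if (!all(need %in% names(taxonomy))) {
    abort(paste0("`taxonomy` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  for (col in need) {
    miss <- is.na(taxonomy[[col]]) | taxonomy[[col]] == ""
    if (any(miss)) {
      abort(paste0("Missing ", col, " for: ",
                   paste(head(taxonomy$species[miss], 5), collapse = ", "), "."))
    }
  }
  if (anyDuplicated(taxonomy$species)) {
    abort("Duplicate species in taxonomy.")
  }
  # rank consistency: each genus in one family, each family in one suborder
  gmap <- distinct(taxonomy, .data$genus, .data$family)
  if (anyDuplicated(gmap$genus)) {
    g <- gmap$genus[duplicated(gmap$genus)][1]
    abort(paste0("Genus '", g, "' is mapped to multiple families."))
  }
  fmap <- distinct(taxonomy, .data$family, .data$suborder)
  if (anyDuplicated(fmap$family)) {
    f <- fmap$family[duplicated(fmap$family)][1]
    abort(paste0("Family '", f, "' is mapped to multiple suborders."))
  }

  n_tip <- nrow(taxonomy)
  subs <- unique(taxonomy$suborder)
  fams <- unique(taxonomy$family)
  gens <- unique(taxonomy$genus)
  # node numbering: tips 1..n, root n+1, then suborders, families, genera
  root <- n_tip + 1L
  sub_id <- setNames(root + seq_along(subs), subs)
  fam_id <- setNames(root + length(subs) + seq_along(fams), fams)
  gen_id <- setNames(root + length(subs) + length(fams) + seq_along(gens), gens)

  edge <- rbind(
    cbind(root, unname(sub_id)),
    cbind(unname(sub_id[fmap$suborder]), unname(fam_id[fmap$family])),
    cbind(unname(fam_id[gmap$family]), unname(gen_id[gmap$genus])),
    cbind(unname(gen_id[taxonomy$genus]), seq_len(n_tip))
  )
  tree <- structure(list(
    edge = edge,
    tip.label = taxonomy$species,
    Nnode = 1L + length(subs) + length(fams) + length(gens),
    edge.length = rep(1, nrow(edge)),
    node.label = c("root", subs, fams, gens)
  ), class = "phylo", order = "cladewise")
  tree
}

#' Phylogenetic variance-covariance matrix of a rooted tree
#'
#' `V[j,k]` is the summed branch length of the shared root-to-MRCA path of
#' tips `j` and `k`; `V[j,j]` is the root-to-tip depth. Under a Brownian
#' model of trait evolution this is the expected trait covariance.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
tree_vcv <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (!ape::is.rooted(tree)) abort("Tree must be rooted.")
  V <- ape::vcv.phylo(ape::collapse.singles(tree))
  V[tree$tip.label, tree$tip.label]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `V` by `lambda`, leaving the
#' diagonal untouched: `lambda = 1` keeps the full phylogenetic structure,
#' `lambda = 0` removes it (phylogenetic independence).
#'
#' @param V Phylogenetic covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix `V(lambda)`.
#' @export
lambda_transform <- function(V, lambda) {
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# Gaussian profile log-likelihood machinery --------------------------------

# whitened GLS solve given the upper Cholesky factor U (Vl = U'U)
gls_chol <- function(y, X, U) {
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qr_Xw <- qr(Xw)
  if (qr_Xw$rank < ncol(X)) abort("Design matrix is singular.")
  beta <- qr.coef(qr_Xw, yw)
  r <- yw - Xw %*% beta
  n <- length(y)
  sigma2 <- sum(r^2) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(U))) + n)
  list(beta = beta, sigma2 = sigma2, logLik = ll, qr = qr_Xw)
}

# eigen-rotated WLS solve: weights w = lambda * ev + (1 - lambda) * v0
gls_eigen <- function(yt, Xt, ev, v0, lambda) {
  w <- lambda * ev + (1 - lambda) * v0
  sw <- 1 / sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qr_Xw <- qr(Xw)
  if (qr_Xw$rank < ncol(Xw)) abort("Design matrix is singular.")
  beta <- qr.coef(qr_Xw, yw)
  r <- yw - Xw %*% beta
  n <- length(yt)
  sigma2 <- sum(r^2) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + n)
  list(beta = beta, sigma2 = sigma2, logLik = ll, qr = qr_Xw)
}

# precompute what the lambda profile needs; fast eigen path only valid when
# the diagonal of V is constant (then V(lambda) = lambda V + (1-lambda) v0 I)
pgls_prep <- function(V) {
  dV <- diag(V)
  if (max(dV) - min(dV) < 1e-10 * max(dV)) {
    eg <- eigen(V, symmetric = TRUE)
    list(fast = TRUE, Q = eg$vectors, ev = eg$values, v0 = dV[1], V = V)
  } else {
    list(fast = FALSE, V = V)
  }
}

pgls_solve_at <- function(y, X, prep, lambda) {
  if (prep$fast) {
    gls_eigen(crossprod(prep$Q, y), crossprod(prep$Q, X),
              prep$ev, prep$v0, lambda)
  } else {
    Vl <- lambda_transform(prep$V, lambda)
    U <- tryCatch(chol(Vl),
                  error = function(e) abort(
                    "V(lambda) is not positive definite."))
    gls_chol(y, X, U)
  }
}

# per-grid-lambda precomputations (fast eigen path only): the design and V
# are fixed across resampling iterations, so the per-lambda weights and the
# Cholesky of the normal-equation matrix X'WX can be reused; only y changes
pgls_grid_cache <- function(X, prep, grid = seq(0, 1, by = 0.01)) {
  if (!prep$fast) return(NULL)
  Xt <- crossprod(prep$Q, X)
  W <- vapply(grid, function(l) 1 / (l * prep$ev + (1 - l) * prep$v0),
              numeric(length(prep$ev)))           # n x n_grid inverse weights
  logdet <- -colSums(log(W))
  U <- lapply(seq_along(grid), function(i) chol(crossprod(Xt * sqrt(W[, i]))))
  list(grid = grid, Xt = Xt, W = W, logdet = logdet, U = U, Q = prep$Q)
}

# profile log-likelihood on the whole grid at once, via normal equations:
# ll(l) = -n/2 log(2 pi sigma2_l) - logdet_l / 2 - n/2,
# sigma2_l = (y'Wy - v' (X'WX)^-1 v) / n with v = X'Wy
profile_ll_grid <- function(y, cache) {
  yt <- as.numeric(crossprod(cache$Q, y))
  n <- length(yt)
  q_all <- colSums(yt^2 * cache$W)
  Vv <- crossprod(cache$Xt, yt * cache$W)          # p x n_grid
  qf <- vapply(seq_along(cache$grid), function(i) {
    t <- backsolve(cache$U[[i]], Vv[, i], transpose = TRUE)
    sum(t * t)
  }, numeric(1))
  sigma2 <- (q_all - qf) / n
  -0.5 * (n * log(2 * pi * sigma2) + cache$logdet + n)
}

# single-lambda profile log-likelihood via normal equations (fast path)
profile_ll_at <- function(yt, Xt, ev, v0, lambda) {
  w <- lambda * ev + (1 - lambda) * v0
  Winv <- 1 / w
  n <- length(yt)
  v <- crossprod(Xt, yt * Winv)
  U <- chol(crossprod(Xt * sqrt(Winv)))
  t <- backsolve(U, v, transpose = TRUE)
  sigma2 <- (sum(yt^2 * Winv) - sum(t * t)) / n
  -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + n)
}

# profile-ML estimate of lambda: 101-point grid scan + bounded refinement,
# ties broken toward smaller lambda
pgls_ml_lambda <- function(y, X, prep, tol = 1e-6, cache = NULL) {
  if (!is.null(cache)) {
    grid <- cache$grid
    ll <- profile_ll_grid(y, cache)
    yt <- as.numeric(crossprod(cache$Q, y))
    obj <- function(l) profile_ll_at(yt, cache$Xt, prep$ev, prep$v0, l)
  } else {
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, function(l) pgls_solve_at(y, X, prep, l)$logLik,
                 numeric(1))
    obj <- function(l) pgls_solve_at(y, X, prep, l)$logLik
  }
  i <- which.max(ll) # first max = smallest lambda on ties
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective > ll[i] + tol) {
    list(lambda = opt$maximum, logLik = opt$objective)
  } else {
    list(lambda = grid[i], logLik = ll[i])
  }
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 V(lambda))`, where `V` is a
#' phylogenetic covariance matrix and `V(lambda)` its Pagel's-lambda
#' transform. With `lambda = "ML"`, lambda is estimated by profile maximum
#' likelihood over `[0, 1]` (101-point grid scan followed by bounded local
#' refinement, tolerance 1e-6, ties broken toward smaller lambda). At
#' `lambda = 0` the estimator reduces to ordinary least squares.
#'
#' @param y Numeric response, one value per species, aligned to `V`'s order
#'   (checked via names when present).
#' @param X Design matrix (include the intercept column), rows aligned to
#'   `y`; must have full column rank.
#' @param V Phylogenetic covariance matrix (see [tree_vcv()]).
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @return An object of class `pgls_fit`: `coefficients`, `lambda`,
#'   `logLik`, `sigma2` (ML residual variance on the `V(lambda)` scale),
#'   `std.error`, `n`, `residuals`, `lambda_estimated`.
#' @export
pgls_fit <- function(y, X, V, lambda = "ML") {
  y <- as.numeric(if (is.data.frame(y)) y[[1]] else y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    abort("`y`, `X` and `V` must agree in size.")
  }
  if (!is.null(rownames(X)) && !is.null(rownames(V)) &&
      !identical(rownames(X), rownames(V))) {
    abort("Rows of `X` and `V` are not in the same species order.")
  }
  if (qr(X)$rank < ncol(X)) abort("Design matrix is singular.")
  prep <- pgls_prep(V)
  if (identical(lambda, "ML")) {
    ml <- pgls_ml_lambda(y, X, prep)
    lam <- ml$lambda
    estimated <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      abort("`lambda` must be \"ML\" or a value in [0, 1].")
    }
    lam <- lambda
    estimated <- FALSE
  }
  fit <- pgls_solve_at(y, X, prep, lam)
  beta <- setNames(as.numeric(fit$beta), colnames(X))
  # std errors from (X' V(lambda)^-1 X)^-1, unbiased variance scaling
  R <- qr.R(fit$qr)
  XtVX_inv <- chol2inv(R)
  s2_unb <- fit$sigma2 * n / max(1, n - ncol(X))
  se <- sqrt(diag(XtVX_inv) * s2_unb)
  structure(list(coefficients = beta, lambda = lam, logLik = fit$logLik,
                 sigma2 = fit$sigma2, std.error = setNames(se, colnames(X)),
                 n = n, k = ncol(X), lambda_estimated = estimated),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Pagel's lambda ",
      if (x$lambda_estimated) "ML" else "fixed", ")\n", sep = "")
  cat("  lambda = ", signif(x$lambda, 4), ", logLik = ",
      signif(x$logLik, 6), ", n = ", x$n, "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$std.error))
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda = x$lambda, logLik = x$logLik, sigma2 = x$sigma2,
         nobs = x$n, df = x$k)
}
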