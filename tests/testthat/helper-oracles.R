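# Independent brute-force implementations used as oracles. Deliberately
# written with plain loops and no shared code with the package internals.

oracle_filter_records <- function(raw, start_year, end_year, species = NULL) {
  seen <- new.env(hash = TRUE)
  sp <- character(0); dt <- as.Date(character(0)); si <- character(0)
  for (i in seq_len(nrow(raw))) {
    d_chr <- as.character(raw$date[i])
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", d_chr)) next
    d <- as.Date(d_chr, format = "%Y-%m-%d")
    if (is.na(d)) next
    yr <- as.integer(format(d, "%Y"))
    if (yr < start_year || yr > end_year) next
    if (!is.null(species) && !(raw$species[i] %in% species)) next
    key <- paste(raw$species[i], d_chr, raw$site[i], sep = "|")
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    sp <- c(sp, raw$species[i]); dt <- c(dt, d); si <- c(si, raw$site[i])
  }
  tibble::tibble(species = sp, date = dt, site = si)
}

oracle_visits <- function(records) {
  key <- paste(records$site, format(records$date, "%Y-%m-%d"), sep = "|")
  out <- list()
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    out[[k]] <- list(site = records$site[rows[1]],
                     date = records$date[rows[1]],
                     species = sort(unique(records$species[rows])))
  }
  out
}

oracle_filter_sites <- function(visits, min_years) {
  keep_rows <- logical(nrow(visits))
  for (s in unique(visits$site)) {
    rows <- which(visits$site == s)
    yrs <- unique(visits$year[rows])
    if (length(yrs) >= min_years) keep_rows[rows] <- TRUE
  }
  visits[keep_rows, ]
}

# shared root-to-MRCA path lengths by explicit edge-path intersection
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    len_of[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_edges <- function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v) # identify the edge by its child node
      v <- parent_of[v]
    }
    nodes
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      shared <- intersect(paths[[j]], paths[[k]])
      V[j, k] <- sum(len_of[shared])
    }
  }
  V
}

# explicit GLS matrix formula, no factorization tricks
oracle_gls <- function(y, X, V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vi <- solve(Vl)
  as.numeric(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}

# small MCMC settings for unit tests (not the analysis defaults)
tiny_config <- function(seed = 1, ...) {
  occu_config(n_chains = 2, n_iter = 700, n_burnin = 250, thin = 1,
              n_adapt = 200, seed = seed, ...)
}
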