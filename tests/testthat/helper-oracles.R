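# Independent brute-force / enumeration oracles used to cross-check the
# package implementations on small instances.  These deliberately avoid the
# code paths (and where possible the base-R routines) they validate.

# Step-mode module coverage by explicit enumeration: a step counts when any
# of its alternatives leaves no required KO unmatched.
oracle_module_coverage <- function(module, kos, mode = "steps") {
  sat <- 0L
  matched <- character(0)
  for (step in module$steps) {
    hit <- FALSE
    for (alt in step) {
      unmatched <- setdiff(alt$required, kos)
      if (length(unmatched) == 0L) hit <- TRUE
      matched <- c(matched, intersect(alt$required, kos))
    }
    if (hit) sat <- sat + 1L
  }
  if (mode == "steps") {
    sat / length(module$steps)
  } else {
    req <- unique(unlist(lapply(module$steps, function(s)
      lapply(s, `[[`, "required"))))
    length(intersect(req, kos)) / length(req)
  }
}

# Pearson chi-squared statistic straight from the textbook formula.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  list(statistic = stat, df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (tie-free) observations to the first group.
oracle_mww_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  u_obs <- sum(outer(a, b, ">")) # count of pairs where a beats b
  u_all <- apply(combos, 2, function(idx) {
    ga <- pooled[idx]; gb <- pooled[-idx]
    sum(outer(ga, gb, ">"))
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Benjamini-Hochberg step-up computed by hand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Midranks computed by explicit counting, then the tie-corrected
# Kruskal-Wallis statistic from the textbook formula.
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Dunn pairwise z from mean midranks and the tie-corrected pooled variance.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mi <- mean(r[idx == i]); mj <- mean(r[idx == j])
  se <- sqrt((n * (n + 1) / 12 - tie_term) *
             (1 / sum(idx == i) + 1 / sum(idx == j)))
  (mi - mj) / se
}

# PCA scores via a direct eigendecomposition of the covariance matrix.
oracle_pca_scores <- function(mat) {
  centred <- sweep(mat, 2, colMeans(mat))
  ev <- eigen(stats::cov(centred), symmetric = TRUE)
  centred %*% ev$vectors
}

# Random small module for oracle-equivalence sweeps.
random_module <- function(id, max_steps = 6, max_alts = 3, max_complex = 3) {
  n_steps <- sample(1:max_steps, 1)
  steps <- lapply(seq_len(n_steps), function(s) {
    n_alt <- sample(1:max_alts, 1)
    lapply(seq_len(n_alt), function(a) {
      size <- sample(1:max_complex, 1)
      list(required = sprintf("K%05d", sample(1:400, size)),
           optional = character())
    })
  })
  module_definition(sprintf("RM%03d", id), "random module", steps)
}

random_genome <- function(id, n_kos = 60, universe = 400) {
  kos <- sprintf("K%05d", sample(1:universe, n_kos))
  genome_annotation(sprintf("rg%03d", id),
                    stats::setNames(rep(1L, length(kos)), kos))
}
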