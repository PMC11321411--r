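#' Inverse-normal z-score of a gene-level p-value
#'
#' Transforms a one-sided gene-level p-value into a standard-normal quantile,
#' `qnorm(1 - p)`, signed by the direction of the effect (+1/-1 for the two
#' groups being contrasted).  P-values are clamped to
#' `[1e-15, 1 - 1e-15]` to keep the transform finite.
#'
#' @param p P-value(s) in (0, 1).
#' @param direction Sign(s) in `{-1, +1}`.
#' @return Numeric vector of signed z-scores.
#' @examples
#' gene_z(0.025, +1)  # ~ 1.96
#' @export
gene_z <- function(p, direction = 1) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p-values must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!all(direction %in% c(-1, 1))) {
    stop("direction must be -1 or +1", call. = FALSE)
  }
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(1 - p) * direction
}

#' Aggregate member z-scores into a raw pathway score
#'
#' @param zs Numeric vector of member gene z-scores (length k >= 1).
#' @return `sum(zs) / sqrt(k)`.
#' @export
pathway_score <- function(zs) {
  k <- length(zs)
  if (k < 1) stop("pathway has no members", call. = FALSE)
  sum(zs) / sqrt(k)
}

#' Monte-Carlo background correction of a raw pathway score
#'
#' Estimates the null mean and standard deviation of the size-k aggregate by
#' repeatedly drawing k genes (without replacement within a draw) from the
#' full gene z-score pool, then standardises the raw score.
#'
#' @param z_raw Raw aggregate score of the pathway.
#' @param k Pathway member count.
#' @param gene_z_pool Numeric vector of all gene z-scores (length >= k).
#' @param n_samples Number of Monte-Carlo draws (>= 100). Default 10000.
#' @param seed Integer seed for reproducibility.
#' @return A list with `mu_k`, `sigma_k`, `z_adj`.
#' @export
background_adjust <- function(z_raw, k, gene_z_pool, n_samples = 10000L,
                              seed = NULL) {
  if (k < 1 || length(gene_z_pool) < k) {
    stop("pool must contain at least k genes", call. = FALSE)
  }
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  if (length(unique(gene_z_pool)) == 1) {
    stop("degenerate background: gene z pool is constant", call. = FALSE)
  }
  bg <- background_moments(k, gene_z_pool, n_samples, seed)
  if (bg$sigma_k == 0) {
    stop("degenerate background: sigma is zero", call. = FALSE)
  }
  list(mu_k = bg$mu_k, sigma_k = bg$sigma_k,
       z_adj = (z_raw - bg$mu_k) / bg$sigma_k)
}

background_moments <- function(k, pool, n_samples, seed) {
  npool <- length(pool)
  draws <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i)
      sum(pool[sample.int(npool, k)]), numeric(1)) / sqrt(k)
  })
  list(mu_k = mean(draws), sigma_k = stats::sd(draws))
}

#' Classify a pathway from its adjusted reporter score
#'
#' The convention signs scores so that enrichment in the group of interest
#' (here: pre-weaning/infant samples) drives the score negative; a pathway
#' is called enriched when `z_adj` is strictly below `-reporter_threshold`.
#'
#' @param z_adj Background-adjusted score(s).
#' @param config An [analysis_config] (supplies `reporter_threshold`).
#' @return Logical vector of enrichment calls.
#' @examples
#' classify_reporter(c(-1.61, -1.6, 2.5))  # TRUE FALSE FALSE
#' @export
classify_reporter <- function(z_adj, config = analysis_config()) {
  z_adj < -config$reporter_threshold
}

#' Reporter-score pathway enrichment analysis
#'
#' Full pipeline: inverse-normal transform of gene-level p-values (signed by
#' effect direction), sum/sqrt(k) aggregation per pathway, Monte-Carlo
#' background standardisation against the full gene pool, and thresholded
#' enrichment calls.
#'
#' @param gene_stats Data frame with columns `gene` (or `ko`), `p`,
#'   `direction`.
#' @param membership Data frame with columns `pathway`, `gene` mapping
#'   pathways to member genes, or a named list of gene-id vectors.
#' @param config An [analysis_config] (supplies `reporter_threshold` and
#'   `reporter_n_samples`).
#' @param seed Integer seed for the background sampling (defaults to
#'   `config$rng_seed`).
#' @return Data frame with one row per pathway: `pathway`, `k`, `z_raw`,
#'   `mu_k`, `sigma_k`, `z_adj`, `enriched`.  Pathways with no annotated
#'   members are skipped with a warning.
#' @export
reporter_analysis <- function(gene_stats, membership,
                              config = analysis_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$rng_seed
  gcol <- if ("gene" %in% names(gene_stats)) "gene" else "ko"
  zs <- gene_z(gene_stats$p, gene_stats$direction)
  names(zs) <- gene_stats[[gcol]]
  if (is.data.frame(membership)) {
    membership <- split(membership$gene, membership$pathway)
  }
  # one background per distinct pathway size, shared across pathways
  rows <- list(); moments <- list()
  for (pw in names(membership)) {
    members <- intersect(membership[[pw]], names(zs))
    if (!length(members)) {
      warning(sprintf("pathway %s has no annotated members; skipped", pw),
              call. = FALSE)
      next
    }
    k <- length(members)
    key <- as.character(k)
    if (is.null(moments[[key]])) {
      moments[[key]] <- background_moments(
        k, zs, config$reporter_n_samples,
        seed = if (is.null(seed)) NULL else seed + k)
    }
    bg <- moments[[key]]
    z_raw <- pathway_score(zs[members])
    z_adj <- (z_raw - bg$mu_k) / bg$sigma_k
    rows[[pw]] <- data.frame(pathway = pw, k = k, z_raw = z_raw,
                             mu_k = bg$mu_k, sigma_k = bg$sigma_k,
                             z_adj = z_adj,
                             enriched = classify_reporter(z_adj, config),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
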