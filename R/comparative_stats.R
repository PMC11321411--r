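#' Remove near-ubiquitous modules before differential analysis
#'
#' Modules found in strictly more than
#' `floor(high_prevalence_fraction * N)` of the N pooled isolates carry
#' little contrast between consortia and are removed (with the study's 29
#' pooled isolates and fraction 0.80 the cutoff is 23 carriers).
#'
#' @param presence Logical matrix, pooled isolates x modules (all consortia
#'   stacked).
#' @param config An [analysis_config].
#' @return Character vector of retained module ids.
#' @export
high_prevalence_filter <- function(presence, config = analysis_config()) {
  n <- nrow(presence)
  cutoff <- floor(config$high_prevalence_fraction * n)
  carriers <- colSums(presence)
  colnames(presence)[carriers <= cutoff]
}

#' Pearson chi-squared test on a contingency table
#'
#' Classic Pearson test without continuity correction, as used for pairwise
#' comparisons of KO-by-subcategory distributions between consortia.
#' All-zero rows and columns are dropped with a warning before testing.
#'
#' @param table Matrix of nonnegative counts with >= 2 rows and >= 2 columns
#'   after dropping empty margins.
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' chisq_test(matrix(c(10, 30, 20, 40), 2))
#' @export
chisq_test <- function(table) {
  table <- as.matrix(table)
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns from contingency table",
            call. = FALSE)
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("contingency table needs >= 2 rows and >= 2 columns", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("degenerate table: expected cell is zero",
                               call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pairwise chi-squared tests between consortia
#'
#' @param counts Matrix, consortia (rows) x subcategories (columns), of KO
#'   counts.
#' @param config An [analysis_config]; p-values are BH-adjusted across the
#'   pairs.
#' @return Data frame with one row per consortium pair: `a`, `b`,
#'   `statistic`, `df`, `p`, `q`.
#' @export
pairwise_chisq <- function(counts, config = analysis_config()) {
  cons <- rownames(counts)
  if (length(cons) < 2) stop("need >= 2 consortia", call. = FALSE)
  pairs <- utils::combn(cons, 2)
  rows <- apply(pairs, 2, function(pr) {
    res <- chisq_test(counts[pr, , drop = FALSE])
    data.frame(a = pr[1], b = pr[2], statistic = res$statistic,
               df = res$df, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Within-consortium functional dissimilarity
#'
#' Euclidean distances between member KO-count vectors (restricted to a
#' retained module/feature set), over all unordered member pairs, summarised
#' by the median.
#'
#' @param counts Numeric matrix, members x features (e.g. KO counts within
#'   retained modules).
#' @param features Optional character vector restricting the columns used.
#' @param name Consortium label carried through to the result.
#' @return An object of class `dissimilarity_index`: list with `consortium`,
#'   `pairwise_distances` (length n(n-1)/2) and `median`.
#' @export
dissimilarity_index <- function(counts, features = NULL, name = "") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) {
    stop("dissimilarity index undefined for < 2 members", call. = FALSE)
  }
  if (!is.null(features)) {
    counts <- counts[, intersect(colnames(counts), features), drop = FALSE]
  }
  d <- as.numeric(stats::dist(counts, method = "euclidean"))
  structure(list(consortium = name, pairwise_distances = d,
                 median = stats::median(d)),
            class = "dissimilarity_index")
}

#' @export
print.dissimilarity_index <- function(x, ...) {
  cat(sprintf("<dissimilarity_index> %s: median %.3f over %d pairs\n",
              x$consortium, x$median, length(x$pairwise_distances)))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based Kruskal-Wallis test (with tie correction) across >= 3 groups,
#' followed by Dunn's pairwise z tests on the pooled ranks; pairwise
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param groups Named list of numeric vectors (>= 2 values each).
#' @return A list with `statistic`, `df`, `p`, and `pairwise` (data frame
#'   `a`, `b`, `z`, `p`, `q`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values",
                                     call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1) {
    kw <- list(statistic = 0, parameter = length(groups) - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  # Dunn's z: difference of mean ranks scaled by the tie-corrected pooled
  # rank variance
  n <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    ni <- sum(g == pr[1]); nj <- sum(g == pr[2])
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    z <- if (se == 0) 0 else
      (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) / se
    data.frame(a = pr[1], b = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$q <- stats::p.adjust(pw$p, method = "BH")
  rownames(pw) <- NULL
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw)
}

#' PCA of per-genome pathway KO counts
#'
#' Column-centred (unscaled) principal component analysis of a genome x
#' pathway count matrix, i.e. the Euclidean geometry of the raw counts.
#' Optionally computes 95% normal concentration ellipses per group from the
#' 2-D score covariance.
#'
#' @param counts Numeric matrix, genomes x pathways (>= 2 of each).
#' @param groups Optional factor/character vector of group labels (one per
#'   genome) for ellipse computation.
#' @param scale. Scale columns to unit variance first? Default `FALSE`.
#' @return A list with `scores` (genomes x components), `explained`
#'   (variance fractions), `sdev`, and `ellipses` (per group: centre,
#'   covariance, radius at the 0.95 chi-squared quantile) when `groups` is
#'   given.  A zero-variance input yields all-zero scores and
#'   `explained = NA`, flagged via `degenerate = TRUE`.
#' @export
pca_scores <- function(counts, groups = NULL, scale. = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need >= 2 genomes and >= 2 pathways", call. = FALSE)
  }
  centred <- scale(counts, center = TRUE, scale = FALSE)
  if (all(abs(centred) < 1e-12)) {
    k <- min(dim(counts))
    scores <- matrix(0, nrow(counts), k,
                     dimnames = list(rownames(counts), paste0("PC", 1:k)))
    return(list(scores = scores, explained = rep(NA_real_, k),
                sdev = rep(0, k), ellipses = NULL, degenerate = TRUE))
  }
  pc <- stats::prcomp(counts, center = TRUE, scale. = scale.)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  ellipses <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    ellipses <- lapply(split(seq_len(nrow(counts)), groups), function(idx) {
      sc <- pc$x[idx, 1:2, drop = FALSE]
      list(centre = colMeans(sc),
           cov = if (length(idx) > 2) stats::cov(sc) else NULL,
           radius = sqrt(stats::qchisq(0.95, df = 2)))
    })
  }
  list(scores = pc$x, explained = explained, sdev = pc$sdev,
       ellipses = ellipses, degenerate = FALSE)
}

#' KO-by-subcategory contingency counts for consortia
#'
#' Builds the consortium x subcategory matrix of distinct KO counts (or
#' KO-token counts with multiplicity) used in the pairwise chi-squared
#' comparisons, restricted to KOs of retained modules.
#'
#' @param consortia Named list of [consortium_spec] objects.
#' @param hierarchy A `functional_hierarchy`.
#' @param multiplicity Count KO copies rather than distinct KOs?
#'   Default `FALSE`.
#' @return Integer matrix, consortia x subcategories.
#' @export
subcategory_counts <- function(consortia, hierarchy, multiplicity = FALSE) {
  subcats <- sort(unique(hierarchy$subcategory))
  mat <- matrix(0L, length(consortia), length(subcats),
                dimnames = list(names(consortia), subcats))
  for (i in seq_along(consortia)) {
    cons <- consortia[[i]]
    if (multiplicity) {
      pooled <- integer(0)
      for (g in cons$members) {
        for (ko in names(g$ko_counts)) {
          sc <- unique(hierarchy$subcategory[hierarchy$ko == ko])
          for (s in sc) {
            mat[i, s] <- mat[i, s] + g$ko_counts[[ko]]
          }
        }
      }
    } else {
      kos <- union_kos(cons)
      hits <- unique(hierarchy[hierarchy$ko %in% kos,
                               c("ko", "subcategory")])
      tab <- table(hits$subcategory)
      mat[i, names(tab)] <- as.integer(tab)
    }
  }
  mat[, colSums(mat) > 0, drop = FALSE]
}
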