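#' Construct an amino-acid concentration table
#'
#' Samples x analytes concentrations (nmol/g) with a two-group design.
#' Values below the limit of detection (LOD) are stored as `NA` and handled
#' by the configured LOD policy when summing or testing.
#'
#' @param values Numeric matrix, samples (rows) x analytes (columns), in
#'   nmol/g; `NA` marks below-LOD measurements.
#' @param groups Character/factor vector of group labels, one per sample
#'   (exactly two levels for testing).
#' @param lod Limit of detection, nmol/g. Default 1.
#' @return An object of class `aa_table`.
#' @export
aa_table <- function(values, groups, lod = 1) {
  values <- as.matrix(values)
  if (length(groups) != nrow(values)) {
    stop("one group label per sample required", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  structure(list(values = values, groups = as.character(groups), lod = lod),
            class = "aa_table")
}

#' @export
print.aa_table <- function(x, ...) {
  cat(sprintf("<aa_table> %d samples x %d analytes (LOD %g nmol/g); groups: %s\n",
              nrow(x$values), ncol(x$values), x$lod,
              paste(names(table(x$groups)), table(x$groups),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Below-LOD substitution under the configured policy.
lod_fill <- function(values, lod, policy) {
  fill <- switch(policy, zero = 0, half = lod / 2)
  values[is.na(values)] <- fill
  values
}

#' Total free amino-acid concentration of a sample
#'
#' @param table An [aa_table].
#' @param sample Sample id (rowname) or index; if missing, totals for all
#'   samples are returned.
#' @param config An [analysis_config] (supplies the LOD policy).
#' @return Total concentration(s), nmol/g.
#' @export
total_free_aa <- function(table, sample = NULL, config = analysis_config()) {
  vals <- lod_fill(table$values, table$lod, config$lod_policy)
  totals <- rowSums(vals)
  if (is.null(sample)) totals else {
    if (is.character(sample) && !sample %in% rownames(table$values)) {
      stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
    }
    unname(totals[sample])
  }
}

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Exact enumeration when the pooled sample size is at most 20 and the data
#' are tie-free; otherwise the normal approximation with tie and continuity
#' correction.  The returned U is the rank-sum statistic for the first
#' group.
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @return A list with `U` and `p`.
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mww_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  if (all(c(a, b) == c(a, b)[1])) {
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(res$statistic), p = min(res$p.value, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-analyte two-group comparison with FDR control
#'
#' Mann-Whitney-Wilcoxon test per analyte, Benjamini-Hochberg adjustment
#' across analytes, group medians reported alongside.
#'
#' @param table An [aa_table] with exactly two groups.
#' @param config An [analysis_config] (supplies `alpha` and the LOD policy).
#' @return Data frame with one row per analyte: `analyte`, `median_A`,
#'   `median_B` (groups in sorted label order), `U`, `p`, `q`,
#'   `significant` (q < alpha).
#' @export
compare_aa_groups <- function(table, config = analysis_config()) {
  lv <- sort(unique(table$groups))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(table$groups) < 2)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  vals <- lod_fill(table$values, table$lod, config$lod_policy)
  ia <- table$groups == lv[1]; ib <- table$groups == lv[2]
  rows <- lapply(colnames(vals), function(an) {
    res <- mww_test(vals[ia, an], vals[ib, an])
    data.frame(analyte = an,
               median_A = stats::median(vals[ia, an]),
               median_B = stats::median(vals[ib, an]),
               U = res$U, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < config$alpha
  attr(out, "groups") <- lv
  rownames(out) <- NULL
  out
}

#' Row-wise z-score normalisation
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation 1
#' (the usual pre-processing before concentration heatmaps).  Constant rows
#' cannot be scaled and are emitted as all-zero with a warning.
#'
#' @param mat Numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  out <- t(apply(mat, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(out) <- dimnames(mat)
  const <- apply(mat, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning(sprintf("%d constant row(s) emitted as zeros", sum(const)),
            call. = FALSE)
  }
  out
}

#' Ward-1 hierarchical clustering order
#'
#' Agglomerative clustering with the Ward-1 criterion: the Lance-Williams
#' update applied to unsquared Euclidean distances (`hclust` method
#' `"ward.D"`), as distinct from the squared-distance Ward-2 variant.
#' Returns the dendrogram leaf order and merge heights.
#'
#' @param mat Numeric matrix; rows are clustered.
#' @param axis `"rows"` (default) or `"cols"`.
#' @param variant `"ward1"` (default, unsquared) or `"ward2"`.
#' @return A list with `order` (leaf labels in dendrogram order), `heights`
#'   (merge heights) and the `hclust` object.
#' @export
ward_order <- function(mat, axis = c("rows", "cols"),
                       variant = c("ward1", "ward2")) {
  axis <- match.arg(axis)
  variant <- match.arg(variant)
  mat <- as.matrix(mat)
  if (axis == "cols") mat <- t(mat)
  if (nrow(mat) < 2) stop("need >= 2 items to cluster", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("i", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = if (variant == "ward1") "ward.D" else "ward.D2")
  list(order = hc$labels[hc$order], heights = hc$height, hclust = hc)
}
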