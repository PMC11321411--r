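#' Non-redundant KO set of a consortium
#'
#' The union of member KO sets; duplicate KOs (multi-copy or shared across
#' members) are counted once.
#'
#' @param consortium A [consortium_spec].
#' @return Sorted character vector of KO ids.
#' @export
union_kos <- function(consortium) {
  sort(unique(unlist(lapply(consortium$members, ko_set))))
}

#' Genome x KO copy-count matrix for a consortium
#'
#' @param consortium A [consortium_spec].
#' @return Integer matrix, members (rows, in consortium order) x KOs
#'   (columns, sorted).
#' @export
ko_matrix <- function(consortium) {
  kos <- union_kos(consortium)
  ids <- vapply(consortium$members, `[[`, character(1), "genome_id")
  mat <- matrix(0L, length(ids), length(kos), dimnames = list(ids, kos))
  for (i in seq_along(consortium$members)) {
    cc <- consortium$members[[i]]$ko_counts
    mat[i, names(cc)] <- as.integer(cc)
  }
  mat
}

#' Summarise a consortium's functional content
#'
#' @param consortium A [consortium_spec].
#' @param profile Optional module completeness profile from
#'   [profile_consortium_modules] (supplies the module union).
#' @return An object of class `consortium_profile` with the non-redundant KO
#'   set, the per-member KO copy matrix and, if available, the module union.
#' @export
consortium_profile <- function(consortium, profile = NULL) {
  structure(
    list(
      name = consortium$name,
      ko_union = union_kos(consortium),
      module_union = if (is.null(profile)) character() else
        consortium_module_set(profile),
      ko_matrix = ko_matrix(consortium)
    ),
    class = "consortium_profile"
  )
}

#' @export
print.consortium_profile <- function(x, ...) {
  cat(sprintf("<consortium_profile> %s: %d non-redundant KOs, %d modules, %d members\n",
              x$name, length(x$ko_union), length(x$module_union),
              nrow(x$ko_matrix)))
  invisible(x)
}

#' KOs unique to one consortium
#'
#' Set difference on presence: KOs found in at least one member of the target
#' consortium and in no member of any other.  Copy numbers play no role.
#'
#' @param target A `consortium_profile`.
#' @param others List of `consortium_profile` objects (>= 1).
#' @return Sorted character vector of KO ids.
#' @export
unique_kos <- function(target, others) {
  if (!length(others)) stop("need >= 1 other consortium", call. = FALSE)
  other_union <- unique(unlist(lapply(others, `[[`, "ko_union")))
  sort(setdiff(target$ko_union, other_union))
}

#' Build a KO prevalence table for a consortium
#'
#' For each KO (optionally restricted to a filter set) the table reports the
#' per-isolate copy counts in consortium member order, the summed gene count,
#' and the prevalence (number of carrier isolates out of consortium size).
#' Rows are restricted to KOs carried by at least
#' `config$prevalence_min_isolates` members and sorted by carriers
#' descending, gene count descending, then KO id.
#'
#' @param consortium A [consortium_spec].
#' @param ko_filter Optional character vector of KO ids to restrict to; KOs
#'   absent from every genome are dropped silently.
#' @param config An [analysis_config].
#' @param hierarchy Optional `functional_hierarchy` used to attach a pathway
#'   label (first listed pathway) per KO.
#' @return A data frame with columns `ko`, `pathway`, one count column per
#'   isolate, `gene_count`, `n_present`, `n_total`.
#' @export
build_prevalence_table <- function(consortium, ko_filter = NULL,
                                   config = analysis_config(),
                                   hierarchy = NULL) {
  mat <- ko_matrix(consortium)
  kos <- colnames(mat)
  if (!is.null(ko_filter)) kos <- intersect(ko_filter, kos)
  if (!length(kos)) {
    return(empty_prevalence_table(rownames(mat)))
  }
  mat <- mat[, kos, drop = FALSE]
  n_present <- colSums(mat > 0)
  gene_count <- colSums(mat)
  keep <- n_present >= config$prevalence_min_isolates
  kos <- kos[keep]
  if (!length(kos)) return(empty_prevalence_table(rownames(mat)))
  mat <- mat[, kos, drop = FALSE]
  n_present <- n_present[keep]; gene_count <- gene_count[keep]
  ord <- order(-n_present, -gene_count, kos)
  pathway <- if (is.null(hierarchy)) rep(NA_character_, length(kos)) else
    vapply(kos, function(k) hierarchy_lookup(hierarchy, k)$pathway[1],
           character(1))
  out <- data.frame(ko = kos, pathway = pathway, t(mat),
                    gene_count = as.integer(gene_count),
                    n_present = as.integer(n_present),
                    n_total = nrow(mat),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_prevalence_table <- function(isolates) {
  cols <- c(list(ko = character(), pathway = character()),
            stats::setNames(rep(list(integer()), length(isolates)), isolates),
            list(gene_count = integer(), n_present = integer(),
                 n_total = integer()))
  do.call(data.frame,
          c(cols, list(stringsAsFactors = FALSE, check.names = FALSE)))
}

#' Module prevalence matrix across consortia
#'
#' For each module (optionally restricted to one functional category) the
#' matrix gives the proportion of each consortium's members in which the
#' module is present.  Rows are sorted by the first (reference) consortium's
#' proportion, descending, ties broken by module id.
#'
#' @param profiles Named list of completeness profiles (one per consortium,
#'   from [profile_consortium_modules] on a shared module database).
#' @param modules The module database (list of [module_definition]); needed
#'   only when `category_filter` is given.
#' @param category_filter Optional category name to restrict modules to.
#' @return Numeric matrix, modules x consortia, values in [0, 1].
#' @export
gmm_prevalence_matrix <- function(profiles, modules = NULL,
                                  category_filter = NULL) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, function(p)
      attr(p, "consortium") %||% "consortium", character(1))
  }
  mod_ids <- sort(unique(unlist(lapply(profiles, `[[`, "module_id"))))
  if (!is.null(category_filter)) {
    if (is.null(modules)) {
      stop("category_filter requires the module database", call. = FALSE)
    }
    cats <- vapply(modules, `[[`, character(1), "category")
    ids <- vapply(modules, `[[`, character(1), "module_id")
    keep <- ids[cats == category_filter]
    if (!length(keep)) {
      warning(sprintf("unknown category '%s': empty matrix", category_filter),
              call. = FALSE)
    }
    mod_ids <- intersect(mod_ids, keep)
  }
  mat <- matrix(NA_real_, length(mod_ids), length(profiles),
                dimnames = list(mod_ids, names(profiles)))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    n <- length(unique(p$genome_id))
    carriers <- tapply(p$present, p$module_id, sum)
    mat[, j] <- as.numeric(carriers[mod_ids]) / n
    mat[is.na(mat[, j]), j] <- 0
  }
  if (nrow(mat)) {
    ord <- order(-mat[, 1], rownames(mat))
    mat <- mat[ord, , drop = FALSE]
  }
  mat
}

#' Allocate a genome's KOs to functional categories
#'
#' Counts distinct KOs per (category, subcategory) through the functional
#' hierarchy.  A KO annotated under several categories contributes once to
#' each (the per-category sums are therefore not additive-exclusive).  Also
#' reports how many of the genome's KOs belong to at least one module of the
#' supplied database.
#'
#' @param genome A [genome_annotation].
#' @param hierarchy A `functional_hierarchy`.
#' @param modules Optional module database (list of [module_definition]).
#' @return A list with `counts` (data frame `category`, `subcategory`,
#'   `n_kos`) and `n_module_kos` (distinct genome KOs found in >= 1 module;
#'   `NA` when `modules` is NULL).
#' @export
category_allocation <- function(genome, hierarchy, modules = NULL) {
  kos <- ko_set(genome)
  hits <- hierarchy[hierarchy$ko %in% kos, , drop = FALSE]
  unannotated <- setdiff(kos, hits$ko)
  if (length(unannotated)) {
    hits <- rbind(as.data.frame(hits),
                  data.frame(ko = unannotated, pathway = "unannotated",
                             category = "unannotated",
                             subcategory = "unannotated",
                             stringsAsFactors = FALSE))
  }
  key <- unique(hits[, c("ko", "category", "subcategory")])
  agg <- stats::aggregate(list(n_kos = key$ko),
                          by = list(category = key$category,
                                    subcategory = key$subcategory),
                          FUN = length)
  agg <- agg[order(agg$category, agg$subcategory), ]
  rownames(agg) <- NULL
  n_module_kos <- NA_integer_
  if (!is.null(modules)) {
    all_module_kos <- unique(unlist(lapply(modules, module_kos,
                                           include_optional = TRUE)))
    n_module_kos <- length(intersect(kos, all_module_kos))
  }
  list(counts = agg, n_module_kos = n_module_kos)
}

#' Per-genome module-KO totals and consortium median
#'
#' @param consortium A [consortium_spec].
#' @param modules Module database.
#' @return A list with `per_genome` (named integer vector of distinct KOs
#'   belonging to >= 1 module, per member) and `median`.
#' @export
module_ko_totals <- function(consortium, modules) {
  all_module_kos <- unique(unlist(lapply(modules, module_kos,
                                         include_optional = TRUE)))
  per <- vapply(consortium$members, function(g)
    length(intersect(ko_set(g), all_module_kos)), integer(1))
  names(per) <- vapply(consortium$members, `[[`, character(1), "genome_id")
  list(per_genome = per, median = stats::median(per))
}
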