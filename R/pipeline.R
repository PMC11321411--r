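#' Run a pipeline stage
#'
#' Thin orchestration over the package's functions: each stage reads its
#' inputs, runs one analysis, and writes TSV results with a provenance
#' header (tool version, full configuration, seed) under `out_dir`.  Reruns
#' with an identical configuration and seed produce byte-identical outputs.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{Generate a synthetic module database, three consortia
#'     (9, 8 and 12 members), and write annotations, module flat file and
#'     consortium metadata.}
#'   \item{profile}{Score module completeness for each consortium against
#'     the module database.}
#'   \item{compare}{Consortium KO/module set algebra, unique KOs and
#'     prevalence tables.}
#'   \item{stats}{High-prevalence filter, pairwise chi-squared,
#'     dissimilarity indices and Kruskal-Wallis/Dunn across consortia.}
#'   \item{reporter}{Reporter-score enrichment from gene-stat and membership
#'     tables.}
#'   \item{metabolome}{Two-group amino-acid comparison, z-scored matrix and
#'     Ward leaf orders.}
#'   \item{clusters}{Sialic-acid catabolism (nan/nanH) cluster calls.}
#' }
#'
#' @param stage One of `"simulate"`, `"profile"`, `"compare"`, `"stats"`,
#'   `"reporter"`, `"metabolome"`, `"clusters"`.
#' @param out_dir Output directory (created if needed); inputs are never
#'   modified.
#' @param config An [analysis_config]; validated before any input is read.
#' @param inputs Named list of stage inputs (see Details); the `simulate`
#'   stage needs none, later stages default to the files `simulate` wrote in
#'   `out_dir`.
#' @param seed Integer seed recorded in provenance and used by randomised
#'   stages (defaults to `config$rng_seed`, then 1).
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(stage = c("simulate", "profile", "compare", "stats",
                                   "reporter", "metabolome", "clusters"),
                         out_dir, config = analysis_config(),
                         inputs = list(), seed = NULL) {
  stage <- match.arg(stage)
  if (!inherits(config, "analysis_config")) {
    stop("config must be an analysis_config()", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$rng_seed %||% 1L
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- switch(stage,
    simulate = stage_simulate(out_dir, config, seed),
    profile = stage_profile(out_dir, config, inputs),
    compare = stage_compare(out_dir, config, inputs),
    stats = stage_stats(out_dir, config, inputs),
    reporter = stage_reporter(out_dir, config, inputs, seed),
    metabolome = stage_metabolome(out_dir, config, inputs),
    clusters = stage_clusters(out_dir, config, inputs)
  )
  invisible(written)
}

sim_consortia_sizes <- c(preweaning = 9L, adultA = 8L, adultB = 12L)

load_sim_consortia <- function(dir) {
  meta_path <- file.path(dir, "consortium_metadata.tsv")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            comment.char = "#")
  lapply(split(meta, meta$consortium)[unique(meta$consortium)], function(rows) {
    members <- lapply(seq_len(nrow(rows)), function(i)
      read_ko_annotation(file.path(dir, rows$annotation_path[i]),
                         rows$genome_id[i],
                         taxonomy = c(phylum = rows$phylum[i],
                                      family = rows$family[i])))
    consortium_spec(rows$consortium[1], members)
  })
}

stage_simulate <- function(out_dir, config, seed) {
  db <- gen_module_db(n_modules = 30, seed = seed)
  write_gmm_definitions(db, file.path(out_dir, "modules.gmm"))
  meta <- list()
  for (i in seq_along(sim_consortia_sizes)) {
    nm <- names(sim_consortia_sizes)[i]
    gen <- gen_consortium(nm, sim_consortia_sizes[[i]], db,
                          seed = seed + i)
    for (g in gen$consortium$members) {
      rel <- paste0(g$genome_id, ".ko.tsv")
      write_ko_annotation(g, file.path(out_dir, rel))
      meta[[length(meta) + 1]] <- data.frame(
        genome_id = g$genome_id, consortium = nm,
        phylum = unname(g$taxonomy["phylum"]),
        family = unname(g$taxonomy["family"]),
        annotation_path = rel, stringsAsFactors = FALSE)
    }
    write_stage_tsv(gen$truth$planted,
                    file.path(out_dir, paste0("truth_", nm, ".tsv")),
                    config, extra = list(stage = "simulate", seed = seed))
  }
  meta <- do.call(rbind, meta)
  write_stage_tsv(meta, file.path(out_dir, "consortium_metadata.tsv"),
                  config, extra = list(stage = "simulate", seed = seed))
  c(file.path(out_dir, "modules.gmm"),
    file.path(out_dir, "consortium_metadata.tsv"))
}

stage_profile <- function(out_dir, config, inputs) {
  dir <- inputs$data_dir %||% out_dir
  db <- read_gmm_definitions(inputs$modules %||% file.path(dir, "modules.gmm"))
  consortia <- load_sim_consortia(dir)
  files <- character(0)
  for (nm in names(consortia)) {
    prof <- profile_consortium_modules(consortia[[nm]], db, config)
    f <- file.path(out_dir, paste0("completeness_", nm, ".tsv"))
    write_stage_tsv(prof, f, config, extra = list(stage = "profile",
                                                  consortium = nm))
    files <- c(files, f)
  }
  files
}

stage_compare <- function(out_dir, config, inputs) {
  dir <- inputs$data_dir %||% out_dir
  consortia <- load_sim_consortia(dir)
  profiles <- lapply(names(consortia), function(nm) {
    f <- file.path(dir, paste0("completeness_", nm, ".tsv"))
    if (file.exists(f)) read_stage_tsv(f) else NULL
  })
  names(profiles) <- names(consortia)
  cps <- lapply(names(consortia), function(nm)
    consortium_profile(consortia[[nm]], profiles[[nm]]))
  names(cps) <- names(consortia)
  summary <- data.frame(
    consortium = names(cps),
    n_members = vapply(consortia, function(cs) length(cs$members), integer(1)),
    n_kos = vapply(cps, function(p) length(p$ko_union), integer(1)),
    n_modules = vapply(cps, function(p) length(p$module_union), integer(1)),
    n_unique_kos = vapply(seq_along(cps), function(i)
      length(unique_kos(cps[[i]], cps[-i])), integer(1)),
    stringsAsFactors = FALSE)
  f1 <- file.path(out_dir, "consortium_summary.tsv")
  write_stage_tsv(summary, f1, config, extra = list(stage = "compare"))
  ref <- names(cps)[1]
  prev <- build_prevalence_table(consortia[[ref]],
                                 ko_filter = unique_kos(cps[[1]], cps[-1]),
                                 config = config)
  f2 <- file.path(out_dir, paste0("prevalence_", ref, ".tsv"))
  write_stage_tsv(prev, f2, config, extra = list(stage = "compare"))
  c(f1, f2)
}

stage_stats <- function(out_dir, config, inputs) {
  dir <- inputs$data_dir %||% out_dir
  consortia <- load_sim_consortia(dir)
  profiles <- lapply(names(consortia), function(nm)
    read_stage_tsv(file.path(dir, paste0("completeness_", nm, ".tsv"))))
  names(profiles) <- names(consortia)
  pooled <- do.call(rbind, profiles)
  retained <- high_prevalence_filter(presence_matrix(pooled), config)
  db <- read_gmm_definitions(inputs$modules %||% file.path(dir, "modules.gmm"))
  db_ids <- vapply(db, `[[`, character(1), "module_id")
  groups <- lapply(names(consortia), function(nm) {
    counts <- module_ko_count_matrix(consortia[[nm]],
                                     db[db_ids %in% retained])
    dissimilarity_index(counts, name = nm)$pairwise_distances
  })
  names(groups) <- names(consortia)
  kd <- kruskal_dunn(groups)
  stats_df <- data.frame(
    test = c("kruskal_wallis",
             paste0("dunn_", kd$pairwise$a, "_vs_", kd$pairwise$b)),
    statistic = c(kd$statistic, kd$pairwise$z),
    df = c(kd$df, rep(NA, nrow(kd$pairwise))),
    p = c(kd$p, kd$pairwise$p),
    q = c(NA, kd$pairwise$q),
    stringsAsFactors = FALSE)
  f1 <- file.path(out_dir, "dissimilarity_tests.tsv")
  write_stage_tsv(stats_df, f1, config,
                  extra = list(stage = "stats",
                               n_retained_modules = length(retained)))
  f1
}

# genome x module matrix of KO copies falling inside each retained module
module_ko_count_matrix <- function(consortium, modules) {
  ids <- vapply(consortium$members, `[[`, character(1), "genome_id")
  mids <- vapply(modules, `[[`, character(1), "module_id")
  mat <- matrix(0, length(ids), length(mids), dimnames = list(ids, mids))
  for (j in seq_along(modules)) {
    kos <- module_kos(modules[[j]], include_optional = TRUE)
    for (i in seq_along(consortium$members)) {
      cc <- consortium$members[[i]]$ko_counts
      mat[i, j] <- sum(cc[names(cc) %in% kos])
    }
  }
  mat
}

stage_reporter <- function(out_dir, config, inputs, seed) {
  if (is.null(inputs$gene_stats)) {
    ds <- gen_reporter_dataset(n_genes = 2000, n_pathways = 50,
                               n_enriched = 5, effect_mean_z = 1.0,
                               seed = seed)
    gene_stats <- ds$gene_stats; membership <- ds$membership
  } else {
    gene_stats <- read_stage_tsv(inputs$gene_stats)
    membership <- read_stage_tsv(inputs$membership)
  }
  res <- reporter_analysis(gene_stats, membership, config, seed = seed)
  f <- file.path(out_dir, "reporter_scores.tsv")
  write_stage_tsv(res, f, config,
                  extra = list(stage = "reporter", seed = seed))
  f
}

stage_metabolome <- function(out_dir, config, inputs) {
  if (is.null(inputs$concentrations)) {
    stop("metabolome stage requires inputs$concentrations (TSV: sample, group, analyte columns)",
         call. = FALSE)
  }
  df <- read_stage_tsv(inputs$concentrations)
  vals <- as.matrix(df[, setdiff(names(df), c("sample", "group")),
                       drop = FALSE])
  rownames(vals) <- df$sample
  tab <- aa_table(vals, df$group, lod = config$lod)
  comp <- compare_aa_groups(tab, config)
  f1 <- file.path(out_dir, "aa_comparison.tsv")
  write_stage_tsv(comp, f1, config, extra = list(stage = "metabolome"))
  filled <- lod_fill(tab$values, tab$lod, config$lod_policy)
  z <- zscore_rows(t(filled))
  zdf <- data.frame(analyte = rownames(z), z, check.names = FALSE,
                    stringsAsFactors = FALSE)
  f2 <- file.path(out_dir, "aa_zscores.tsv")
  write_stage_tsv(zdf, f2, config, extra = list(stage = "metabolome"))
  ord <- data.frame(
    axis = c(rep("analytes", nrow(z)), rep("samples", ncol(z))),
    id = c(ward_order(z)$order, ward_order(z, axis = "cols")$order),
    stringsAsFactors = FALSE)
  f3 <- file.path(out_dir, "aa_leaf_order.tsv")
  write_stage_tsv(ord, f3, config, extra = list(stage = "metabolome"))
  c(f1, f2, f3)
}

stage_clusters <- function(out_dir, config, inputs) {
  dir <- inputs$data_dir %||% out_dir
  consortia <- load_sim_consortia(dir)
  rules <- list(nan_cluster_rule(), nanH_rule())
  calls <- do.call(rbind, lapply(consortia, detect_clusters, rules = rules))
  rownames(calls) <- NULL
  f <- file.path(out_dir, "cluster_calls.tsv")
  write_stage_tsv(calls, f, config, extra = list(stage = "clusters"))
  f
}
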