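# sample() treats a scalar as 1:n; draw uniformly from an inclusive range
sample_range <- function(lo, hi) {
  if (lo == hi) as.integer(lo) else sample(lo:hi, 1)
}

#' Generate a synthetic module database
#'
#' Builds a random but structurally valid module database for closed-loop
#' testing.  Module KOs are drawn without replacement from a dedicated id
#' block, so modules never share KOs and planted step coverage is exact by
#' construction; background KOs (see [gen_consortium]) come from a disjoint
#' block.
#'
#' @param n_modules Number of modules.
#' @param steps_range Integer range (length 2) of steps per module.
#' @param alternatives_range Integer range of alternatives per step.
#' @param complex_prob Probability that an alternative is a multi-KO complex
#'   (2-3 members) rather than a single KO.
#' @param seed Integer seed.
#' @param categories Category labels cycled over the modules.
#' @return List of [module_definition] objects.
#' @export
gen_module_db <- function(n_modules, steps_range = c(2L, 5L),
                          alternatives_range = c(1L, 3L),
                          complex_prob = 0.2, seed = 1L,
                          categories = c("carbohydrate degradation",
                                         "lipid degradation",
                                         "amino acid degradation")) {
  if (n_modules == 0) return(list())
  with_seed(seed, {
    # module KO ids live in K1####..K4####; background uses K9####
    pool <- sprintf("K%05d", sample(10000:49999))
    nxt <- 1
    take <- function(n) {
      ids <- pool[nxt:(nxt + n - 1)]
      nxt <<- nxt + n
      ids
    }
    lapply(seq_len(n_modules), function(i) {
      n_steps <- sample_range(steps_range[1], steps_range[2])
      steps <- lapply(seq_len(n_steps), function(s) {
        n_alt <- sample_range(alternatives_range[1], alternatives_range[2])
        lapply(seq_len(n_alt), function(a) {
          size <- if (stats::runif(1) < complex_prob) sample(2:3, 1) else 1L
          list(required = take(size), optional = character())
        })
      })
      module_definition(sprintf("SM%04d", i), sprintf("synthetic module %d", i),
                        steps,
                        category = categories[(i - 1) %% length(categories) + 1])
    })
  })
}

#' Generate a consortium with planted module completeness
#'
#' Each synthetic genome receives exactly the KOs needed to satisfy its
#' planted fraction of steps for each module (the first alternative of the
#' first `round(coverage * n_steps)` steps), plus Poisson background KOs
#' drawn from an id block disjoint from all module KOs.  Planted step
#' coverage is therefore recovered exactly by the module engine.
#'
#' @param name Consortium name.
#' @param n_genomes Number of member genomes.
#' @param module_db Module database from [gen_module_db].
#' @param completeness_plan Optional data frame `genome` (index), `module`
#'   (module id), `coverage` (multiple of 1/steps).  Unplanned pairs get a
#'   random achievable coverage.
#' @param background_ko_rate Poisson mean of background KOs per genome.
#' @param seed Integer seed.
#' @param taxonomy_pool Data frame of `phylum`, `family` rows sampled for
#'   member taxonomy.
#' @return A list with `consortium` (a [consortium_spec]) and `truth`
#'   (planted coverage per genome x module plus generator parameters).
#' @export
gen_consortium <- function(name, n_genomes, module_db,
                           completeness_plan = NULL,
                           background_ko_rate = 50, seed = 1L,
                           taxonomy_pool = data.frame(
                             phylum = c("Bacillota", "Bacteroidota",
                                        "Pseudomonadota"),
                             family = c("Lachnospiraceae", "Tannerellaceae",
                                        "Enterobacteriaceae"),
                             stringsAsFactors = FALSE)) {
  stopifnot(n_genomes >= 1, length(module_db) >= 1)
  mod_ids <- vapply(module_db, `[[`, character(1), "module_id")
  n_steps <- vapply(module_db, function(m) length(m$steps), integer(1))
  names(n_steps) <- mod_ids
  if (!is.null(completeness_plan)) {
    bad <- abs(completeness_plan$coverage * n_steps[completeness_plan$module] -
               round(completeness_plan$coverage * n_steps[completeness_plan$module])) > 1e-9
    if (any(bad)) {
      stop(sprintf("unachievable coverage for module(s): %s",
                   paste(unique(completeness_plan$module[bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    planted <- expand.grid(genome = seq_len(n_genomes), module = mod_ids,
                           stringsAsFactors = FALSE)
    planted$coverage <- vapply(seq_len(nrow(planted)), function(i) {
      t <- n_steps[[planted$module[i]]]
      sample(0:t, 1) / t
    }, numeric(1))
    if (!is.null(completeness_plan)) {
      for (i in seq_len(nrow(completeness_plan))) {
        sel <- planted$genome == completeness_plan$genome[i] &
               planted$module == completeness_plan$module[i]
        planted$coverage[sel] <- completeness_plan$coverage[i]
      }
    }
    members <- lapply(seq_len(n_genomes), function(gi) {
      kos <- character(0)
      for (m in module_db) {
        cov <- planted$coverage[planted$genome == gi &
                                planted$module == m$module_id]
        s <- round(cov * length(m$steps))
        if (s > 0) {
          for (step in m$steps[seq_len(s)]) {
            kos <- c(kos, step[[1]]$required)
          }
        }
      }
      n_bg <- stats::rpois(1, background_ko_rate)
      if (n_bg > 0) {
        kos <- c(kos, sprintf("K9%04d", sample(0:9999, n_bg)))
      }
      tax <- taxonomy_pool[sample(nrow(taxonomy_pool), 1), ]
      counts <- table(kos)
      genome_annotation(
        sprintf("%s_g%02d", name, gi),
        stats::setNames(as.integer(counts), names(counts)),
        taxonomy = c(phylum = tax$phylum, family = tax$family))
    })
    list(
      consortium = consortium_spec(name, members),
      truth = list(planted = planted, seed = seed,
                   background_ko_rate = background_ko_rate)
    )
  })
}

#' Generate a synthetic gene-level dataset for reporter enrichment
#'
#' Null genes receive uniform(0, 1) p-values with random direction; members
#' of the planted enriched pathways receive p-values derived from normal
#' z-scores centred at `effect_mean_z`, with direction fixed to the planted
#' (pre-weaning, negative-score) group.
#'
#' @param n_genes Number of genes.
#' @param n_pathways Number of pathways.
#' @param k_range Integer range of pathway sizes.
#' @param n_enriched Number of planted enriched pathways (<= n_pathways).
#' @param effect_mean_z Mean gene-level z magnitude in planted pathways.
#' @param seed Integer seed.
#' @return A list with `gene_stats` (data frame gene, p, direction),
#'   `membership` (data frame pathway, gene) and `truth` (planted pathway
#'   ids and parameters).
#' @export
gen_reporter_dataset <- function(n_genes, n_pathways, k_range = c(5L, 50L),
                                 n_enriched = 0L, effect_mean_z = 1.0,
                                 seed = 1L) {
  stopifnot(n_enriched <= n_pathways)
  if (n_genes == 0) {
    return(list(
      gene_stats = data.frame(gene = character(), p = numeric(),
                              direction = numeric()),
      membership = data.frame(pathway = character(), gene = character()),
      truth = list(enriched = character(), effect_mean_z = effect_mean_z,
                   seed = seed)))
  }
  with_seed(seed, {
    genes <- sprintf("gene%06d", seq_len(n_genes))
    p <- stats::runif(n_genes)
    direction <- sample(c(-1, 1), n_genes, replace = TRUE)
    pathways <- sprintf("pw%04d", seq_len(n_pathways))
    membership <- do.call(rbind, lapply(pathways, function(pw) {
      k <- sample_range(k_range[1], k_range[2])
      data.frame(pathway = pw, gene = sample(genes, k),
                 stringsAsFactors = FALSE)
    }))
    enriched <- if (n_enriched > 0) sample(pathways, n_enriched) else character()
    for (pw in enriched) {
      members <- membership$gene[membership$pathway == pw]
      idx <- match(members, genes)
      z <- stats::rnorm(length(idx), mean = effect_mean_z, sd = 1)
      p[idx] <- pmin(pmax(1 - stats::pnorm(z), 1e-12), 1 - 1e-12)
      direction[idx] <- -1   # planted pre-weaning direction
    }
    list(
      gene_stats = data.frame(gene = genes, p = p, direction = direction,
                              stringsAsFactors = FALSE),
      membership = membership,
      truth = list(enriched = sort(enriched), effect_mean_z = effect_mean_z,
                   seed = seed)
    )
  })
}

#' Generate a two-group amino-acid concentration table
#'
#' Baseline analyte medians are log-uniform between 50 and 5000 nmol/g;
#' group A values are multiplied by the planted fold change for affected
#' analytes; all values carry multiplicative log-normal noise.  Values below
#' the LOD are marked as censored (`NA`).
#'
#' @param n_A,n_B Group sizes.
#' @param n_analytes Number of analytes.
#' @param planted_effects Named numeric vector analyte -> fold change (> 0)
#'   applied to group A; analytes may be named `"aa01"` ... or custom names
#'   occupying the first positions.
#' @param noise_sigma Log-scale noise standard deviation.
#' @param lod Limit of detection, nmol/g.
#' @param seed Integer seed.
#' @return A list with `table` (an [aa_table]) and `truth`.
#' @export
gen_aa_table <- function(n_A = 7L, n_B = 8L, n_analytes = 15L,
                         planted_effects = c(), noise_sigma = 0.3,
                         lod = 1, seed = 1L) {
  if (length(planted_effects) && any(planted_effects <= 0)) {
    stop("fold changes must be > 0", call. = FALSE)
  }
  with_seed(seed, {
    analytes <- sprintf("aa%02d", seq_len(n_analytes))
    if (length(planted_effects)) {
      if (is.null(names(planted_effects))) {
        names(planted_effects) <- analytes[seq_along(planted_effects)]
      } else {
        custom <- setdiff(names(planted_effects), analytes)
        analytes[seq_along(custom)] <- custom
      }
      stopifnot(all(names(planted_effects) %in% analytes))
    }
    base <- exp(stats::runif(n_analytes, log(50), log(5000)))
    names(base) <- analytes
    fold <- stats::setNames(rep(1, n_analytes), analytes)
    fold[names(planted_effects)] <- planted_effects
    n <- n_A + n_B
    vals <- matrix(NA_real_, n, n_analytes,
                   dimnames = list(c(sprintf("A%02d", seq_len(n_A)),
                                     sprintf("B%02d", seq_len(n_B))),
                                   analytes))
    groups <- c(rep("A", n_A), rep("B", n_B))
    for (j in seq_len(n_analytes)) {
      mu <- ifelse(groups == "A", base[j] * fold[j], base[j])
      vals[, j] <- mu * exp(stats::rnorm(n, 0, noise_sigma))
    }
    vals[vals < lod] <- NA
    list(table = aa_table(vals, groups, lod = lod),
         truth = list(planted_effects = planted_effects, base = base,
                      noise_sigma = noise_sigma, seed = seed))
  })
}
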