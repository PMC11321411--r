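#' Is a reaction step satisfied by a KO set?
#'
#' A step is satisfied when at least one of its alternatives has all of its
#' required KOs present.  Optional KOs never affect satisfaction.
#'
#' @param step A step (list of alternatives, each
#'   `list(required = <chr>, optional = <chr>)`).
#' @param kos Character vector of KO ids present in the genome.
#' @return `TRUE` or `FALSE`.
#' @export
step_satisfied <- function(step, kos) {
  if (!length(step)) stop("step must have >= 1 alternative", call. = FALSE)
  for (alt in step) {
    if (all(alt$required %in% kos)) return(TRUE)
  }
  FALSE
}

#' Score module completeness for one genome
#'
#' Computes the coverage of a module in a genome and calls presence at the
#' configured threshold (inclusive: coverage exactly at the threshold counts
#' as present, i.e. "at least 75%").  Two coverage modes are supported:
#' `"steps"` (default) counts satisfied reaction steps over total
#' non-optional steps; `"genes"` counts matched required KOs over the union
#' of required KOs.  Optional components are excluded from denominators in
#' both modes.
#'
#' @param module A [module_definition].
#' @param genome A [genome_annotation].
#' @param config An [analysis_config].
#' @return A one-row data frame (class `completeness_call`) with columns
#'   `genome_id`, `module_id`, `coverage`, `present`, `satisfied_steps`,
#'   `total_steps`, and the matched KOs as an attribute `matched_kos`.
#' @examples
#' m <- parse_kegg_definition("K00001 (K00002,K00003)", "M1", "toy")
#' g <- genome_annotation("g1", c(K00001 = 1L, K00003 = 2L))
#' module_coverage(m, g, analysis_config())
#' @export
module_coverage <- function(module, genome, config = analysis_config()) {
  kos <- ko_set(genome)
  total <- length(module$steps)
  if (total == 0) {
    stop(sprintf("module %s has no non-optional steps", module$module_id),
         call. = FALSE)
  }
  sat <- vapply(module$steps, step_satisfied, logical(1), kos = kos)
  req_union <- unique(unlist(lapply(module$steps, function(step)
    lapply(step, `[[`, "required"))))
  matched <- intersect(req_union, kos)
  coverage <- switch(config$coverage_mode,
    steps = sum(sat) / total,
    genes = if (length(req_union)) length(matched) / length(req_union) else 0
  )
  out <- data.frame(
    genome_id = genome$genome_id,
    module_id = module$module_id,
    coverage = coverage,
    present = coverage >= config$presence_threshold,
    satisfied_steps = sum(sat),
    total_steps = total,
    stringsAsFactors = FALSE
  )
  attr(out, "matched_kos") <- matched
  class(out) <- c("completeness_call", "data.frame")
  out
}

#' Profile module completeness across a consortium
#'
#' Evaluates every (genome, module) pair and returns the dense long-format
#' table of completeness calls; the consortium-level module set is the set of
#' modules present in at least one member.
#'
#' @param consortium A [consortium_spec].
#' @param modules List of [module_definition] objects.
#' @param config An [analysis_config].
#' @return A data frame with one row per (genome, module) and columns
#'   `genome_id`, `module_id`, `coverage`, `present`, `satisfied_steps`,
#'   `total_steps`; the consortium name is kept in attribute `consortium`.
#' @export
profile_consortium_modules <- function(consortium, modules,
                                       config = analysis_config()) {
  if (!length(modules)) stop("module list must be nonempty", call. = FALSE)
  rows <- vector("list", length(consortium$members) * length(modules))
  i <- 0
  for (g in consortium$members) {
    for (m in modules) {
      i <- i + 1
      call <- module_coverage(m, g, config)
      attr(call, "matched_kos") <- NULL
      rows[[i]] <- call
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  attr(out, "consortium") <- consortium$name
  out
}

#' Module presence matrix from a completeness profile
#'
#' @param profile Output of [profile_consortium_modules].
#' @return Logical matrix, genomes x modules.
#' @export
presence_matrix <- function(profile) {
  genomes <- unique(profile$genome_id)
  mods <- unique(profile$module_id)
  mat <- matrix(FALSE, length(genomes), length(mods),
                dimnames = list(genomes, mods))
  mat[cbind(match(profile$genome_id, genomes),
            match(profile$module_id, mods))] <- profile$present
  mat
}

#' Modules present in at least one consortium member
#' @param profile Output of [profile_consortium_modules].
#' @return Character vector of module ids.
#' @export
consortium_module_set <- function(profile) {
  sort(unique(profile$module_id[profile$present]))
}
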