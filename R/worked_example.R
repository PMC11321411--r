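#' Infant-microbiome-enriched KO counts across the PedsCom isolates
#'
#' The package ships a small worked-example dataset: per-isolate gene copy
#' counts, across the nine isolates of the pre-weaning PedsCom consortium,
#' for KEGG Orthologs that are unique to PedsCom (relative to the ASF and
#' Oligo-MM12 adult consortia) and whose functions are over-represented in
#' human infant fecal metagenomes.  The printed `gene_count` and
#' `prevalence` columns allow the prevalence-table stage to be checked
#' end-to-end against known aggregates.
#'
#' @return Data frame with columns `ko`, `pathway`, `description`, nine
#'   isolate count columns, `gene_count`, `prevalence` (e.g. `"6/9"`),
#'   `absent_in_ASF`, `absent_in_OMM12`.
#' @examples
#' head(infant_enriched_ko_table())
#' @export
infant_enriched_ko_table <- function() {
  path <- system.file("extdata", "pedscom_infant_enriched_kos.tsv",
                      package = "gnotofun", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fill = TRUE)
}

#' Isolate column names of the worked-example table
#' @return Character vector of the nine isolate columns.
#' @export
infant_enriched_isolates <- function() {
  c("Anaerostipes_sp", "C_intestinale", "L_johnsonii", "L_murinus",
    "E_faecalis", "M_sciuri", "S_xylosus", "K_cowanii", "P_distasonis")
}

#' Build a consortium from a KO-by-isolate count table
#'
#' Turns a table of per-isolate KO copy counts (KOs in rows, isolates in
#' columns) into a [consortium_spec], so that printed count tables can be
#' fed straight into the set-algebra and prevalence machinery.
#'
#' @param counts Data frame or matrix with a `ko` column/rownames and one
#'   integer column per isolate.
#' @param isolate_cols Names of the isolate columns (defaults to all
#'   numeric columns).
#' @param name Consortium name.
#' @return A [consortium_spec].
#' @export
consortium_from_count_table <- function(counts, isolate_cols = NULL,
                                        name = "consortium") {
  counts <- as.data.frame(counts)
  kos <- if ("ko" %in% names(counts)) counts$ko else rownames(counts)
  if (is.null(isolate_cols)) {
    isolate_cols <- names(counts)[vapply(counts, is.numeric, logical(1))]
  }
  members <- lapply(isolate_cols, function(col) {
    cc <- counts[[col]]
    keep <- !is.na(cc) & cc > 0
    genome_annotation(col, stats::setNames(as.integer(cc[keep]), kos[keep]))
  })
  consortium_spec(name, members)
}
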