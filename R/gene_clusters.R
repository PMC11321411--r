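#' Define a gene-cluster detection rule
#'
#' A rule names the gene symbols whose KOs must co-occur in a genome for a
#' functional gene cluster to be called, with optional members and
#' taxon-conditional requirements (symbols required only for taxa outside a
#' stated clade).  Co-occurrence within the genome is evaluated, not
#' physical adjacency: the inputs are KO tables without coordinates.
#'
#' @param name Rule name.
#' @param required Character vector of required gene symbols.
#' @param optional Character vector of optional symbols (reported when
#'   matched, never required).
#' @param conditional_optional Named list mapping a symbol to a taxon
#'   predicate `function(taxonomy) -> logical`; when the predicate is TRUE
#'   for a genome the symbol is optional for it, otherwise required.
#' @param symbol_to_ko Named list mapping each gene symbol to its KO id(s).
#'   Shipped defaults are configuration to be reviewed against the KO
#'   catalogue in use, not ground truth.
#' @return An object of class `cluster_rule`.
#' @export
cluster_rule <- function(name, required, optional = character(),
                         conditional_optional = list(),
                         symbol_to_ko = list()) {
  if (length(intersect(required, optional))) {
    stop("required and optional symbol sets must be disjoint", call. = FALSE)
  }
  syms <- unique(c(required, optional, names(conditional_optional)))
  missing <- setdiff(syms, names(symbol_to_ko))
  if (length(missing)) {
    stop(sprintf("rule '%s': no KO mapping for symbol(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, required = required, optional = optional,
                 conditional_optional = conditional_optional,
                 symbol_to_ko = symbol_to_ko),
            class = "cluster_rule")
}

# Default symbol -> KO map for sialic-acid catabolism genes; editable
# configuration (KO ids should be checked against the catalogue release in
# use before production runs).
nan_symbol_map <- function() {
  list(nanA = "K01639",   # N-acetylneuraminate lyase
       nanE = "K01788",   # N-acetylmannosamine-6-phosphate 2-epimerase
       nanK = "K00885",   # N-acetylmannosamine kinase
       nanH = "K01186")   # sialidase
}

#' Built-in sialic-acid catabolism cluster rules
#'
#' `nan_cluster_rule()` encodes the canonical nan cluster: nanA (lyase) and
#' nanE (epimerase) required, nanK (kinase) required except in Bacteroidota,
#' which catabolise sialic acid without it.  A permissive variant
#' (`permissive = TRUE`) requires only nanE.  `nanH_rule()` is the separate
#' single-gene sialidase rule.
#'
#' @param permissive Use the permissive (nanE-only) variant?
#' @param symbol_to_ko Override the default symbol -> KO map.
#' @return A [cluster_rule].
#' @export
nan_cluster_rule <- function(permissive = FALSE,
                             symbol_to_ko = nan_symbol_map()) {
  bacteroidota <- function(taxonomy) {
    identical(unname(taxonomy["phylum"]), "Bacteroidota")
  }
  if (permissive) {
    cluster_rule("nan_cluster_permissive", required = "nanE",
                 optional = c("nanA", "nanK"),
                 symbol_to_ko = symbol_to_ko)
  } else {
    cluster_rule("nan_cluster", required = c("nanA", "nanE"),
                 conditional_optional = list(nanK = bacteroidota),
                 symbol_to_ko = symbol_to_ko)
  }
}

#' @rdname nan_cluster_rule
#' @export
nanH_rule <- function(symbol_to_ko = nan_symbol_map()) {
  cluster_rule("nanH_sialidase", required = "nanH",
               symbol_to_ko = symbol_to_ko)
}

#' Detect a gene cluster in a genome
#'
#' Resolves each rule symbol through the symbol -> KO map, applies any
#' taxon-conditional relaxations for this genome's taxonomy, and classifies
#' the genome as `complete` (all effectively-required symbols matched),
#' `partial` (some matched) or `absent` (none matched).
#'
#' @param genome A [genome_annotation].
#' @param rule A [cluster_rule].
#' @return A list of class `cluster_call` with `genome_id`, `rule`,
#'   `status`, `matched` (all matched symbols, optional ones included) and
#'   `missing_required`.
#' @examples
#' g <- genome_annotation("toy", c(K01639 = 1L, K01788 = 1L),
#'                        taxonomy = c(phylum = "Bacteroidota"))
#' detect_cluster(g, nan_cluster_rule())$status  # "complete"
#' @export
detect_cluster <- function(genome, rule) {
  kos <- ko_set(genome)
  symbol_present <- function(sym) {
    any(rule$symbol_to_ko[[sym]] %in% kos)
  }
  relaxed <- names(Filter(function(pred) isTRUE(pred(genome$taxonomy)),
                          rule$conditional_optional))
  effective_required <- unique(c(
    rule$required,
    setdiff(names(rule$conditional_optional), relaxed)))
  all_syms <- unique(c(effective_required, rule$optional, relaxed))
  matched <- all_syms[vapply(all_syms, symbol_present, logical(1))]
  missing_req <- setdiff(effective_required, matched)
  status <- if (!length(missing_req)) "complete"
            else if (length(matched)) "partial"
            else "absent"
  structure(list(genome_id = genome$genome_id, rule = rule$name,
                 status = status, matched = matched,
                 missing_required = missing_req),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf("<cluster_call> %s / %s: %s (matched: %s)\n", x$genome_id,
              x$rule, x$status,
              if (length(x$matched)) paste(x$matched, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Apply cluster rules across a consortium
#'
#' @param consortium A [consortium_spec].
#' @param rules List of [cluster_rule] objects.
#' @return Data frame with columns `genome_id`, `rule`, `status`,
#'   `matched`, `missing_required` (symbol lists collapsed with ';').
#' @export
detect_clusters <- function(consortium, rules) {
  rows <- list()
  for (g in consortium$members) {
    for (r in rules) {
      call <- detect_cluster(g, r)
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = call$genome_id, rule = call$rule, status = call$status,
        matched = paste(call$matched, collapse = ";"),
        missing_required = paste(call$missing_required, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
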