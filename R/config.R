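#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object so
#' that result files can carry a complete provenance record.
#'
#' @param presence_threshold Module completeness fraction at or above which a
#'   module is called present in a genome (inclusive). Default 0.75.
#' @param coverage_mode How module completeness is computed: `"steps"`
#'   (satisfied reaction steps / total non-optional steps, the default) or
#'   `"genes"` (matched required KOs / union of required KOs).
#' @param prevalence_min_isolates Minimum number of carrier isolates for a KO
#'   to enter a prevalence table. Default 3.
#' @param high_prevalence_fraction Modules found in strictly more than
#'   `floor(high_prevalence_fraction * N)` of the N pooled isolates are
#'   dropped before differential and dissimilarity analyses (they carry
#'   little contrast). Default 0.80, i.e. a cutoff of 23 isolates when
#'   N = 29.
#' @param reporter_threshold Magnitude of the background-adjusted reporter
#'   score beyond which a pathway is called enriched; the call is strict
#'   (`z_adj < -reporter_threshold` under the sign convention where the
#'   group of interest is negative). Default 1.6.
#' @param alpha Significance level for q-values and test decisions.
#'   Default 0.05.
#' @param lod Limit of detection for amino-acid concentrations, nmol/g.
#'   Default 1.
#' @param lod_policy Contribution of below-LOD values to sums: `"zero"`
#'   (default) or `"half"` (LOD/2).
#' @param reporter_n_samples Monte-Carlo background sample count for the
#'   reporter score. Default 10000.
#' @param rng_seed Optional integer seed recorded in provenance and used by
#'   stages that draw random numbers.
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$presence_threshold
#' @export
analysis_config <- function(presence_threshold = 0.75,
                            coverage_mode = c("steps", "genes"),
                            prevalence_min_isolates = 3L,
                            high_prevalence_fraction = 0.80,
                            reporter_threshold = 1.6,
                            alpha = 0.05,
                            lod = 1,
                            lod_policy = c("zero", "half"),
                            reporter_n_samples = 10000L,
                            rng_seed = NULL) {
  coverage_mode <- match.arg(coverage_mode)
  lod_policy <- match.arg(lod_policy)
  if (!is.numeric(presence_threshold) || length(presence_threshold) != 1 ||
      is.na(presence_threshold) ||
      presence_threshold <= 0 || presence_threshold > 1) {
    stop("presence_threshold must be a single value in (0, 1]", call. = FALSE)
  }
  if (high_prevalence_fraction <= 0 || high_prevalence_fraction > 1) {
    stop("high_prevalence_fraction must be in (0, 1]", call. = FALSE)
  }
  if (reporter_threshold <= 0) {
    stop("reporter_threshold must be positive", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (prevalence_min_isolates < 1) {
    stop("prevalence_min_isolates must be >= 1", call. = FALSE)
  }
  if (reporter_n_samples < 100) {
    stop("reporter_n_samples must be >= 100", call. = FALSE)
  }
  structure(
    list(
      presence_threshold = presence_threshold,
      coverage_mode = coverage_mode,
      prevalence_min_isolates = as.integer(prevalence_min_isolates),
      high_prevalence_fraction = high_prevalence_fraction,
      reporter_threshold = reporter_threshold,
      alpha = alpha,
      lod = lod,
      lod_policy = lod_policy,
      reporter_n_samples = as.integer(reporter_n_samples),
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-25s %s\n", nm,
                if (is.null(val)) "<unset>" else format(val)))
  }
  invisible(x)
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream; all randomised operations in the package route through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One-line key=value provenance block written at the top of output TSVs.
provenance_header <- function(config, extra = list()) {
  fields <- c(
    list(tool = "gnotofun", version = as.character(utils::packageVersion("gnotofun"))),
    unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    extra
  )
  paste0("# ", names(fields), "=", vapply(fields, function(v)
    paste(format(v), collapse = ","), character(1)))
}

# TSV writer used by every stage: provenance comments then a header row.
write_stage_tsv <- function(df, path, config = NULL, extra = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(provenance_header(config, extra), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
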