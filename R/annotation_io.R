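#' Construct a genome annotation object
#'
#' A `genome_annotation` holds one genome's KEGG Ortholog (KO) copy-number
#' profile together with its taxonomy labels; it is the atomic input of all
#' downstream comparisons.
#'
#' @param genome_id Non-empty genome identifier.
#' @param ko_counts Named integer vector, KO id -> copy count (all >= 1).
#' @param taxonomy Named character vector of rank -> name (e.g. `phylum`,
#'   `family`).
#' @param n_unassigned Number of annotated genes with no KO assignment.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, ko_counts = integer(),
                              taxonomy = character(), n_unassigned = 0L) {
  if (!is.character(genome_id) || length(genome_id) != 1 || !nzchar(genome_id)) {
    stop("genome_id must be a non-empty string", call. = FALSE)
  }
  ko_counts <- as.integer(round(ko_counts)) |> stats::setNames(names(ko_counts))
  if (length(ko_counts)) {
    if (is.null(names(ko_counts)) || any(!nzchar(names(ko_counts)))) {
      stop("ko_counts must be a named vector", call. = FALSE)
    }
    if (any(ko_counts < 1L)) stop("all KO counts must be >= 1", call. = FALSE)
    if (anyDuplicated(names(ko_counts))) {
      stop("duplicate KO ids in ko_counts", call. = FALSE)
    }
    bad <- !grepl("^K[0-9]{5}$", names(ko_counts))
    if (any(bad)) {
      # EC-labelled / provisional tokens are admitted and matched verbatim
      warning(sprintf("%d KO id(s) do not match K#####: %s", sum(bad),
                      paste(utils::head(names(ko_counts)[bad], 3), collapse = ", ")),
              call. = FALSE)
    }
  }
  structure(
    list(genome_id = genome_id,
         taxonomy = taxonomy,
         ko_counts = ko_counts,
         n_unassigned = as.integer(n_unassigned)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d distinct KOs (%d genes), %d unassigned\n",
              x$genome_id, length(x$ko_counts), sum(x$ko_counts), x$n_unassigned))
  if (length(x$taxonomy)) {
    cat("  taxonomy:", paste(names(x$taxonomy), x$taxonomy, sep = "=",
                             collapse = "; "), "\n")
  }
  invisible(x)
}

#' Distinct KO ids of a genome
#' @param genome A `genome_annotation`.
#' @return Character vector of KO ids.
#' @export
ko_set <- function(genome) names(genome$ko_counts)

#' Read a gene-to-KO annotation table
#'
#' Reads the two-column tab-separated output of an automatic KO annotation
#' run (gene id, KO id or empty) and aggregates it into a per-genome KO
#' copy-count profile.  Duplicate KO assignments across genes become copy
#' counts; genes without a KO are tallied as unassigned.
#'
#' @param path Path to the TSV file (no header; blank lines, `#` comments and
#'   CRLF endings are tolerated).
#' @param genome_id Identifier for the genome.
#' @param taxonomy Optional named character vector of rank -> name.
#' @return A [genome_annotation].
#' @examples
#' f <- tempfile()
#' writeLines(c("g1\tK00001", "g2\tK00001", "g3\tK00002", "g4\t"), f)
#' read_ko_annotation(f, "toy")
#' @export
read_ko_annotation <- function(path, genome_id, taxonomy = character()) {
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  genes <- character(0); kos <- character(0)
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2 || !nzchar(trimws(parts[1]))) {
      stop(sprintf("malformed annotation line %d in %s", i, path), call. = FALSE)
    }
    genes <- c(genes, trimws(parts[1]))
    kos <- c(kos, if (length(parts) == 2) trimws(parts[2]) else "")
  }
  if (anyDuplicated(genes)) {
    warning(sprintf("duplicate gene ids in %s; counted once", path), call. = FALSE)
    first <- !duplicated(genes)
    genes <- genes[first]; kos <- kos[first]
  }
  assigned <- kos[nzchar(kos)]
  counts <- if (length(assigned)) {
    tab <- table(assigned)
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  genome_annotation(genome_id, counts, taxonomy,
                    n_unassigned = sum(!nzchar(kos)))
}

#' Write a genome annotation as a gene-to-KO table
#'
#' Inverse of [read_ko_annotation] up to gene naming: each KO copy becomes one
#' row with a synthetic gene id, and unassigned genes become rows with an
#' empty KO column.
#'
#' @param genome A [genome_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ko_annotation <- function(genome, path) {
  kos <- rep(names(genome$ko_counts), genome$ko_counts)
  kos <- c(kos, rep("", genome$n_unassigned))
  ids <- sprintf("%s_g%05d", genome$genome_id, seq_along(kos))
  writeLines(paste(ids, kos, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Construct a module definition
#'
#' A module is an ordered list of reaction steps; each step is a set of
#' alternatives; each alternative is a complex: a set of required KOs that
#' must all be present, plus optional KOs that never affect satisfaction or
#' denominators.
#'
#' @param module_id Module identifier (unique within a database).
#' @param name Human-readable name.
#' @param steps List of steps; each step a list of alternatives; each
#'   alternative a `list(required = <chr>, optional = <chr>)`.
#' @param category Optional functional category label.
#' @param optional_kos Module-level optional KOs (components marked optional
#'   outside any step).
#' @return An object of class `module_definition`.
#' @export
module_definition <- function(module_id, name, steps, category = "",
                              optional_kos = character()) {
  if (!length(steps)) stop("module must have >= 1 step", call. = FALSE)
  steps <- lapply(steps, function(step) {
    step <- Filter(function(alt) length(alt$required) > 0, step)
    if (!length(step)) {
      stop(sprintf("module %s: step with no valid alternative", module_id),
           call. = FALSE)
    }
    lapply(step, function(alt) {
      list(required = unique(as.character(alt$required)),
           optional = unique(as.character(alt$optional %||% character())))
    })
  })
  structure(
    list(module_id = module_id, name = name, category = category,
         steps = steps, optional_kos = unique(optional_kos)),
    class = "module_definition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.module_definition <- function(x, ...) {
  cat(sprintf("<module_definition> %s (%s): %d step(s)\n",
              x$module_id, x$name, length(x$steps)))
  invisible(x)
}

#' All KO ids used by a module
#' @param module A [module_definition].
#' @param include_optional Include optional components?
#' @return Character vector of KO ids.
#' @export
module_kos <- function(module, include_optional = FALSE) {
  req <- unlist(lapply(module$steps, function(step)
    lapply(step, `[[`, "required")))
  opt <- c(unlist(lapply(module$steps, function(step)
    lapply(step, `[[`, "optional"))), module$optional_kos)
  unique(c(req, if (include_optional) opt))
}

#' Read a GMM-style module flat file
#'
#' Parses the gut-metabolic-module flat-file dialect: blocks beginning with a
#' header line `ID<TAB>Name[<TAB>Category]`, followed by one line per
#' reaction step, terminated by `///`.  Within a step line, comma-separated
#' tokens are OR-alternatives and `+`-joined KOs within a token form a
#' required complex.  Blank lines and `#` comments are ignored.
#'
#' @param path Path to the flat file.
#' @return List of [module_definition] objects in file order.
#' @export
read_gmm_definitions <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  modules <- list()
  seen <- character(0)
  i <- 1
  while (i <= length(lines)) {
    header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(header) < 2) {
      stop(sprintf("malformed module header at line '%s'", lines[i]),
           call. = FALSE)
    }
    mid <- trimws(header[1]); mname <- trimws(header[2])
    mcat <- if (length(header) >= 3) trimws(header[3]) else ""
    j <- i + 1
    steps <- list()
    terminated <- FALSE
    while (j <= length(lines)) {
      if (lines[j] == "///") { terminated <- TRUE; break }
      steps[[length(steps) + 1]] <- parse_gmm_step(lines[j], mid)
      j <- j + 1
    }
    if (!terminated) {
      stop(sprintf("module block %s missing '///' terminator", mid),
           call. = FALSE)
    }
    if (mid %in% seen) {
      warning(sprintf("duplicate module id %s; keeping first", mid),
              call. = FALSE)
    } else {
      seen <- c(seen, mid)
      modules[[length(modules) + 1]] <-
        module_definition(mid, mname, steps, category = mcat)
    }
    i <- j + 1
  }
  modules
}

parse_gmm_step <- function(line, module_id) {
  tokens <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  alts <- lapply(tokens, function(tok) {
    kos <- trimws(strsplit(tok, "+", fixed = TRUE)[[1]])
    kos <- kos[nzchar(kos)]
    list(required = kos, optional = character())
  })
  alts <- Filter(function(a) length(a$required) > 0, alts)
  if (!length(alts)) {
    stop(sprintf("module %s: step line with no valid KO token", module_id),
         call. = FALSE)
  }
  alts
}

#' Write module definitions as a GMM-style flat file
#'
#' Inverse of [read_gmm_definitions] for modules without optional components
#' (the flat-file dialect cannot express them).
#'
#' @param modules List of [module_definition] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmm_definitions <- function(modules, path) {
  out <- character(0)
  for (m in modules) {
    header <- if (nzchar(m$category)) {
      paste(m$module_id, m$name, m$category, sep = "\t")
    } else paste(m$module_id, m$name, sep = "\t")
    steplines <- vapply(m$steps, function(step) {
      paste(vapply(step, function(alt)
        paste(alt$required, collapse = "+"), character(1)), collapse = ",")
    }, character(1))
    out <- c(out, header, steplines, "///")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Parse a KEGG-style boolean module definition
#'
#' Parses the DEFINITION grammar used for KEGG modules: space separates
#' serial reaction steps, comma is OR (inside parentheses), `+` joins members
#' of a required complex, a leading `-` marks an optional component, and
#' parentheses group (nesting supported).  Optional components are recorded
#' but excluded from coverage denominators.
#'
#' @param defstring The definition string.
#' @param module_id Module identifier.
#' @param name Module name.
#' @param category Optional category label.
#' @return A [module_definition].
#' @examples
#' parse_kegg_definition("(K00001,K00002) K00003", "M0001", "toy")
#' @export
parse_kegg_definition <- function(defstring, module_id, name, category = "") {
  check_parens(defstring)
  tokens <- split_top_level(defstring, " ")
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty module definition", call. = FALSE)
  steps <- list()
  module_optional <- character(0)
  for (tok in tokens) {
    if (startsWith(tok, "-")) {
      # a wholly optional component: record, do not count as a step
      opt_alts <- parse_or_expr(substring(tok, 2))
      opt_kos <- unique(unlist(lapply(opt_alts, function(a)
        c(a$required, a$optional))))
      if (length(steps)) {
        k <- length(steps)
        steps[[k]] <- lapply(steps[[k]], function(alt) {
          alt$optional <- unique(c(alt$optional, opt_kos)); alt
        })
      } else {
        module_optional <- c(module_optional, opt_kos)
      }
    } else {
      steps[[length(steps) + 1]] <- parse_or_expr(tok)
    }
  }
  if (!length(steps)) {
    stop(sprintf("module %s: definition has only optional components",
                 module_id), call. = FALSE)
  }
  module_definition(module_id, name, steps, category = category,
                    optional_kos = module_optional)
}

check_parens <- function(s) {
  depth <- 0
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth < 0) {
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      }
    }
  }
  if (depth > 0) {
    stop(sprintf("unclosed '(' (%d unmatched)", depth), call. = FALSE)
  }
  invisible(TRUE)
}

# Split on a separator at parenthesis depth 0 only.
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0; parts <- character(0); cur <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (ch == sep && depth == 0) {
      parts <- c(parts, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
  }
  c(parts, paste(cur, collapse = ""))
}

# OR over comma at top level -> union of alternatives.
parse_or_expr <- function(s) {
  s <- trimws(s)
  parts <- split_top_level(s, ",")
  alts <- list()
  for (p in parts) {
    alts <- c(alts, parse_and_expr(p))
  }
  alts
}

# AND over '+' and embedded spaces (serial reactions folded into the complex
# when they occur inside a grouped alternative).  Returns a list of
# alternatives (the cartesian product when factors are themselves OR groups).
parse_and_expr <- function(s) {
  s <- trimws(s)
  factors <- unlist(lapply(split_top_level(s, "+"),
                           function(p) split_top_level(p, " ")))
  factors <- trimws(factors)
  factors <- factors[nzchar(factors)]
  alts <- list(list(required = character(), optional = character()))
  for (f in factors) {
    optional_factor <- startsWith(f, "-")
    if (optional_factor) f <- substring(f, 2)
    inner <- if (startsWith(f, "(")) strip_outer_parens(f) else f
    sub_alts <- if (!identical(inner, f)) {
      parse_or_expr(inner)
    } else {
      list(list(required = f, optional = character()))
    }
    new_alts <- list()
    for (a in alts) {
      for (b in sub_alts) {
        if (optional_factor) {
          new_alts[[length(new_alts) + 1]] <- list(
            required = a$required,
            optional = unique(c(a$optional, b$required, b$optional)))
        } else {
          new_alts[[length(new_alts) + 1]] <- list(
            required = unique(c(a$required, b$required)),
            optional = unique(c(a$optional, b$optional)))
        }
      }
    }
    alts <- new_alts
  }
  alts
}

strip_outer_parens <- function(s) {
  # only strip when the opening paren matches the final character
  chars <- strsplit(s, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth == 0 && i < length(chars)) return(s)  # e.g. "(a)b(c)"
    }
  }
  substring(s, 2, nchar(s) - 1)
}

#' Read a KO functional hierarchy table
#'
#' Reads a TSV with header and at least four columns (KO id, pathway,
#' category, subcategory) mapping each KO to one or more pathways.  Lookups
#' of unknown KOs return an explicit "unannotated" bucket, never an error.
#'
#' @param path Path to the TSV.
#' @return A data frame of class `functional_hierarchy` with columns
#'   `ko`, `pathway`, `category`, `subcategory`.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (ncol(df) < 4) {
    stop(sprintf("hierarchy file %s must have >= 4 columns (ko, pathway, category, subcategory)",
                 path), call. = FALSE)
  }
  df <- df[, 1:4]
  names(df) <- c("ko", "pathway", "category", "subcategory")
  df$ko <- trimws(df$ko)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("functional_hierarchy", "data.frame")
  df
}

#' Build a hierarchy object from a data frame
#' @param df Data frame with columns ko, pathway, category, subcategory.
#' @return A `functional_hierarchy`.
#' @export
functional_hierarchy <- function(df) {
  stopifnot(all(c("ko", "pathway", "category", "subcategory") %in% names(df)))
  df <- unique(as.data.frame(df)[, c("ko", "pathway", "category", "subcategory")])
  rownames(df) <- NULL
  class(df) <- c("functional_hierarchy", "data.frame")
  df
}

#' Look up the pathway entries of a KO
#'
#' @param hierarchy A `functional_hierarchy`.
#' @param ko KO id.
#' @return Data frame of matching entries; unknown KOs yield one row with
#'   pathway/category/subcategory set to `"unannotated"`.
#' @export
hierarchy_lookup <- function(hierarchy, ko) {
  hits <- hierarchy[hierarchy$ko == ko, , drop = FALSE]
  if (!nrow(hits)) {
    hits <- data.frame(ko = ko, pathway = "unannotated",
                       category = "unannotated", subcategory = "unannotated",
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  as.data.frame(hits)
}

#' Construct a consortium
#'
#' @param name Consortium name.
#' @param members List of [genome_annotation] objects with unique ids.
#' @return An object of class `consortium_spec`.
#' @export
consortium_spec <- function(name, members) {
  if (!length(members)) stop("consortium must have >= 1 member", call. = FALSE)
  ids <- vapply(members, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop("member genome ids must be unique within a consortium", call. = FALSE)
  }
  structure(list(name = name, members = members), class = "consortium_spec")
}

#' @export
print.consortium_spec <- function(x, ...) {
  cat(sprintf("<consortium_spec> %s: %d member(s)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a consortium from a metadata table
#'
#' The metadata TSV has columns `genome_id`, `consortium`, `phylum`,
#' `family`, `annotation_path`; annotation paths are resolved relative to the
#' metadata file's directory.
#'
#' @param path Path to the metadata TSV.
#' @param name Consortium to load (a value of the `consortium` column); if
#'   `NULL` and the file holds a single consortium, that one is used.
#' @return A [consortium_spec].
#' @export
read_consortium <- function(path, name = NULL) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genome_id", "consortium", "phylum", "family", "annotation_path")
  if (!all(need %in% names(meta))) {
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(name)) {
    name <- unique(meta$consortium)
    if (length(name) != 1) {
      stop("metadata holds multiple consortia; pass `name`", call. = FALSE)
    }
  }
  rows <- meta[meta$consortium == name, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("no members for consortium '%s'", name),
                        call. = FALSE)
  base <- dirname(path)
  members <- lapply(seq_len(nrow(rows)), function(i) {
    p <- rows$annotation_path[i]
    if (!file.exists(p)) p <- file.path(base, rows$annotation_path[i])
    read_ko_annotation(p, rows$genome_id[i],
                       taxonomy = c(phylum = rows$phylum[i],
                                    family = rows$family[i]))
  })
  consortium_spec(name, members)
}

# Line reader tolerant of CRLF endings and missing trailing newline.
read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}
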