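#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column order for GWAS summary-statistic tables.
gwas_columns <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

valid_bases <- c("A", "C", "G", "T")

#' Validate a GWAS summary-statistics table
#'
#' Checks a data frame of per-variant associations against the schema used
#' throughout the package and drops rows that violate it, keeping a tally of
#' the reasons. A valid row has a single-base effect and other allele
#' (A/C/G/T, distinct), a positive standard error, a p-value in (0, 1], a
#' sample size greater than 2, and an effect-allele frequency strictly
#' between 0 and 1 when present (`NA` is allowed and marks the frequency as
#' missing).
#'
#' @param x A data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param quiet If `TRUE`, suppress the message reporting dropped rows.
#' @return A tibble in canonical column order containing only valid rows,
#'   with alleles upper-cased. The number of rows dropped per reason is
#'   attached as the `"dropped"` attribute (a named integer vector) and can
#'   be read with [dropped_tally()].
#' @export
as_gwas_tbl <- function(x, quiet = FALSE) {
  missing_cols <- setdiff(gwas_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as_tibble(x)[gwas_columns]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  x$n <- as.numeric(x$n)

  bad <- list(
    bad_allele = !(x$effect_allele %in% valid_bases &
                     x$other_allele %in% valid_bases) |
      x$effect_allele == x$other_allele,
    bad_se   = !is.finite(x$se) | x$se <= 0,
    bad_pval = !is.finite(x$pval) | x$pval <= 0 | x$pval > 1,
    bad_n    = !is.finite(x$n) | x$n <= 2,
    bad_eaf  = !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1),
    bad_beta = !is.finite(x$beta),
    bad_pos  = is.na(x$pos) | x$pos < 1,
    bad_id   = is.na(x$snp_id) | x$snp_id == ""
  )
  drop_any <- Reduce(`|`, bad)
  tally <- vapply(bad, function(v) sum(v & !is.na(v)), integer(1))
  keep <- x[!drop_any, ]

  dup <- duplicated(keep$snp_id)
  if (any(dup)) {
    stop("duplicate snp_id: ",
         paste(unique(keep$snp_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (!quiet && sum(tally) > 0) {
    message("dropped ", sum(drop_any), " invalid row(s): ",
            paste(names(tally)[tally > 0], tally[tally > 0],
                  sep = "=", collapse = ", "))
  }
  attr(keep, "dropped") <- tally
  keep
}

#' Number of records dropped during validation or parsing
#'
#' @param x An object returned by [as_gwas_tbl()], [read_gwas()] or
#'   [read_edge_list()].
#' @return Named integer vector of drop counts by reason.
#' @export
dropped_tally <- function(x) {
  d <- attr(x, "dropped")
  if (is.null(d)) integer(0) else d
}

#' Read GWAS summary statistics from a TSV file
#'
#' Reads a tab-separated table with a header row and validates it with
#' [as_gwas_tbl()]. Non-canonical headers are supported through
#' `column_map`.
#'
#' @param path Path to a tab-separated file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the names used in the file, e.g.
#'   `c(effect_allele = "A1", other_allele = "A2", eaf = "freq")`.
#' @param quiet Passed on to [as_gwas_tbl()].
#' @return A validated tibble of summary statistics (see [as_gwas_tbl()]).
#' @export
read_gwas <- function(path, column_map = NULL, quiet = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c("NA", ""),
                           check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column_map refers to absent column: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(gwas_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_gwas_tbl(raw, quiet = quiet)
}

#' Write GWAS summary statistics to a TSV file
#'
#' Writes the canonical tab-separated representation. Numeric fields are
#' serialized with 15 significant digits so that a read/write round trip
#' reproduces them to well below 1e-9.
#'
#' @param stats A summary-statistics tibble (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(stats, path) {
  stats <- as_gwas_tbl(stats, quiet = TRUE)
  out <- stats
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  out$n <- formatC(out$n, format = "fg")
  utils::write.table(out[gwas_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a labelled LD correlation matrix
#'
#' Expects a tab-separated square matrix whose first row and first column
#' carry variant identifiers. The matrix must be symmetric (within 1e-8),
#' have a unit diagonal, and all entries in \[-1, 1\].
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with `snp_id` dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) {
    stop("LD matrix body is not square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column labels disagree", call. = FALSE)
  }
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(m) {
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("LD matrix has non-finite entries", call. = FALSE)
  if (any(abs(m) > 1 + 1e-12)) stop("|r| > 1 in LD matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("LD matrix asymmetric beyond 1e-8", call. = FALSE)
  }
  if (any(abs(diag(m) - 1) > 1e-12)) {
    stop("LD matrix diagonal is not 1", call. = FALSE)
  }
  m
}

#' Write a labelled LD matrix to TSV
#'
#' @param ld Square symmetric correlation matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  ld <- validate_ld_matrix(ld)
  df <- data.frame(snp_id = rownames(ld),
                   formatC(ld, digits = 15, format = "g"),
                   check.names = FALSE)
  names(df) <- c("snp_id", colnames(ld))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list into a graph
#'
#' Each non-empty line holds two whitespace- or tab-separated node labels.
#' Self-loops are dropped (and counted), duplicate and reversed edges are
#' collapsed, so the result is a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @param quiet If `TRUE`, suppress the message about dropped self-loops.
#' @return An [igraph::igraph] object with a `"dropped"` attribute counting
#'   removed self-loops.
#' @export
read_edge_list <- function(path, quiet = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(tokens) != 2)
  if (length(bad) > 0) {
    stop("edge list line ", bad[1], " does not have exactly 2 tokens: '",
         lines[bad[1]], "'", call. = FALSE)
  }
  if (length(tokens) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    attr(g, "dropped") <- c(self_loops = 0L)
    return(g)
  }
  em <- do.call(rbind, tokens)
  loops <- em[, 1] == em[, 2]
  n_loops <- sum(loops)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!quiet && n_loops > 0) {
    message("dropped ", n_loops, " self-loop(s)")
  }
  attr(g, "dropped") <- c(self_loops = as.integer(n_loops))
  g
}

#' Write a graph as a two-column edge list
#'
#' @param graph An [igraph::igraph] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  em <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(em, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
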