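#' Construct a validated abundance table
#'
#' The central container of the ecology stack: a samples x taxa matrix of
#' non-negative integer counts with unique, lexicographically ordered sample
#' and taxon identifiers.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.  Values must be non-negative integers (integer-valued doubles
#'   are accepted and coerced).
#' @param provenance free-text description of where the counts came from.
#' @param canonicalize if `TRUE` (default) rows and columns are sorted
#'   lexicographically by id so downstream results never depend on input
#'   ordering.
#' @return an object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix), `sample_ids`, `taxon_ids`, `provenance`.
#' @export
abundance_table <- function(counts, provenance = "", canonicalize = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("abundance_table: counts must have sample (row) and taxon (column) names")
  if (!is.numeric(counts))
    stop("abundance_table: non-numeric cell values")
  if (anyNA(counts))
    stop("abundance_table: NA cell values")
  if (any(counts < 0))
    stop("abundance_table: negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("abundance_table: counts must be integers (relative abundances are rejected; rarefaction needs counts)")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("abundance_table: duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  dup_t <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_t))
    stop("abundance_table: duplicate taxon id(s): ", paste(dup_t, collapse = ", "))
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("abundance_table: need at least 2 samples and 2 taxa")
  storage.mode(counts) <- "integer"
  if (any(rowSums(counts) == 0L))
    stop("abundance_table: sample(s) with zero total counts: ",
         paste(rownames(counts)[rowSums(counts) == 0L], collapse = ", "))
  if (canonicalize)
    counts <- counts[order(rownames(counts)), order(colnames(counts)), drop = FALSE]
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         taxon_ids = colnames(counts),
         provenance = provenance),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  total counts:", sum(x$counts),
      "| depth range:", paste(range(rowSums(x$counts)), collapse = "-"), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Per-sample relative abundances
#'
#' @param table an `abundance_table`.
#' @return numeric matrix of the same shape with rows summing to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  sweep(table$counts, 1L, rowSums(table$counts), "/")
}

#' Aggregate ASV-level columns to genus level
#'
#' Columns mapping to the same genus are summed.  Taxa whose genus rank is
#' unresolved are pooled into a per-family `"uncultured <family>"` bucket so no
#' abundance mass is dropped; if the family is also unresolved the domain (or
#' `"unknown"`) is used.
#'
#' @param table an `abundance_table` at ASV (or any sub-genus) resolution.
#' @param taxonomy a `taxonomy_map` covering every taxon in `table`.
#' @return an `abundance_table` whose columns are genus labels.  Per-sample
#'   totals are conserved exactly.
#' @export
aggregate_to_genus <- function(table, taxonomy) {
  stopifnot(inherits(table, "abundance_table"), inherits(taxonomy, "taxonomy_map"))
  missing <- setdiff(table$taxon_ids, taxonomy$taxon_id)
  if (length(missing))
    stop("aggregate_to_genus: taxa missing from taxonomy: ",
         paste(missing, collapse = ", "))
  idx <- match(table$taxon_ids, taxonomy$taxon_id)
  genus <- taxonomy$genus[idx]
  family <- taxonomy$family[idx]
  domain <- taxonomy$domain[idx]
  fallback <- ifelse(nzchar(family), paste("uncultured", family),
                     ifelse(nzchar(domain), paste("uncultured", domain),
                            "uncultured unknown"))
  genus <- ifelse(nzchar(genus), genus, fallback)
  agg <- rowsum(t(table$counts), group = genus)  # genera x samples
  abundance_table(t(agg),
                  provenance = paste0(table$provenance,
                                      " | aggregated to genus (",
                                      nrow(agg), " genera)"))
}
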