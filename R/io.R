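#' Read an abundance table from TSV or BIOM-json
#'
#' Tab-delimited tables may be oriented samples-in-rows or taxa-in-rows.  With
#' `orientation = "auto"` (default) the reader matches row/column labels
#' against `sample_hint` (e.g. the sample ids from a metadata file); lacking a
#' hint it assumes taxa-in-rows, the common QIIME export orientation, unless
#' the header cell says otherwise.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param orientation `"auto"`, `"samples_rows"` or `"taxa_rows"` (TSV only).
#' @param sample_hint optional character vector of known sample ids used by
#'   orientation auto-detection.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom-json"),
                                 orientation = c("auto", "samples_rows", "taxa_rows"),
                                 sample_hint = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("read_abundance_table: no such file: ", path)
  if (format == "biom-json") return(read_biom_json(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("read_abundance_table: duplicate id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!is.numeric(m)) stop("read_abundance_table: non-numeric cell values in ", path)
  if (orientation == "auto") {
    rows_are_samples <- if (!is.null(sample_hint)) {
      mean(rownames(m) %in% sample_hint) >= mean(colnames(m) %in% sample_hint)
    } else FALSE
    if (!rows_are_samples) m <- t(m)
  } else if (orientation == "taxa_rows") {
    m <- t(m)
  }
  abundance_table(m, provenance = paste0("read from ", path, " (", format, ")"))
}

#' Write an abundance table
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param format `"tsv"` (samples in rows) or `"biom-json"` (BIOM 1.0 dense).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "abundance_table"))
  if (format == "tsv") {
    df <- data.frame(sample_id = table$sample_ids, table$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_biom_json(table, path)
  }
  invisible(path)
}

# BIOM 1.0 "Table" json, dense matrix, rows = observations (taxa) per the
# format convention, columns = samples.
write_biom_json <- function(table, path) {
  m <- t(table$counts)  # taxa x samples
  obj <- list(
    id = NULL,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = "granuleco",
    date = "1970-01-01T00:00:00",
    rows = lapply(rownames(m), function(id) list(id = id, metadata = NULL)),
    columns = lapply(colnames(m), function(id) list(id = id, metadata = NULL)),
    matrix_type = "dense",
    matrix_element_type = "int",
    shape = c(nrow(m), ncol(m)),
    data = unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

read_biom_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$format) || !grepl("Biological Observation Matrix", obj$format))
    stop("read_biom_json: not a BIOM 1.0 json file: ", path)
  taxa <- vapply(obj$rows, function(r) r$id, character(1))
  samples <- vapply(obj$columns, function(c) c$id, character(1))
  nr <- length(taxa); nc <- length(samples)
  m <- matrix(0, nr, nc, dimnames = list(taxa, samples))
  if (identical(obj$matrix_type, "dense")) {
    for (i in seq_len(nr)) m[i, ] <- unlist(obj$data[[i]])
  } else if (identical(obj$matrix_type, "sparse")) {
    for (trip in obj$data)
      m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  } else stop("read_biom_json: unknown matrix_type")
  abundance_table(t(m), provenance = paste0("read from ", path, " (biom-json)"))
}

#' Read sample metadata
#'
#' Expects a tab-delimited file with columns `sample_id`, `fraction`,
#' `replicate` and any of the studied covariates (`size_mm`,
#' `settling_velocity_m_s`, `density_kg_m3`, `vs_fraction`).  Rows with a
#' missing covariate cell are kept but flagged `complete = FALSE` so
#' covariate-dependent stages can exclude them.
#'
#' @param path file path.
#' @param fraction_labels allowed fraction labels (default A-J).
#' @return a `sample_metadata` data.frame.
#' @export
read_metadata <- function(path, fraction_labels = LETTERS[1:10]) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  req <- c("sample_id", "fraction", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("read_metadata: missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$fraction), fraction_labels)
  if (length(bad))
    stop("read_metadata: fraction label(s) outside the scheme: ",
         paste(bad, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("read_metadata: duplicate sample id(s): ", paste(dup, collapse = ", "))
  cov_cols <- intersect(covariate_names(), names(df))
  df$complete <- if (length(cov_cols))
    stats::complete.cases(df[, cov_cols, drop = FALSE]) else TRUE
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Names of the four studied covariates
#' @return character vector.
#' @export
covariate_names <- function() {
  c("size_mm", "settling_velocity_m_s", "density_kg_m3", "vs_fraction")
}

#' Join an abundance table with its metadata
#'
#' @param table an [abundance_table()].
#' @param metadata a `sample_metadata` data.frame.
#' @return metadata reordered to match `table$sample_ids`.
#' @export
join_metadata <- function(table, metadata) {
  stopifnot(inherits(table, "abundance_table"))
  missing <- setdiff(table$sample_ids, metadata$sample_id)
  if (length(missing))
    stop("join_metadata: sample(s) present in table but absent from metadata: ",
         paste(missing, collapse = ", "))
  metadata[match(table$sample_ids, metadata$sample_id), , drop = FALSE]
}

#' Read a taxonomy map
#'
#' Accepts either explicit rank columns (`domain` ... `genus`) or a QIIME-style
#' `lineage` column of `d__...;p__...;c__...;o__...;f__...;g__...` strings.
#' Unresolved ranks are stored as empty strings.
#'
#' @param path file path (tab-delimited, header required, first column
#'   `taxon_id`).
#' @return a `taxonomy_map` data.frame with columns `taxon_id`, `domain`,
#'   `phylum`, `class`, `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!"taxon_id" %in% names(df))
    stop("read_taxonomy: first column must be 'taxon_id'")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  if ("lineage" %in% names(df)) {
    parsed <- parse_lineage_strings(df$lineage)
    df <- cbind(df["taxon_id"], parsed)
  }
  for (r in ranks) if (!r %in% names(df)) df[[r]] <- ""
  df[ranks] <- lapply(df[ranks], function(x) ifelse(is.na(x), "", x))
  bad <- setdiff(unique(df$domain[nzchar(df$domain)]), c("Bacteria", "Archaea", "unknown"))
  if (length(bad))
    stop("read_taxonomy: domain must be Bacteria/Archaea/unknown, got: ",
         paste(bad, collapse = ", "))
  df <- df[c("taxon_id", ranks)]
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

parse_lineage_strings <- function(lineage) {
  ranks <- c(d = "domain", p = "phylum", c = "class",
             o = "order", f = "family", g = "genus")
  out <- matrix("", nrow = length(lineage), ncol = length(ranks),
                dimnames = list(NULL, unname(ranks)))
  for (i in seq_along(lineage)) {
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      mm <- regmatches(p, regexec("^([dpcofg])__(.*)$", p))[[1]]
      if (length(mm) == 3L && nzchar(mm[3]))
        out[i, ranks[[mm[2]]]] <- mm[3]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Validate a taxonomy map against a table
#'
#' @param table an [abundance_table()].
#' @param taxonomy a `taxonomy_map`.
#' @return invisibly, a list with `n_mapped` and the per-domain tally.
#' @export
check_taxonomy_coverage <- function(table, taxonomy) {
  missing <- setdiff(table$taxon_ids, taxonomy$taxon_id)
  if (length(missing))
    stop("taxonomy does not map taxa: ", paste(missing, collapse = ", "))
  dom <- taxonomy$domain[match(table$taxon_ids, taxonomy$taxon_id)]
  dom[!nzchar(dom)] <- "unknown"
  invisible(list(n_mapped = length(table$taxon_ids), domains = table(dom)))
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' @param path Newick file path.
#' @return an [ape::read.tree()] `phylo` object, validated to have
#'   non-negative branch lengths.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("read_tree: unparseable Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("read_tree: unparseable Newick file: ", path)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("read_tree: tree must have non-negative branch lengths")
  tree
}

#' Check that every table taxon is a tree tip
#'
#' @param table an [abundance_table()].
#' @param tree a `phylo` object.
#' @return invisibly `TRUE`; errors listing the missing tips otherwise.
#' @export
check_tree_coverage <- function(table, tree) {
  missing <- setdiff(table$taxon_ids, tree$tip.label)
  if (length(missing))
    stop("tree is missing tip(s) for table taxa: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Validate a complete input bundle
#'
#' Cross-checks an abundance table against metadata, taxonomy and (optionally)
#' a tree, as the `io validate` entry point does.
#'
#' @param table an [abundance_table()].
#' @param metadata a `sample_metadata` data.frame (optional).
#' @param taxonomy a `taxonomy_map` (optional).
#' @param tree a `phylo` (optional).
#' @return a list report with per-component status.
#' @export
validate_inputs <- function(table, metadata = NULL, taxonomy = NULL, tree = NULL) {
  report <- list(table = sprintf("%d samples x %d taxa", nrow(table$counts),
                                 ncol(table$counts)))
  if (!is.null(metadata)) {
    join_metadata(table, metadata)
    report$metadata <- sprintf("%d records, %d fractions",
                               nrow(metadata), length(unique(metadata$fraction)))
  }
  if (!is.null(taxonomy))
    report$taxonomy <- check_taxonomy_coverage(table, taxonomy)
  if (!is.null(tree)) {
    check_tree_coverage(table, tree)
    report$tree <- sprintf("%d tips, total branch length %.4g",
                           length(tree$tip.label), sum(tree$edge.length))
  }
  report
}
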