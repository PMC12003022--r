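#' Rarefy an abundance table to an even depth
#'
#' Each sample's reads are subsampled without replacement (multivariate
#' hypergeometric draw) to exactly `depth` reads.  The study rule is to
#' rarefy to the minimum sample depth, the default here.
#'
#' @param table an [abundance_table()].
#' @param depth target depth; default `min(rowSums(counts))`.
#' @param seed RNG seed for the draw (default 1; the draw is a single
#'   realisation, as in the original analysis).
#' @return a rarefied [abundance_table()] (taxa with all-zero columns are
#'   retained so taxon sets stay aligned).
#' @export
rarefy <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  rs <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(rs)
  shallow <- table$sample_ids[rs < depth]
  if (length(shallow))
    stop("rarefy: depth ", depth, " exceeds reads in sample(s): ",
         paste(shallow, collapse = ", "))
  counts <- table$counts
  out <- with_seed(seed, {
    t(apply(counts, 1L, function(row) {
      pool <- rep.int(seq_along(row), row)
      drawn <- if (length(pool) == depth) pool else sample(pool, depth)
      tabulate(drawn, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(counts)
  res <- table
  res$counts <- out
  storage.mode(res$counts) <- "integer"
  res$provenance <- paste0(table$provenance, " | rarefied to ", depth,
                           " (seed ", seed, ")")
  res
}

#' Observed richness of a count vector
#' @param counts non-negative counts for one sample.
#' @return number of taxa with non-zero count.
#' @export
richness <- function(counts) {
  if (sum(counts) <= 0) stop("richness: all-zero sample")
  sum(counts > 0)
}

#' Shannon entropy (nats) of a count vector
#' @param counts non-negative counts for one sample.
#' @return H = -sum p log p over taxa with p > 0, natural log.
#' @export
shannon <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("shannon: all-zero sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Pielou's evenness of a count vector
#' @param counts non-negative counts for one sample.
#' @return J = H / log(S); defined as 0 when only one taxon is present.
#' @export
pielou <- function(counts) {
  s <- richness(counts)
  if (s == 1L) return(0)
  shannon(counts) / log(s)
}

#' Alpha diversity table
#'
#' Computes rarefied richness, Shannon entropy and Pielou's evenness per
#' sample.  All metrics are computed on the rarefied table (the `"rarefied
#' richness"` convention of the study).
#'
#' @param table an [abundance_table()] of raw counts.
#' @param depth,seed passed to [rarefy()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`, plus attributes `depth` and `seed`.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1) {
  rt <- rarefy(table, depth, seed)
  out <- data.frame(
    sample_id = rt$sample_ids,
    richness = apply(rt$counts, 1L, richness),
    shannon = apply(rt$counts, 1L, shannon),
    pielou = apply(rt$counts, 1L, pielou),
    row.names = NULL)
  attr(out, "depth") <- sum(rt$counts[1, ])
  attr(out, "seed") <- seed
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i,j) = 1 - 2 sum_k min(x_ik, x_jk) / (sum_k x_ik + sum_k x_jk)`.
#'
#' @param x an [abundance_table()] or a samples x taxa numeric matrix.
#' @return symmetric matrix in `[0,1]` with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  if (any(rowSums(m) <= 0)) stop("bray_curtis: zero-sum sample")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  rs <- rowSums(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- sum(pmin(m[i, ], m[j, ]))
    d[i, j] <- d[j, i] <- 1 - 2 * shared / (rs[i] + rs[j])
  }
  distance_matrix(d, "bray_curtis")
}

# Edge x sample presence matrix: does any tip below this edge occur in the
# sample?  Computed by postorder accumulation over the rooted tree.
edge_presence <- function(tree, presence) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  node_pres <- matrix(FALSE, n_node, nrow(presence))
  node_pres[seq_len(n_tip), ] <- t(presence[, tree$tip.label, drop = FALSE])
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; child <- po$edge[k, 2]
    node_pres[par, ] <- node_pres[par, ] | node_pres[child, ]
  }
  node_pres[tree$edge[, 2], , drop = FALSE]  # one row per edge
}

#' Unweighted UniFrac distance matrix
#'
#' Fraction of the branch length observed in either sample that is unique to
#' one of them, on presence/absence of tips.
#'
#' @param table an [abundance_table()] whose taxa are all tips of `tree`.
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric matrix in `[0,1]` with attribute
#'   `metric = "unweighted_unifrac"`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "abundance_table"))
  check_tree_coverage(table, tree)
  pres <- table$counts > 0
  B <- edge_presence(tree, pres) * 1  # edges x samples, 0/1
  bl <- tree$edge.length
  shared <- crossprod(B * bl, B)       # sum over edges of bl * p_i * p_j
  per_sample <- colSums(B * bl)
  n <- ncol(B)
  d <- matrix(0, n, n, dimnames = list(table$sample_ids, table$sample_ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    union <- per_sample[i] + per_sample[j] - shared[i, j]
    d[i, j] <- if (union > 0) 1 - shared[i, j] / union else 0
  }
  distance_matrix((d + t(d)) / 2, "unweighted_unifrac")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS (vegan's `monoMDS`, global model) with multiple
#' random restarts, keeping the lowest-stress solution.
#'
#' @param d a distance matrix (as from [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param seed RNG seed.
#' @param restarts number of random restarts (default 20).
#' @return list with `points` (n x k coordinates) and `stress` (Kruskal
#'   stress-1, in `[0,1]`).
#' @export
nmds <- function(d, k = 2, seed = 1, restarts = 20) {
  if (k >= nrow(d)) stop("nmds: k must be smaller than the number of samples")
  dd <- stats::as.dist(d)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- vegan::monoMDS(dd, k = k, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    list(points = best$points, stress = best$stress)
  })
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  a <- length(lev)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix: pseudo-F from among/within
#' sums of squared distances, p-value by free permutation of sample labels.
#'
#' @param d distance matrix.
#' @param groups factor-like group labels, one per sample.
#' @param n_perm number of permutations (default 999, giving p resolution
#'   1/1000).
#' @param seed RNG seed.
#' @return list with `pseudo_f`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("permanova: length(groups) != nrow(d)")
  tab <- table(groups)
  if (length(tab) < 2) stop("permanova: need at least 2 groups")
  if (all(tab < 2)) stop("permanova: all groups are singletons")
  d2 <- unclass(d)^2
  f_obs <- permanova_f(d2, groups)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      permanova_f(d2, sample(groups)) >= f_obs, logical(1)))
  })
  list(pseudo_f = f_obs, p_value = (1 + count) / (n_perm + 1),
       n_permutations = n_perm, seed = seed)
}

#' Classical one-way ANOVA
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return list with `f`, `p_value`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("anova_oneway: need >= 2 groups")
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df_b <- nlevels(groups) - 1L
  df_w <- n - nlevels(groups)
  if (ssw <= 0) {
    if (ssb <= 0) stop("anova_oneway: degenerate input (no variance at all)")
    return(list(f = Inf, p_value = 0, df_between = df_b, df_within = df_w))
  }
  f <- (ssb / df_b) / (ssw / df_w)
  list(f = f, p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Per-sample proportion of a lineage and its trend along a covariate
#'
#' Computes, per sample, the summed relative abundance of a lineage set
#' (e.g. all archaeal taxa), then tests (i) differences across fraction
#' groups by one-way ANOVA and (ii) the linear trend against a continuous
#' covariate by least squares.
#'
#' @param table an [abundance_table()].
#' @param taxa character vector of taxon ids in the lineage, or a
#'   `taxonomy_map` together with `domain` to select by domain.
#' @param metadata `sample_metadata` with `fraction` and the covariate.
#' @param covariate covariate column name (default `"size_mm"`).
#' @param domain when `taxa` is a `taxonomy_map`, the domain to select.
#' @return list with `proportion` (per sample), `slope`, `slope_p`,
#'   `anova_f`, `anova_p`.
#' @export
domain_proportion_trend <- function(table, taxa, metadata,
                                    covariate = "size_mm", domain = "Archaea") {
  if (inherits(taxa, "taxonomy_map"))
    taxa <- taxa$taxon_id[taxa$domain == domain]
  taxa <- intersect(taxa, table$taxon_ids)
  if (!length(taxa)) stop("domain_proportion_trend: no lineage taxa in table")
  md <- join_metadata(table, metadata)
  rel <- relative_abundance(table)
  prop <- rowSums(rel[, taxa, drop = FALSE])
  x <- md[[covariate]]
  if (is.null(x)) stop("domain_proportion_trend: covariate '", covariate,
                       "' absent from metadata")
  if (stats::var(x) == 0) stop("domain_proportion_trend: covariate does not vary")
  fit <- stats::lm(prop ~ x)
  sm <- summary(fit)
  av <- anova_oneway(prop, md$fraction)
  list(proportion = stats::setNames(prop, table$sample_ids),
       slope = unname(stats::coef(fit)[2]),
       slope_p = sm$coefficients[2, 4],
       anova_f = av$f, anova_p = av$p_value)
}
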