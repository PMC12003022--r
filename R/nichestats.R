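#' A taxon's proportional profile over resource states
#'
#' @param table an [abundance_table()].
#' @param taxon taxon id.
#' @param grouping optional vector of state labels, one per sample (e.g. the
#'   fraction label); `NULL` treats each sample as its own state.
#' @return named proportion vector `p` with `sum(p) = 1`.
#' @export
taxon_profile <- function(table, taxon, grouping = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (!taxon %in% table$taxon_ids) stop("taxon_profile: unknown taxon ", taxon)
  cnt <- table$counts[, taxon]
  if (!is.null(grouping)) cnt <- tapply(cnt, grouping, sum)
  tot <- sum(cnt)
  if (tot <= 0) stop("taxon_profile: taxon ", taxon, " has zero total count")
  cnt / tot
}

#' Abundance-weighted mean pairwise covariate distance
#'
#' The empirical specificity statistic: the Rao-type dispersion
#' `E = sum_{i<k} p_i p_k |x_i - x_k| / sum_{i<k} p_i p_k`.  A taxon whose
#' abundance is concentrated on samples with similar covariate values has a
#' small E.
#'
#' @param p weights over samples, summing to 1.
#' @param x covariate values per sample.
#' @return E (0 when all weight sits on a single sample).
#' @export
spec_empirical <- function(p, x) {
  stopifnot(length(p) == length(x), abs(sum(p) - 1) < 1e-8)
  denom <- 1 - sum(p^2)
  if (denom <= 0) return(0)
  D <- abs(outer(x, x, "-"))
  as.numeric(p %*% D %*% p) / denom
}

#' Permutation-null specificity (Spec) scores
#'
#' For each taxon, the empirical statistic E ([spec_empirical()]) is compared
#' with its null distribution under random permutation of the taxon's weights
#' across samples.  `Spec = (E - mean(E_null)) / mean(E_null)` is centred at
#' 0: negative values flag taxa confined to a narrow covariate range
#' (specific), positive values flag cosmopolitan taxa.  Two-sided permutation
#' p-values (doubled smaller tail) are corrected across taxa by
#' Benjamini-Hochberg.
#'
#' @param table an [abundance_table()].
#' @param metadata `sample_metadata` carrying the covariate.
#' @param covariate covariate column name.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param alpha FDR level for the `label` column (default 0.05).
#' @param occupancy_min taxa must occur in at least this many samples.
#' @return data.frame of class `spec_result`: `taxon_id`, `E`, `null_mean`,
#'   `null_sd`, `spec`, `p_value`, `q_value`, `label`.
#' @export
spec_score <- function(table, metadata, covariate = "size_mm", n_perm = 999,
                       seed = 1, alpha = 0.05, occupancy_min = 2) {
  stopifnot(inherits(table, "abundance_table"))
  md <- join_metadata(table, metadata)
  x <- md[[covariate]]
  if (is.null(x)) stop("spec_score: covariate '", covariate, "' not in metadata")
  if (anyNA(x)) stop("spec_score: covariate has missing values")
  if (stats::var(x) == 0) stop("spec_score: covariate is constant; Spec undefined")
  keep <- colSums(table$counts > 0) >= occupancy_min
  cnt <- table$counts[, keep, drop = FALSE]
  P <- t(sweep(cnt, 2L, colSums(cnt), "/"))   # taxa x samples weights
  denom <- 1 - rowSums(P^2)
  D <- abs(outer(x, x, "-"))
  e_obs <- rowSums((P %*% D) * P) / denom
  n <- length(x)
  null_sum <- numeric(nrow(P)); null_sq <- numeric(nrow(P))
  n_le <- integer(nrow(P)); n_ge <- integer(nrow(P))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Db <- D[idx, idx]
      e_b <- rowSums((P %*% Db) * P) / denom
      null_sum <- null_sum + e_b
      null_sq <- null_sq + e_b^2
      n_le <- n_le + (e_b <= e_obs)
      n_ge <- n_ge + (e_b >= e_obs)
    }
  })
  null_mean <- null_sum / n_perm
  null_sd <- sqrt(pmax(null_sq / n_perm - null_mean^2, 0))
  spec <- (e_obs - null_mean) / null_mean
  p_lo <- (1 + n_le) / (n_perm + 1)
  p_hi <- (1 + n_ge) / (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_lo, p_hi))
  q <- stats::p.adjust(p, method = "BH")
  label <- ifelse(q < alpha & spec < 0, "specific",
                  ifelse(q < alpha & spec > 0, "cosmopolitan", "ns"))
  out <- data.frame(taxon_id = rownames(P), covariate = covariate, E = e_obs,
                    null_mean = null_mean, null_sd = null_sd, spec = spec,
                    p_value = p, q_value = q, label = label, row.names = NULL)
  class(out) <- c("spec_result", "data.frame")
  out
}

#' Pairwise correlation of Spec scores across covariates
#'
#' @param spec_list named list of `spec_result` data.frames (one per
#'   covariate) over the same taxon set.
#' @return symmetric matrix of Pearson R between per-taxon Spec vectors.
#' @export
spec_pairwise_correlation <- function(spec_list) {
  if (length(spec_list) < 2) stop("spec_pairwise_correlation: need >= 2 covariates")
  ids <- Reduce(intersect, lapply(spec_list, `[[`, "taxon_id"))
  if (length(ids) < 3) stop("spec_pairwise_correlation: fewer than 3 shared taxa")
  m <- sapply(spec_list, function(s) s$spec[match(ids, s$taxon_id)])
  stats::cor(m)
}

#' Levins' niche breadth
#'
#' @param p proportion vector over N resource states (sums to 1).
#' @return list with `B = 1 / sum(p^2)` (inverse Simpson concentration,
#'   between 1 and N) and the standardisation `BA = (B - 1) / (N - 1)`.
#' @export
levins_breadth <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, length(p) >= 2)
  B <- 1 / sum(p^2)
  list(B = B, BA = (B - 1) / (length(p) - 1))
}

#' Hurlbert's niche breadth
#'
#' Levins' breadth weighted by resource availability:
#' `B' = 1 / sum(p_i^2 / a_i)` with `sum(a) = 1`.  Equals 1 when use is
#' proportional to availability and `min(a)` when all use falls in the
#' scarcest state.
#'
#' @param p proportion vector of resource use.
#' @param a availability weights, positive, summing to 1.
#' @return B'.
#' @export
hurlberts_breadth <- function(p, a) {
  stopifnot(length(p) == length(a), abs(sum(p) - 1) < 1e-8,
            abs(sum(a) - 1) < 1e-8)
  if (any(a <= 0 & p > 0))
    stop("hurlberts_breadth: zero availability in an occupied state")
  ok <- p > 0
  1 / sum(p[ok]^2 / a[ok])
}

#' Availability weights from a continuous state covariate
#'
#' Min-max normalises the per-state covariate onto `[floor, 1]` and
#' renormalises to sum 1.  NOTE: the availability construction for
#' continuous gradients is a modelling choice, not a measured quantity; the
#' floor (default 0.05) keeps every state's availability positive.
#'
#' @param x covariate value per state.
#' @param floor lower bound of the normalised range.
#' @return availability vector summing to 1.
#' @export
availability_from_covariate <- function(x, floor = 0.05) {
  if (max(x) == min(x)) return(rep(1 / length(x), length(x)))
  a <- floor + (1 - floor) * (x - min(x)) / (max(x) - min(x))
  a / sum(a)
}

#' Generalist/specialist classification by a null model on Levins' B
#'
#' The observed pooled-by-fraction breadth is compared with a null obtained
#' by reallocating the taxon's total count across states by multinomial
#' draws with probabilities proportional to state availability (state total
#' abundance).  Observed B above the upper null quantile is a generalist,
#' below the lower quantile a specialist.
#'
#' @param table an [abundance_table()].
#' @param taxon taxon id.
#' @param grouping state label per sample (e.g. fraction); `NULL` for
#'   per-sample states.
#' @param n_perm null draws (default 999).
#' @param ci central null interval mass (default 0.95).
#' @param seed RNG seed.
#' @return list with `B`, `BA`, `null_lower`, `null_upper`,
#'   `classification`.
#' @export
classify_breadth <- function(table, taxon, grouping = NULL, n_perm = 999,
                             ci = 0.95, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  cnt <- table$counts[, taxon]
  state_tot <- if (is.null(grouping)) colSums(t(table$counts)) else
    tapply(rowSums(table$counts), grouping, sum)
  if (!is.null(grouping)) cnt <- tapply(cnt, grouping, sum)
  total <- sum(cnt)
  if (total <= 0) stop("classify_breadth: taxon absent")
  obs <- levins_breadth(cnt / total)
  avail <- state_tot / sum(state_tot)
  null_b <- with_seed(seed, {
    draws <- stats::rmultinom(n_perm, total, avail)
    1 / colSums((draws / total)^2)
  })
  lo <- stats::quantile(null_b, (1 - ci) / 2, names = FALSE)
  hi <- stats::quantile(null_b, 1 - (1 - ci) / 2, names = FALSE)
  cls <- if (obs$B > hi) "generalist" else if (obs$B < lo) "specialist" else "neither"
  list(B = obs$B, BA = obs$BA, null_lower = lo, null_upper = hi,
       classification = cls)
}

#' Sign of a taxon's association with a covariate
#'
#' Spearman correlation between the taxon's state profile and the covariate,
#' reported as `"+"`/`"-"` when its permutation p-value is below `alpha`,
#' `"0"` otherwise.
#'
#' @param p taxon proportion profile over states.
#' @param x covariate per state.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return one of `"+"`, `"-"`, `"0"`.
#' @export
association_sign <- function(p, x, n_perm = 999, seed = 1, alpha = 0.05) {
  if (stats::sd(p) == 0 || stats::sd(x) == 0) return("0")
  rho <- stats::cor(p, x, method = "spearman")
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      abs(stats::cor(sample(p), x, method = "spearman")) >= abs(rho) - 1e-12,
      logical(1)))
  })
  p_val <- (1 + count) / (n_perm + 1)
  if (p_val < alpha) (if (rho > 0) "+" else "-") else "0"
}

#' Asymmetric Levins' niche overlap
#'
#' `LO_{1,2} = sum_i p1_i p2_i / sum_i p1_i^2`.  `LO_{1,2} = 1` means taxon 1
#' fully overlaps wherever taxon 2 occurs; the matrix is generally
#' asymmetric.
#'
#' @param p1,p2 proportion profiles over the same states.
#' @return LO value for (taxon 1, taxon 2).
#' @export
levins_overlap <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  sum(p1 * p2) / sum(p1^2)
}

#' Levins' overlap matrix for a set of taxa
#'
#' @param table an [abundance_table()].
#' @param taxa taxon ids (e.g. the generalist/specialist call list).
#' @param grouping state label per sample, or `NULL` for per-sample states.
#' @return square (asymmetric) matrix with unit diagonal.
#' @export
overlap_matrix <- function(table, taxa, grouping = NULL) {
  profiles <- sapply(taxa, function(t) taxon_profile(table, t, grouping))
  k <- length(taxa)
  LO <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k)) for (j in seq_len(k))
    LO[i, j] <- levins_overlap(profiles[, i], profiles[, j])
  LO
}

#' Full niche-breadth table across taxa and covariates
#'
#' Convenience wrapper computing, per taxon: pooled-by-fraction Levins'
#' B/BA, the generalist/specialist call, and per covariate Hurlbert's B' and
#' the association sign.
#'
#' @param table an [abundance_table()].
#' @param metadata `sample_metadata`.
#' @param covariates covariate column names present in the metadata.
#' @param n_perm,ci,seed passed to the null model.
#' @param occupancy_min minimum sample occupancy for a taxon to be scored.
#' @return data.frame with one row per taxon.
#' @export
breadth_table <- function(table, metadata, covariates = covariate_names(),
                          n_perm = 999, ci = 0.95, seed = 1,
                          occupancy_min = 2) {
  md <- join_metadata(table, metadata)
  covariates <- intersect(covariates, names(md))
  keep <- table$taxon_ids[colSums(table$counts > 0) >= occupancy_min]
  state_x <- lapply(covariates, function(cv)
    tapply(md[[cv]], md$fraction, mean))
  names(state_x) <- covariates
  rows <- lapply(seq_along(keep), function(i) {
    tx <- keep[i]
    cb <- classify_breadth(table, tx, grouping = md$fraction,
                           n_perm = n_perm, ci = ci, seed = seed + i)
    p <- taxon_profile(table, tx, grouping = md$fraction)
    row <- data.frame(taxon_id = tx, B = cb$B, BA = cb$BA,
                      classification = cb$classification)
    for (cv in covariates) {
      a <- availability_from_covariate(state_x[[cv]])
      row[[paste0("hurlbert_", cv)]] <- hurlberts_breadth(p, a)
      row[[paste0("assoc_", cv)]] <-
        association_sign(p, state_x[[cv]], n_perm = n_perm, seed = seed + i)
    }
    row
  })
  do.call(rbind, rows)
}
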