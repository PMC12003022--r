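#' Genetic algorithm hyperparameters for EQO
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param crossover_rate probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate per-bit flip probability; `NULL` means `1/n_taxa`.
#' @param elitism_count individuals copied unchanged each generation.
#' @param parsimony small per-member penalty applied to the search fitness
#'   (not to the reported objective).  It breaks the near-ties created by
#'   very-low-abundance taxa whose inclusion changes the objective by
#'   essentially nothing ("free riders"), so returned ensembles contain only
#'   members that earn their place.  Default `1e-4`.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `ga_params`.
#' @export
ga_params <- function(population_size = 200, generations = 500,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism_count = 2, parsimony = 1e-4, seed = 1) {
  stopifnot(population_size > 0, generations > 0,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) || (mutation_rate >= 0 && mutation_rate <= 1),
            elitism_count >= 1, parsimony >= 0)
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism_count = elitism_count, parsimony = parsimony,
                 seed = seed),
            class = "ga_params")
}

#' Summed relative abundance of an ensemble
#'
#' @param rel samples x taxa relative-abundance matrix (rows sum to 1), or an
#'   [abundance_table()] (converted internally).
#' @param members taxon ids (or column indices) of the ensemble.
#' @return per-sample ensemble abundance, in `[0, 1]`.
#' @export
ensemble_abundance <- function(rel, members) {
  if (inherits(rel, "abundance_table")) rel <- relative_abundance(rel)
  if (is.character(members)) {
    bad <- setdiff(members, colnames(rel))
    if (length(bad)) stop("ensemble_abundance: unknown member id(s): ",
                          paste(bad, collapse = ", "))
  }
  if (length(members) == 0) return(stats::setNames(rep(0, nrow(rel)), rownames(rel)))
  rowSums(rel[, members, drop = FALSE])
}

#' Continuous-mode EQO objective: Pearson r with a covariate
#'
#' @inheritParams ensemble_abundance
#' @param covariate numeric covariate, one value per sample.
#' @return Pearson correlation of ensemble abundance with the covariate;
#'   defined as 0 (with attribute `degenerate = TRUE`) when the ensemble
#'   abundance has zero variance.
#' @export
objective_continuous <- function(rel, members, covariate) {
  a <- ensemble_abundance(rel, members)
  if (stats::sd(a) == 0) return(structure(0, degenerate = TRUE))
  stats::cor(a, covariate)
}

#' Uniform-mode EQO objective: coefficient of variation
#'
#' @inheritParams ensemble_abundance
#' @return `sd/mean` of the per-sample ensemble abundance; `Inf` (flagged)
#'   when the mean is zero.
#' @export
objective_uniform <- function(rel, members) {
  a <- ensemble_abundance(rel, members)
  if (mean(a) == 0) return(structure(Inf, degenerate = TRUE))
  stats::sd(a) / mean(a)
}

# Raw objective of a matrix of candidate ensemble-abundance columns
# (continuous: Pearson r, maximized; uniform: -CV, maximized).
obj_cols <- function(M, covariate, mode) {
  if (mode == "continuous") {
    sds <- apply(M, 2L, stats::sd)
    r <- rep(0, ncol(M))
    ok <- sds > 0
    if (any(ok)) r[ok] <- as.vector(stats::cor(M[, ok, drop = FALSE], covariate))
    r[!ok] <- -Inf
    r
  } else {
    mu <- colMeans(M)
    -ifelse(mu > 0, apply(M, 2L, stats::sd) / mu, Inf)
  }
}

# Fitness (penalized) and raw objective of a population.
# P: pop x n binary matrix; X: samples x n relative abundances.
eqo_fitness <- function(P, X, covariate, mode, parsimony = 0) {
  A <- X %*% t(P)
  raw <- obj_cols(A, covariate, mode)
  obj <- if (mode == "continuous") raw else -raw
  list(fitness = raw - parsimony * rowSums(P), objective = obj)
}

# Per-taxon alignment score used by the repair operator (cheap proxy for
# marginal contribution): continuous mode = correlation with the covariate,
# uniform mode = negative single-taxon CV.
taxon_scores <- function(X, covariate, mode) {
  s <- obj_cols(X, covariate, mode)
  s[!is.finite(s)] <- -1e9
  s
}

repair_population <- function(P, m, scores) {
  sizes <- rowSums(P)
  for (i in which(sizes > m)) {
    on <- which(P[i, ])
    drop <- on[order(scores[on])][seq_len(length(on) - m)]
    P[i, drop] <- FALSE
  }
  for (i in which(sizes == 0))
    P[i, sample.int(ncol(P), 1L)] <- TRUE
  P
}

# Best-improvement local search over single-member moves: additions (within
# the size budget), drops, and swaps, under the penalized fitness.
local_search <- function(members, X, covariate, mode, m, parsimony = 0) {
  n <- ncol(X)
  fit_one <- function(a, k) obj_cols(matrix(a, ncol = 1), covariate, mode) -
    parsimony * k
  repeat {
    k <- length(members)
    a <- rowSums(X[, members, drop = FALSE])
    cur <- fit_one(a, k)
    best_gain <- 1e-12; best_set <- NULL
    out <- setdiff(seq_len(n), members)
    if (k < m && length(out)) {
      f <- obj_cols(X[, out, drop = FALSE] + a, covariate, mode) -
        parsimony * (k + 1)
      j <- which.max(f)
      if (f[j] - cur > best_gain) { best_gain <- f[j] - cur
                                    best_set <- c(members, out[j]) }
    }
    for (i in members) {
      a_minus <- a - X[, i]
      rest <- setdiff(members, i)
      if (length(rest)) {
        o <- fit_one(a_minus, k - 1)
        if (o - cur > best_gain) { best_gain <- o - cur; best_set <- rest }
      }
      if (length(out)) {
        f <- obj_cols(X[, out, drop = FALSE] + a_minus, covariate, mode) -
          parsimony * k
        j <- which.max(f)
        if (f[j] - cur > best_gain) { best_gain <- f[j] - cur
                                      best_set <- c(rest, out[j]) }
      }
    }
    if (is.null(best_set)) return(members)
    members <- best_set
  }
}

greedy_seed <- function(X, covariate, mode, m, parsimony = 0) {
  n <- ncol(X)
  members <- integer(0)
  best_fit <- -Inf
  a <- rep(0, nrow(X))
  avail <- seq_len(n)
  for (step in seq_len(m)) {
    f <- obj_cols(X[, avail, drop = FALSE] + a, covariate, mode) -
      parsimony * step
    pick <- which.max(f)
    if (f[pick] <= best_fit) break
    best_fit <- f[pick]
    members <- c(members, avail[pick])
    a <- a + X[, avail[pick]]
    avail <- avail[-pick]
    if (!length(avail)) break
  }
  members
}

#' Ensemble quotient optimisation by genetic algorithm
#'
#' Searches binary genus-membership vectors of cardinality at most `m` for
#' the subset whose summed relative abundance either maximally correlates
#' with a continuous covariate (`mode = "continuous"`) or is maximally
#' stable, i.e. has minimal coefficient of variation across samples
#' (`mode = "uniform"`).  Memetic elitist GA: tournament selection, uniform
#' crossover, per-bit mutation, a repair operator enforcing the size budget,
#' greedy/top-correlate seeding, and periodic best-improvement local search
#' over single-member moves.  The search fitness carries a small per-member
#' parsimony penalty (see [ga_params()]); the reported objective is the raw
#' statistic.
#'
#' @param table an [abundance_table()] (genus level recommended).
#' @param covariate numeric covariate per sample (continuous mode), or `NULL`
#'   for uniform mode.
#' @param mode `"continuous"` or `"uniform"`.
#' @param m maximum ensemble size.
#' @param ga a [ga_params()] object.
#' @param occupancy_min candidate genera must be non-zero in at least this
#'   many samples (default 2; singletons cannot carry signal).
#' @return list of class `ensemble_result`: `mode`, `member_taxa`,
#'   `objective` (Pearson r or CV), `fitness_trajectory` (best penalized
#'   fitness per generation, non-decreasing), `seed`, `m`.
#' @export
eqo_search <- function(table, covariate = NULL,
                       mode = c("continuous", "uniform"), m = 20,
                       ga = ga_params(), occupancy_min = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "abundance_table"), m >= 1)
  if (mode == "continuous" && is.null(covariate))
    stop("eqo_search: continuous mode needs a covariate")
  rel <- relative_abundance(table)
  pool <- colSums(table$counts > 0) >= occupancy_min
  X <- rel[, pool, drop = FALSE]
  n <- ncol(X)
  if (m > n) stop("eqo_search: m exceeds the candidate taxon count (", n, ")")
  mut <- if (is.null(ga$mutation_rate)) 1 / n else ga$mutation_rate
  scores <- taxon_scores(X, covariate, mode)
  eps <- ga$parsimony

  ls_every <- if (n <= 50) 10L else 50L
  with_seed(ga$seed, {
    pop_n <- ga$population_size
    P <- matrix(FALSE, pop_n, n)
    for (i in seq_len(pop_n))
      P[i, sample.int(n, sample.int(m, 1L))] <- TRUE
    # memetic seeding: greedy forward selection and the top single/multi
    # correlates, each polished by local search
    gs <- local_search(greedy_seed(X, covariate, mode, m, eps),
                       X, covariate, mode, m, eps)
    P[1, ] <- FALSE; P[1, gs] <- TRUE
    top <- order(scores, decreasing = TRUE)[seq_len(min(m, n))]
    ts <- local_search(top, X, covariate, mode, m, eps)
    P[2, ] <- FALSE; P[2, ts] <- TRUE
    for (k in seq_len(min(5L, n)))
      if (k + 2 <= pop_n) { P[k + 2, ] <- FALSE; P[k + 2, top[k]] <- TRUE }
    # small pools: multi-start local search is cheap and covers basins the
    # single-swap neighbourhood of the greedy seed cannot reach
    if (n <= 50) {
      for (k in seq_len(min(20L, pop_n - 8L))) {
        start <- sample.int(n, min(m, sample.int(m, 1L)))
        polished <- local_search(start, X, covariate, mode, m, eps)
        P[k + 7L, ] <- FALSE; P[k + 7L, polished] <- TRUE
      }
    }
    P <- repair_population(P, m, scores)

    trajectory <- numeric(ga$generations)
    ev <- eqo_fitness(P, X, covariate, mode, eps)
    for (gen in seq_len(ga$generations)) {
      ord <- order(ev$fitness, decreasing = TRUE)
      elite <- P[ord[seq_len(ga$elitism_count)], , drop = FALSE]
      i1 <- sample.int(pop_n, pop_n, replace = TRUE)
      i2 <- sample.int(pop_n, pop_n, replace = TRUE)
      winners <- ifelse(ev$fitness[i1] >= ev$fitness[i2], i1, i2)
      parents <- P[winners, , drop = FALSE]
      child <- parents
      for (p in seq(1L, pop_n - 1L, by = 2L)) {
        if (stats::runif(1) < ga$crossover_rate) {
          mask <- stats::runif(n) < 0.5
          a <- parents[p, ]; b <- parents[p + 1L, ]
          child[p, mask] <- b[mask]
          child[p + 1L, mask] <- a[mask]
        }
      }
      flips <- matrix(stats::runif(pop_n * n) < mut, pop_n, n)
      child <- xor(child, flips)
      child <- repair_population(child, m, scores)
      child[seq_len(ga$elitism_count), ] <- elite
      P <- child
      ev <- eqo_fitness(P, X, covariate, mode, eps)
      # memetic step: periodically hill-climb the incumbent (cheap on
      # small candidate pools, so polish more often there)
      if (gen %% ls_every == 0L || gen == ga$generations) {
        b <- which.max(ev$fitness)
        improved <- local_search(which(P[b, ]), X, covariate, mode, m, eps)
        P[b, ] <- FALSE; P[b, improved] <- TRUE
        ev <- eqo_fitness(P, X, covariate, mode, eps)
      }
      trajectory[gen] <- max(ev$fitness)
    }
    best <- which.max(ev$fitness)
    structure(list(mode = mode,
                   member_taxa = colnames(X)[P[best, ]],
                   objective = ev$objective[best],
                   fitness_trajectory = trajectory,
                   seed = ga$seed, m = m),
              class = "ensemble_result")
  })
}

#' Exhaustive EQO search (testing oracle)
#'
#' Enumerates every subset of size `<= m` of the candidate pool and returns
#' the optimum of the same penalized fitness the GA searches (so the two
#' routes share one well-defined optimisation problem).  Refuses instances
#' with more than `max_subsets` candidate subsets.
#'
#' @inheritParams eqo_search
#' @param parsimony per-member penalty (match the GA's, default 1e-4).
#' @param max_subsets enumeration budget (default 1e6).
#' @return an `ensemble_result` (with empty `fitness_trajectory`).
#' @export
eqo_bruteforce <- function(table, covariate = NULL,
                           mode = c("continuous", "uniform"), m = 3,
                           occupancy_min = 2, parsimony = 1e-4,
                           max_subsets = 1e6) {
  mode <- match.arg(mode)
  rel <- relative_abundance(table)
  pool <- colSums(table$counts > 0) >= occupancy_min
  X <- rel[, pool, drop = FALSE]
  n <- ncol(X)
  if (m > n) stop("eqo_bruteforce: m exceeds candidate count")
  n_sub <- sum(choose(n, seq_len(m)))
  if (n_sub > max_subsets) stop("eqo_bruteforce: instance too large (",
                                format(n_sub, big.mark = ","), " subsets)")
  best_members <- integer(0)
  best_fit <- -Inf; best_obj <- NA_real_
  for (k in seq_len(m)) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      a <- rowSums(X[, idx, drop = FALSE])
      raw <- obj_cols(matrix(a, ncol = 1), covariate, mode)
      fit <- raw - parsimony * k
      if (fit > best_fit) {
        best_fit <- fit
        best_obj <- if (mode == "continuous") raw else -raw
        best_members <- idx
      }
    }
  }
  structure(list(mode = mode, member_taxa = colnames(X)[best_members],
                 objective = best_obj, fitness_trajectory = numeric(0),
                 seed = NA_integer_, m = m),
            class = "ensemble_result")
}
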