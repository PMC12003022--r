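test_that("ensemble abundance is additive and closed", {
  tab <- make_table(n_samples = 5, n_taxa = 6, seed = 4)
  rel <- relative_abundance(tab)
  expect_equal(unname(ensemble_abundance(rel, tab$taxon_ids)), rep(1, 5))
  expect_equal(unname(ensemble_abundance(rel, character(0))), rep(0, 5))
  a <- tab$taxon_ids[1:2]; b <- tab$taxon_ids[4:5]
  expect_equal(ensemble_abundance(rel, c(a, b)),
               ensemble_abundance(rel, a) + ensemble_abundance(rel, b))
  expect_error(ensemble_abundance(rel, "nope"), "unknown member")
})

test_that("objectives match their textbook formulas", {
  tab <- make_table(n_samples = 4, n_taxa = 5, seed = 6)
  rel <- relative_abundance(tab)
  x <- c(0.1, 0.5, 1.2, 2.0)
  mem <- tab$taxon_ids[c(1, 3)]
  expect_equal(objective_continuous(rel, mem, x),
               cor(rowSums(rel[, mem]), x))
  # proportionality gives r = 1; reversing the covariate flips the sign
  relp <- matrix(c(x / sum(x), 1 - x / sum(x)), 4, 2,
                 dimnames = list(rownames(rel), c("u", "v")))
  expect_equal(objective_continuous(relp, "u", x), 1)
  expect_equal(objective_continuous(relp, "u", -x),
               -objective_continuous(relp, "u", x))

  # CV: values (0.2, 0.4) -> sd 0.1414 / mean 0.3
  relc <- matrix(c(0.2, 0.4, 0.8, 0.6), 2, 2,
                 dimnames = list(c("s1", "s2"), c("w", "z")))
  expect_equal(objective_uniform(relc, "w"), sd(c(0.2, 0.4)) / 0.3)
  expect_equal(objective_uniform(relc, "w"), 0.4714, tolerance = 1e-4)
  # constant ensemble abundance -> CV 0; scale invariance
  expect_equal(objective_uniform(relc, c("w", "z")), 0)
})

test_that("brute force reduces to argmax at m = 1 and ignores column order", {
  tab <- make_table(n_samples = 8, n_taxa = 7, seed = 9)
  x <- rnorm(8); set.seed(10)
  bf <- eqo_bruteforce(tab, covariate = x, mode = "continuous", m = 1)
  rel <- relative_abundance(tab)
  singles <- apply(rel, 2, function(v) cor(v, x))
  expect_equal(bf$member_taxa, names(which.max(singles)))
  # permutation invariance of the candidate order
  perm <- sample(ncol(tab$counts))
  tab2 <- abundance_table(tab$counts[, perm])
  bf2 <- eqo_bruteforce(tab2, covariate = x, mode = "continuous", m = 1)
  expect_equal(sort(bf$member_taxa), sort(bf2$member_taxa))
  expect_error(eqo_bruteforce(tab, covariate = x, m = 3, max_subsets = 10),
               "too large")
})

test_that("GA never loses to the best single taxon and is reproducible", {
  tab <- make_table(n_samples = 10, n_taxa = 12, lambda = 8, seed = 11)
  x <- seq_len(10)
  ga <- ga_params(population_size = 60, generations = 60, seed = 3)
  res <- eqo_search(tab, covariate = x, mode = "continuous", m = 4, ga = ga)
  best_single <- eqo_bruteforce(tab, covariate = x, mode = "continuous", m = 1)
  expect_gte(res$objective, best_single$objective - 1e-4)
  expect_false(is.unsorted(res$fitness_trajectory))  # elitism: non-decreasing

  res_u <- eqo_search(tab, mode = "uniform", m = 4, ga = ga)
  bs_u <- eqo_bruteforce(tab, mode = "uniform", m = 1)
  expect_lte(res_u$objective, bs_u$objective + 1e-4)

  # bit-for-bit reproducibility under a fixed seed
  res2 <- eqo_search(tab, covariate = x, mode = "continuous", m = 4, ga = ga)
  expect_identical(res, res2)

  expect_error(eqo_search(tab, covariate = x, m = 50), "exceeds")
  expect_error(eqo_search(tab, mode = "continuous"), "covariate")
})

test_that("GA matches exhaustive enumeration on small instances", {
  matches <- 0
  for (i in 1:20) {
    set.seed(200 + i)
    n_t <- sample(8:14, 1); m <- sample(2:4, 1)
    cnt <- matrix(rpois(10 * n_t, 8), 10, n_t,
                  dimnames = list(sprintf("s%02d", 1:10), sprintf("t%02d", 1:n_t)))
    cnt[rowSums(cnt) == 0, 1] <- 1L
    tab <- abundance_table(cnt)
    x <- rnorm(10)
    mode <- if (i %% 2 == 0) "continuous" else "uniform"
    bf <- eqo_bruteforce(tab, covariate = x, mode = mode, m = m)
    ga <- eqo_search(tab, covariate = x, mode = mode, m = m,
                     ga = ga_params(population_size = 100, generations = 100,
                                    seed = i))
    pen <- function(res) {
      raw <- if (mode == "continuous") res$objective else -res$objective
      raw - 1e-4 * length(res$member_taxa)
    }
    if (pen(ga) >= pen(bf) - 1e-9) matches <- matches + 1
  }
  expect_gte(matches, 19)
})
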