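test_that("taxon profiles normalize over samples or pooled states", {
  tab <- make_table(n_samples = 6, n_taxa = 4, seed = 3)
  p <- taxon_profile(tab, tab$taxon_ids[2])
  expect_equal(sum(p), 1)
  grouping <- rep(c("A", "B", "C"), each = 2)
  pg <- taxon_profile(tab, tab$taxon_ids[2], grouping)
  expect_equal(sum(pg), 1)
  expect_length(pg, 3)
  # indicator profile
  cnt <- make_counts(n_samples = 4, n_taxa = 3, seed = 4)
  cnt[, 1] <- c(0L, 0L, 5L, 0L)
  tab2 <- abundance_table(cnt)
  expect_equal(unname(taxon_profile(tab2, "t01")), c(0, 0, 1, 0))
  expect_error(taxon_profile(tab, "zz"), "unknown")
})

test_that("the empirical specificity statistic E behaves as a dispersion", {
  # all weight on samples with identical covariate values
  expect_equal(spec_empirical(c(0.5, 0.5, 0), c(2, 2, 9)), 0)
  # two-point uniform at distance 1
  expect_equal(spec_empirical(c(0.5, 0.5), c(0, 1)), 1)
  # translation invariance and linear scaling
  p <- c(0.2, 0.3, 0.1, 0.4); x <- c(0.3, 1.2, 2.5, 3.1)
  expect_equal(spec_empirical(p, x + 5), spec_empirical(p, x))
  expect_equal(spec_empirical(p, 3 * x), 3 * spec_empirical(p, x))
  # concentrated on one sample: defined as 0
  expect_equal(spec_empirical(c(1, 0, 0), x[1:3]), 0)
})

test_that("Spec flags planted small-fraction taxa and stays calibrated", {
  com <- generate_community(generator_config(seed = 2))
  sp <- spec_score(com$table, com$metadata, "size_mm", n_perm = 999, seed = 31)
  planted <- com$truth$sets$specific
  called <- sp$taxon_id[sp$label == "specific"]
  expect_gte(mean(planted %in% called), 0.9)
  fp <- setdiff(called, planted)
  expect_lte(length(fp) / max(1, length(called)), 0.1)
  # planted specific taxa sit well below the null mean
  expect_true(all(sp$spec[sp$taxon_id %in% planted] < -0.3))
  # permuting sample order consistently leaves Spec unchanged
  perm <- sample(nrow(com$table$counts))
  tab2 <- abundance_table(com$table$counts[perm, ])
  sp2 <- spec_score(tab2, com$metadata, "size_mm", n_perm = 99, seed = 7)
  sp1 <- spec_score(com$table, com$metadata, "size_mm", n_perm = 99, seed = 7)
  expect_equal(sp1$E, sp2$E[match(sp1$taxon_id, sp2$taxon_id)])
  expect_error(spec_score(com$table, com$metadata, "replicate"),
               NA)  # any numeric column is allowed
})

test_that("pairwise Spec correlations behave under duplication and negation", {
  com <- generate_community(generator_config(seed = 4))
  md <- com$metadata
  md$size_neg <- -md$size_mm
  md$size_dup <- md$size_mm
  sl <- lapply(c(size_mm = "size_mm", size_dup = "size_dup",
                 size_neg = "size_neg"), function(cv)
    spec_score(com$table, md, cv, n_perm = 99, seed = 5))
  R <- spec_pairwise_correlation(sl)
  expect_equal(R["size_mm", "size_dup"], 1)
  # distances are sign-invariant: negated covariate gives identical Spec
  expect_equal(R["size_mm", "size_neg"], 1)
  expect_error(spec_pairwise_correlation(sl[1]), ">= 2")
})

test_that("Levins' breadth closed forms and enumeration over rational vectors", {
  expect_equal(levins_breadth(rep(0.1, 10))$B, 10)
  expect_equal(levins_breadth(rep(0.1, 10))$BA, 1)
  expect_equal(levins_breadth(c(1, 0, 0))$B, 1)
  expect_equal(levins_breadth(c(1, 0, 0))$BA, 0)
  expect_equal(levins_breadth(c(0.5, 0.5, 0))$B, 2)
  # all 3-state rational vectors with denominator <= 6
  for (n in 2:6) {
    for (i in 0:n) for (j in 0:(n - i)) {
      k <- n - i - j
      p <- c(i, j, k) / n
      expect_equal(levins_breadth(p)$B, 1 / sum(p^2))
    }
  }
})

test_that("Hurlbert's breadth: availability weighting", {
  a <- c(0.5, 0.3, 0.2)
  expect_equal(hurlberts_breadth(a, a), 1)
  # all use in the scarcest state
  expect_equal(hurlberts_breadth(c(0, 0, 1), a), 0.2)
  # uniform availability reduces to Levins' B / N
  set.seed(8)
  for (i in 1:10) {
    p <- runif(6); p <- p / sum(p)
    expect_equal(hurlberts_breadth(p, rep(1 / 6, 6)),
                 levins_breadth(p)$B / 6)
  }
  expect_error(hurlberts_breadth(c(0.5, 0.5), c(1, 0)), "availability")
})

test_that("availability construction from a covariate is positive and normalized", {
  x <- c(0.1, 0.5, 2, 3.5)
  a <- availability_from_covariate(x)
  expect_equal(sum(a), 1)
  expect_true(all(a > 0))
  expect_equal(availability_from_covariate(rep(2, 4)), rep(0.25, 4))
})

test_that("generalist/specialist classification responds to profile shape", {
  com <- generate_community(generator_config(seed = 6))
  md <- com$metadata
  # a planted specialist (two distant home fractions) is called specialist
  sp_tax <- com$truth$sets$specialists[1]
  cb <- classify_breadth(com$table, sp_tax, grouping = md$fraction,
                         n_perm = 299, seed = 9)
  expect_equal(cb$classification, "specialist")
  expect_lt(cb$B, cb$null_lower)
  expect_true(cb$B >= 1 && cb$B <= 10)
})

test_that("association sign recovers planted monotone trends", {
  com <- generate_community(generator_config(seed = 7))
  md <- com$metadata
  sizes <- tapply(md$size_mm, md$fraction, mean)
  # the planted size ensemble's pooled profile rises with size
  mem <- com$truth$sets$ensemble_continuous
  tot <- tapply(rowSums(com$table$counts[, mem]), md$fraction, sum)
  p_mem <- as.numeric(tot / sum(tot))
  expect_equal(association_sign(p_mem, as.numeric(sizes),
                                n_perm = 499, seed = 3), "+")
  # a planted A-C-specific taxon declines
  spx <- com$truth$sets$specific[1]
  p_sp <- as.numeric(taxon_profile(com$table, spx, md$fraction))
  expect_equal(association_sign(p_sp, as.numeric(sizes), n_perm = 499, seed = 3), "-")
  expect_equal(association_sign(rep(0.1, 10), sizes), "0")
})

test_that("Levins' overlap is asymmetric with unit diagonal", {
  # two-state hand computation demonstrating asymmetry
  p1 <- c(0.5, 0.5); p2 <- c(1, 0)
  expect_equal(levins_overlap(p1, p2), 1)
  expect_equal(levins_overlap(p2, p1), 0.5)
  expect_equal(levins_overlap(p1, p1), 1)
  expect_equal(levins_overlap(c(1, 0), c(0, 1)), 0)

  tab <- make_table(n_samples = 6, n_taxa = 5, lambda = 9, seed = 12)
  LO <- overlap_matrix(tab, tab$taxon_ids[1:4])
  expect_equal(unname(diag(LO)), rep(1, 4))
  expect_true(all(LO >= 0))
  # brute-force double loop over states
  profs <- sapply(tab$taxon_ids[1:4], function(t) taxon_profile(tab, t))
  for (i in 1:4) for (j in 1:4) {
    acc <- 0
    for (s in seq_len(nrow(profs))) acc <- acc + profs[s, i] * profs[s, j]
    expect_equal(LO[i, j], acc / sum(profs[, i]^2))
  }
})

test_that("breadth_table aggregates calls across covariates", {
  com <- generate_community(generator_config(seed = 8))
  sub <- abundance_table(com$table$counts[, c(com$truth$sets$specialists[1:2],
                                              com$truth$sets$generalists[1:2],
                                              com$truth$sets$ensemble_continuous[1:2])])
  bt <- breadth_table(sub, com$metadata, covariates = c("size_mm", "density_kg_m3"),
                      n_perm = 199, seed = 13)
  expect_true(all(c("B", "BA", "classification", "hurlbert_size_mm",
                    "assoc_size_mm") %in% names(bt)))
  expect_true(all(bt$B >= 1 & bt$B <= 10))
  expect_true(all(bt$BA >= 0 & bt$BA <= 1))
})
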