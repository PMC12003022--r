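test_that("rarefaction subsamples without replacement to exact depth", {
  tab <- make_table(n_samples = 5, n_taxa = 8, lambda = 30, seed = 2)
  depth <- min(rowSums(tab$counts))
  r <- rarefy(tab, seed = 7)
  expect_true(all(rowSums(r$counts) == depth))
  expect_true(all(r$counts <= tab$counts))
  # exhaustive draw leaves the minimum-depth sample unchanged
  i <- which.min(rowSums(tab$counts))
  expect_equal(r$counts[i, ], tab$counts[i, ])
  expect_error(rarefy(tab, depth = max(rowSums(tab$counts)) + 1), "exceeds")
  # reproducible under seed
  expect_identical(rarefy(tab, seed = 7)$counts, r$counts)
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- c(a = 50L, b = 30L, c = 20L)
  m <- rbind(x = counts, y = counts)
  tab <- abundance_table(m)
  depth <- 40
  draws <- vapply(1:1000, function(s)
    rarefy(tab, depth = depth, seed = s)$counts["x", "a"], numeric(1))
  expected <- 50 * depth / 100
  se <- sqrt(depth * 0.5 * 0.5 * (100 - depth) / 99) / sqrt(1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("alpha diversity closed forms", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(pielou(c(5, 5, 5, 5)), 1)
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(pielou(c(10, 0, 0)), 0)
  expect_equal(richness(c(10, 0, 3)), 2)
  expect_equal(shannon(c(2, 1, 1)),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  expect_equal(shannon(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches hand computation and vegan", {
  m <- rbind(s1 = c(2, 1, 0), s2 = c(0, 1, 3))
  colnames(m) <- paste0("t", 1:3)
  d <- bray_curtis(abundance_table(m))
  expect_equal(d["s1", "s2"], 5 / 7)
  expect_equal(d["s1", "s1"], 0)
  disj <- rbind(s1 = c(4L, 0L), s2 = c(0L, 9L)); colnames(disj) <- c("t1", "t2")
  expect_equal(bray_curtis(abundance_table(disj))["s1", "s2"], 1)

  skip_if_not_installed("vegan")
  mm <- make_counts(n_samples = 6, n_taxa = 10, seed = 5)
  ours <- bray_curtis(abundance_table(mm))
  ref <- as.matrix(vegan::vegdist(mm[order(rownames(mm)), ]))
  expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("unweighted UniFrac: closed cases and brute-force equivalence", {
  tr <- three_tip_tree()
  m <- rbind(s1 = c(a = 3L, b = 0L, c = 0L), s2 = c(a = 1L, b = 0L, c = 2L),
             s3 = c(a = 3L, b = 0L, c = 0L))
  d <- unweighted_unifrac(abundance_table(m), tr)
  # identical presence sets
  expect_equal(d["s1", "s3"], 0)
  # {a} vs {a, c}: shared = a(1) + internal(1); unique = c(2); 2/4
  expect_equal(d["s1", "s2"], 0.5)
  # opposite sides of the root, no shared tips
  m2 <- rbind(s1 = c(a = 1L, b = 2L, c = 0L), s2 = c(a = 0L, b = 0L, c = 5L))
  expect_equal(unweighted_unifrac(abundance_table(m2), tr)["s1", "s2"], 1)

  expect_error(unweighted_unifrac(make_table(), tr), "missing tip")

  skip_if_not_installed("phyloseq")
  set.seed(14)
  for (i in 1:10) {
    nt <- sample(3:6, 1)
    tree <- ape::rcoal(nt, tip.label = paste0("t", seq_len(nt)))
    cnt <- matrix(rpois(4 * nt, 2), 4, nt,
                  dimnames = list(paste0("s", 1:4), tree$tip.label))
    cnt[rowSums(cnt) == 0, 1] <- 1L
    tab <- abundance_table(cnt)
    ours <- unweighted_unifrac(tab, tree)
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(tab$counts, taxa_are_rows = FALSE),
      phyloseq::phy_tree(tree))
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("NMDS recovers one-dimensional structure and respects k", {
  x <- seq(0, 1, length.out = 10)
  dm <- as.matrix(dist(cbind(x, 0)))
  dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
  dm <- granuleco:::distance_matrix(dm, "euclidean")
  fit2 <- nmds(dm, k = 2, seed = 3, restarts = 5)
  expect_lt(fit2$stress, 0.01)
  fit1 <- nmds(dm, k = 1, seed = 3, restarts = 5)
  expect_lte(fit2$stress, fit1$stress + 1e-8)  # stress non-increasing in k
  expect_error(nmds(dm, k = 10), "smaller")
})

test_that("PERMANOVA pseudo-F matches vegan and hand computation", {
  # hand-computable 2x2: within distances 0.2 and 0.4, all across = 1
  d <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(d) <- 0
  d["s1", "s2"] <- d["s2", "s1"] <- 0.2
  d["s3", "s4"] <- d["s4", "s3"] <- 0.4
  gr <- c("a", "a", "b", "b")
  # SST = (0.04 + 0.16 + 4)/4 = 1.05 ; SSW = 0.02 + 0.08 = 0.1 ; F = 0.95/0.05
  res <- permanova(granuleco:::distance_matrix(d, "custom"), gr,
                   n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f, 19)

  skip_if_not_installed("vegan")
  m <- make_counts(n_samples = 9, n_taxa = 12, seed = 8)
  dd <- bray_curtis(abundance_table(m))
  groups <- rep(c("a", "b", "c"), each = 3)
  ours <- permanova(dd, groups, n_perm = 199, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(dd) ~ groups, permutations = 199)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)

  # planted separation saturates significance at the permutation resolution:
  # two groups on disjoint taxon sets (16 samples so the chance of a random
  # permutation reproducing the original partition is negligible)
  m3 <- make_counts(n_samples = 16, n_taxa = 12, seed = 21)
  m3[1:8, 7:12] <- 0L; m3[9:16, 1:6] <- 0L
  m3[rowSums(m3) == 0, 1] <- 1L
  d2 <- bray_curtis(abundance_table(m3))
  g2 <- rep(c("a", "b"), each = 8)
  expect_equal(permanova(d2, g2, n_perm = 199, seed = 3)$p_value, 1 / 200)

  # consistent relabeling leaves F unchanged
  perm <- sample(9)
  expect_equal(permanova(dd[perm, perm], groups[perm], n_perm = 9, seed = 1)$pseudo_f,
               ours$pseudo_f)
  expect_error(permanova(dd, rep("a", 9)), "2 groups")
})

test_that("one-way ANOVA matches stats::lm and handles degeneracy", {
  v <- c(1.1, 2.3, 0.9, 3.2, 2.8, 3.9)
  g <- rep(c("a", "b"), each = 3)
  ours <- anova_oneway(v, g)
  ref <- anova(lm(v ~ g))
  expect_equal(ours$f, ref$`F value`[1])
  expect_equal(ours$p_value, ref$`Pr(>F)`[1])
  expect_error(anova_oneway(rep(1, 6), g), "degenerate")
  # vanishing within-variance: p tends to 0
  expect_lt(anova_oneway(c(0, 1e-9, 1, 1 + 1e-9), c("a", "a", "b", "b"))$p_value,
            1e-6)
})

test_that("planted archaeal proportion trend is detected", {
  com <- generate_community(generator_config(seed = 5))
  tr <- domain_proportion_trend(com$table, com$taxonomy, com$metadata)
  expect_gt(tr$slope, 0)
  expect_lt(tr$slope_p, 0.001)
  expect_lt(tr$anova_p, 0.001)
  expect_error(
    domain_proportion_trend(com$table, com$taxonomy, com$metadata,
                            covariate = "nope"), "absent")
})
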