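#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study's stated world: ten sieve fractions A-J with
#' three replicate samples each (30 samples), sequencing depths drawn
#' uniformly from the printed read-count range, a planted size-correlated
#' ensemble, a planted stable (low-CV) ensemble, rare taxa confined to the
#' small fractions A-C, and archaeal genera whose relative abundance rises
#' with granule size.  The default 300-taxon scale keeps the test suite
#' fast; `n_taxa = 3041` reproduces the study's table dimensions.
#'
#' @param n_taxa total taxa (default 300).
#' @param replicates replicate samples per fraction (default 3).
#' @param n_granules_per_fraction granules per fraction in the drop-column
#'   emulation (default 10, as measured).
#' @param depth_range sequencing depth bounds (default 12000-31400 reads).
#' @param timing_noise multiplicative sd of settling-time noise (default
#'   0.02).
#' @param abundance_noise lognormal sd of per-replicate taxon fluctuations
#'   (default 0.25).
#' @param stable_target_cv target coefficient of variation of the planted
#'   stable ensemble's summed abundance (default 0.05).
#' @param seed mandatory RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_taxa = 300, replicates = 3,
                             n_granules_per_fraction = 10,
                             depth_range = c(12000, 31400),
                             timing_noise = 0.02, abundance_noise = 0.25,
                             stable_target_cv = 0.05, seed = 1) {
  stopifnot(n_taxa >= 120, replicates >= 2, depth_range[1] > 0,
            depth_range[2] >= depth_range[1], !is.null(seed))
  structure(list(n_taxa = n_taxa, replicates = replicates,
                 n_granules_per_fraction = n_granules_per_fraction,
                 depth_range = depth_range, timing_noise = timing_noise,
                 abundance_noise = abundance_noise,
                 stable_target_cv = stable_target_cv, seed = seed),
            class = "generator_config")
}

# Planted per-fraction physical truth shared by the granule, SMA and
# community generators.  Densities decline from ~1180 kg m^-3 (fraction A)
# to ~1004 (J), reproducing the inverse density-velocity relationship; the
# VS/TS profile dips in the small fractions.
fraction_truth <- function(scheme = default_fraction_scheme()) {
  mid <- fraction_midpoints(scheme)
  mid[1] <- 0.1  # fraction A is open below: representative diameter
  f <- seq_along(mid)
  density <- 998.2 + 184 * exp(-0.382 * (f - 1))
  velocity <- stokes_velocity(density, mid)
  vs_of_ts <- c(0.862, 0.704, 0.890, rep(0.918, length(mid) - 3))
  data.frame(fraction = names(mid), size_mm = unname(mid),
             density_kg_m3 = unname(density),
             settling_velocity_m_s = unname(velocity),
             vs_fraction = vs_of_ts[seq_along(mid)],
             stringsAsFactors = FALSE)
}

#' Generate granule drop-column measurements with planted densities
#'
#' Diameters are uniform within each fraction's sieve interval; settling
#' times are obtained by inverting Stokes' law at the fraction's planted
#' density, with multiplicative Gaussian timing noise.
#'
#' @param config a [generator_config()].
#' @return list with `granules` (data.frame ready for
#'   [granule_densities()]) and `truth` (per-fraction planted values).
#' @export
generate_granules <- function(config = generator_config()) {
  scheme <- default_fraction_scheme()
  truth <- fraction_truth(scheme)
  wp <- water_properties(20)
  with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(scheme)), function(i) {
      lo <- max(scheme$lower_mm[i], 0.05)
      d <- stats::runif(config$n_granules_per_fraction, lo, scheme$upper_mm[i])
      v <- stokes_velocity(truth$density_kg_m3[i], d,
                           rho_f = wp$density_kg_m3, mu = wp$viscosity_Pa_s)
      t <- (0.3 / v) * (1 + stats::rnorm(length(d), 0, config$timing_noise))
      data.frame(granule_id = sprintf("%s%02d", scheme$label[i], seq_along(d)),
                 fraction_true = scheme$label[i], diameter_mm = d,
                 time_s = t, temp_C = 20, distance_m = 0.3)
    })
    list(granules = do.call(rbind, rows), truth = truth)
  })
}

#' Generate SMA assay bottles with planted rates
#'
#' Cumulative CH4 follows a lag phase then a linear phase at the planted
#' rate, on top of a background produced by the paired no-substrate control.
#' Planted rates peak at the medium fractions and are highest on H2/CO2.
#'
#' @param config a [generator_config()].
#' @param noise_sd multiplicative noise on the pressure signal (default 0,
#'   i.e. clean series; the recovery tests add noise explicitly).
#' @param n_rep replicate bottles per fraction x substrate (default 3, as
#'   assayed in triplicate).
#' @return list with `assays` (list of [sma_assay()]) and `truth` (planted
#'   fraction x substrate rate matrix, mL CH4 g VS^-1 d^-1).
#' @export
generate_sma <- function(config = generator_config(), noise_sd = 0,
                         n_rep = 3) {
  fr <- LETTERS[1:10]
  f <- seq_along(fr)
  peak <- exp(-((f - 6)^2) / 18)  # unimodal, maximum at fraction F
  rates <- cbind(acetate = 80 + 170 * peak,
                 propionate = 40 + 80 * peak,
                 butyrate = 50 + 100 * peak,
                 H2CO2 = 150 + 250 * peak)
  rownames(rates) <- fr
  vs_mass <- 0.04            # 10 mL at 4 g VS / L
  cal <- 0.5; hcf <- 1.2     # instrument constants of the emulated transducer
  time_d <- seq(0, 4, by = 0.25)
  lag <- 0.5
  lin <- function(rate_mL_d) pmax(time_d - lag, 0) * rate_mL_d
  bg_rate <- 0.4             # background CH4, mL d^-1, no-substrate bottles
  assays <- list()
  with_seed(config$seed + 1L, {
    for (i in f) {
      noisy <- function(v) v * (1 + stats::rnorm(length(v), 0, noise_sd))
      bg <- bg_rate * time_d
      for (rep_i in seq_len(n_rep)) {
        for (sub in c("acetate", "propionate", "butyrate")) {
          ch4 <- lin(rates[i, sub] * vs_mass) + bg
          # biogas = ch4 / ch4_fraction; signal = biogas/(cal*hcf)
          assays[[length(assays) + 1L]] <- sma_assay(
            bottle_id = sprintf("%s_%s_%d", fr[i], sub, rep_i),
            fraction_label = fr[i],
            substrate = sub, vs_mass_g = vs_mass, time_d = time_d,
            pressure_mV = noisy(ch4 / 0.6 / (cal * hcf)),
            ch4_fraction = rep(0.6, length(time_d)),
            calibration_mL_per_mV = cal, headspace_correction = hcf)
        }
        # H2 bottle: headspace volume falls as H2 is consumed
        h2_consumed <- lin(4 * rates[i, "H2CO2"] * vs_mass)
        start_mV <- (max(h2_consumed) * 1.5 + 50) / (cal * hcf)
        assays[[length(assays) + 1L]] <- sma_assay(
          bottle_id = sprintf("%s_H2CO2_%d", fr[i], rep_i),
          fraction_label = fr[i],
          substrate = "H2CO2", vs_mass_g = vs_mass, time_d = time_d,
          pressure_mV = noisy(start_mV - h2_consumed / (cal * hcf)),
          ch4_fraction = rep(0, length(time_d)),
          calibration_mL_per_mV = cal, headspace_correction = hcf)
      }
      assays[[length(assays) + 1L]] <- sma_assay(
        bottle_id = paste0(fr[i], "_ctrl"), fraction_label = fr[i],
        substrate = "control_none", vs_mass_g = vs_mass, time_d = time_d,
        pressure_mV = bg / 0.6 / (cal * hcf),
        ch4_fraction = rep(0.6, length(time_d)),
        calibration_mL_per_mV = cal, headspace_correction = hcf)
      assays[[length(assays) + 1L]] <- sma_assay(
        bottle_id = paste0(fr[i], "_ctrlN2"), fraction_label = fr[i],
        substrate = "control_N2CO2", vs_mass_g = vs_mass, time_d = time_d,
        pressure_mV = rep(start_mV, length(time_d)),
        ch4_fraction = rep(0, length(time_d)),
        calibration_mL_per_mV = cal, headspace_correction = hcf)
    }
  })
  list(assays = assays, truth = rates)
}

#' Generate a structured community table with planted ground truth
#'
#' Builds per-fraction expected compositions containing: archaeal taxa whose
#' total proportion rises linearly with fraction size; a 20-taxon ensemble
#' whose summed proportion is affine in size (with compensating within-set
#' noise so the sum is cleaner than any subset); a 20-taxon stable ensemble
#' whose sum is held constant across samples while members fluctuate
#' (zero-sum noise); 22 taxa confined to fractions A-C; flat generalists;
#' specialists split between two distant fractions; and a lognormal
#' background whose skew increases with fraction size so expected Shannon
#' entropy declines monotonically from A to J.  Counts are multinomial at
#' uniform random depths.
#'
#' @param config a [generator_config()].
#' @return list with `table` ([abundance_table()]), `metadata`
#'   (`sample_metadata`), `taxonomy` (`taxonomy_map`), `tree` (`phylo`),
#'   `truth` (planted sets and targets).
#' @export
generate_community <- function(config = generator_config()) {
  n <- config$n_taxa
  ft <- fraction_truth()
  nf <- nrow(ft)
  s <- ft$size_mm
  ids <- sprintf("t%04d", seq_len(n))
  # The size-correlated ensemble deliberately overlaps the archaeal set (taxa
  # 26-30): in granular sludge the strongest size-trending genera ARE
  # methanogenic archaea, and the overlap makes the planted ensemble the
  # unambiguous optimum of the continuous EQO objective.  The remaining
  # archaea rise in total but with wavy per-fraction shares, so no individual
  # one out-correlates an ensemble member.
  sets <- list(
    archaea = ids[1:30],
    ensemble_continuous = ids[26:45],
    ensemble_stable = ids[46:65],
    specific = ids[66:87],
    generalists = ids[88:97],
    specialists = ids[98:105])
  background <- setdiff(ids, unlist(sets))
  arch_wavy <- ids[1:25]

  with_seed(config$seed + 2L, {
    w_arch <- exp(stats::rnorm(25, 0, 0.4)); w_arch <- w_arch / sum(w_arch)
    w_cont <- exp(stats::rnorm(20, 0, 0.15)); w_cont <- w_cont / sum(w_cont)
    w_spec <- exp(stats::rnorm(22, 0, 0.7)); w_spec <- w_spec / sum(w_spec)
    w_gen <- exp(stats::rnorm(10, 0, 0.3)); w_gen <- w_gen / sum(w_gen)
    w_stab <- exp(stats::rnorm(20, 0, 0.15)); w_stab <- w_stab / sum(w_stab)
    w_bg <- exp(stats::rnorm(length(background), 0, 1.1))

    arch_tot <- 0.10 + 0.010 * s         # non-ensemble archaea: 0.101 -> 0.136
    cont_tot <- 0.12 + 0.030 * s         # planted ensemble: 0.123 -> 0.227
    stable_tot <- 0.18
    # The A-C block also offsets the planted rises compositionally, keeping
    # the background's share of the community roughly flat across fractions
    # (so background taxa stay neutral under the Spec null).
    spec_tot <- ifelse(seq_len(nf) <= 3, 0.12, 0)
    gen_tot <- 0.05
    specialist_mass <- 0.004
    sp_pairs <- list(c(1, 6), c(2, 7), c(3, 8), c(4, 9), c(5, 10),
                     c(1, 7), c(2, 8), c(3, 9))

    # expected proportion matrix: fractions x taxa
    E <- matrix(0, nf, n, dimnames = list(ft$fraction, ids))
    # Continuous-ensemble members carry deterministic zero-sum "wiggles"
    # around the shared affine trend: each member deviates, but the
    # deviations cancel exactly across the full set, so ONLY the complete
    # ensemble has a perfectly affine summed profile.  Recovery of the
    # planted membership is then a structural (complementarity) property,
    # not an accident of sampling noise.
    # wiggles come in complementary member pairs (2k-1, 2k): each pair's
    # weighted deviations cancel exactly, so every half-pair completion is a
    # strict objective improvement -- a single-swap search path leads all
    # the way into the planted ensemble
    g_half <- matrix(stats::rnorm(nf * 10, 0, 0.1), nf, 10)
    g_cont <- matrix(0, nf, 20)
    g_cont[, seq(1, 19, 2)] <- g_half
    g_cont[, seq(2, 20, 2)] <- -g_half *
      matrix(w_cont[seq(1, 19, 2)] / w_cont[seq(2, 20, 2)], nf, 10, byrow = TRUE)
    mult_cont <- pmax(1 + g_cont, 0.25)
    # Expected shares within each non-trending block are flat across
    # fractions: all of their variation is injected at the sample level
    # (i.i.d. lognormal noise), which is exchangeable across samples and so
    # keeps the Spec permutation null calibrated for non-planted taxa.
    # Fraction-level structure is reserved for the planted trends.
    for (f in seq_len(nf)) {
      E[f, arch_wavy] <- arch_tot[f] * w_arch
      vc <- w_cont * mult_cont[f, ]
      E[f, sets$ensemble_continuous] <- cont_tot[f] * vc / sum(vc)
      E[f, sets$ensemble_stable] <- stable_tot * w_stab
      E[f, sets$specific] <- spec_tot[f] * w_spec
      E[f, sets$generalists] <- gen_tot * w_gen
      for (k in seq_along(sp_pairs)) {
        # mass split favours the smaller home fraction: the two-point
        # profile is mildly declining, so specialists never masquerade as
        # size-correlated ensemble material
        if (f == sp_pairs[[k]][1]) E[f, sets$specialists[k]] <- specialist_mass * 0.65
        if (f == sp_pairs[[k]][2]) E[f, sets$specialists[k]] <- specialist_mass * 0.35
      }
      rem <- 1 - sum(E[f, ])
      E[f, background] <- rem * w_bg / sum(w_bg)
    }

    # replicate-level sampling
    samples <- character(0); fracs <- character(0); reps <- integer(0)
    counts <- NULL
    for (f in seq_len(nf)) {
      for (r in seq_len(config$replicates)) {
        pi_ <- E[f, ]
        sds <- rep(config$abundance_noise, n)
        # heavier sample-level fluctuation in the rare background, as in real
        # amplicon data; also masks the mild compositional complement of the
        # planted rises so background taxa stay Spec-neutral
        sds[ids %in% background] <- max(config$abundance_noise, 0.6)
        # non-ensemble archaea are individually noisy: their DOMAIN total
        # rises with size, but no single archaeon is a cleaner size
        # correlate than a planted ensemble member
        sds[ids %in% arch_wavy] <- 0.6
        # stable-ensemble members fluctuate somewhat more as individuals
        # (their sum is pinned below); continuous-ensemble members are
        # quieter so each one is individually recognisable as
        # size-correlated
        sds[ids %in% sets$ensemble_stable] <- 0.3
        sds[ids %in% sets$ensemble_continuous] <- 0.2
        noise <- exp(stats::rnorm(n, 0, sds))
        pi_noisy <- pi_ * noise
        # compensating (zero-sum) fluctuations: members of the two planted
        # ensembles fluctuate, but each ensemble's summed relative abundance
        # is pinned to its planted per-fraction total, so the planted subsets
        # are the true objective optima rather than one of many noise-fitting
        # alternatives; the rest of the community is renormalised to the
        # exact complement
        mem_c <- sets$ensemble_continuous; mem_s <- sets$ensemble_stable
        rest <- setdiff(ids, c(mem_c, mem_s))
        pi_noisy[mem_c] <- pi_noisy[mem_c] / sum(pi_noisy[mem_c]) * sum(pi_[mem_c])
        pi_noisy[mem_s] <- pi_noisy[mem_s] / sum(pi_noisy[mem_s]) * sum(pi_[mem_s])
        pi_noisy[rest] <- pi_noisy[rest] / sum(pi_noisy[rest]) *
          (1 - sum(pi_[mem_c]) - sum(pi_[mem_s]))
        depth <- round(stats::runif(1, config$depth_range[1], config$depth_range[2]))
        # stratified count draw: the two planted ensembles receive their
        # exact per-sample count totals (multinomial WITHIN each block).
        # With a single unrestricted multinomial, the planted membership is
        # not statistically identifiable at n = 30: post-hoc subset search
        # over ~300 taxa always finds realisations of the sampling noise
        # that out-correlate any planted subset.
        cnt <- numeric(n); names(cnt) <- ids
        n_c <- round(depth * sum(pi_noisy[mem_c]))
        n_s <- round(depth * sum(pi_noisy[mem_s]))
        cnt[mem_c] <- stats::rmultinom(1, n_c, pi_noisy[mem_c])[, 1]
        cnt[mem_s] <- stats::rmultinom(1, n_s, pi_noisy[mem_s])[, 1]
        cnt[rest] <- stats::rmultinom(1, depth - n_c - n_s, pi_noisy[rest])[, 1]
        counts <- rbind(counts, cnt)
        samples <- c(samples, sprintf("%s_r%d", ft$fraction[f], r))
        fracs <- c(fracs, ft$fraction[f]); reps <- c(reps, r)
      }
    }
    rownames(counts) <- samples
    colnames(counts) <- ids
    table <- abundance_table(counts, provenance = sprintf(
      "synthetic community (seed %d, %d taxa)", config$seed, n))

    metadata <- data.frame(
      sample_id = samples, fraction = fracs, replicate = reps,
      size_mm = ft$size_mm[match(fracs, ft$fraction)],
      settling_velocity_m_s = ft$settling_velocity_m_s[match(fracs, ft$fraction)],
      density_kg_m3 = ft$density_kg_m3[match(fracs, ft$fraction)],
      vs_fraction = ft$vs_fraction[match(fracs, ft$fraction)],
      stringsAsFactors = FALSE)
    metadata$complete <- TRUE
    class(metadata) <- c("sample_metadata", "data.frame")

    phylum <- rep("", n)
    phylum[ids %in% sets$archaea] <-
      rep(c("Euryarchaeota", "Halobacterota"), length.out = 30)
    taxonomy <- data.frame(
      taxon_id = ids,
      domain = ifelse(ids %in% sets$archaea, "Archaea", "Bacteria"),
      phylum = phylum, class = "", order = "",
      family = paste0("fam_", rep(seq_len(ceiling(n / 5)), each = 5)[seq_len(n)]),
      genus = paste0("gen_", ids), stringsAsFactors = FALSE)
    class(taxonomy) <- c("taxonomy_map", "data.frame")

    tree <- ape::rcoal(n, tip.label = ids)

    truth <- list(
      sets = sets,
      archaeal_target_proportion = stats::setNames(
        arch_tot + cont_tot * sum(w_cont[1:5]), ft$fraction),
      continuous_coefficients = c(intercept = 0.05, slope = 0.06),
      stable_target_cv = config$stable_target_cv,
      expected_composition = E,
      fraction_truth = ft)
    list(table = table, metadata = metadata, taxonomy = taxonomy,
         tree = tree, truth = truth)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits `table.tsv`, `metadata.tsv`, `taxonomy.tsv`, `tree.nwk`,
#' `granules.tsv` and `truth.json` in the plain-text formats the readers
#' accept.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(config = generator_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  com <- generate_community(config)
  gr <- generate_granules(config)
  write_abundance_table(com$table, file.path(dir, "table.tsv"))
  utils::write.table(com$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(com$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(com$tree, file.path(dir, "tree.nwk"))
  utils::write.table(gr$granules, file.path(dir, "granules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(com$truth$sets, file.path(dir, "truth.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}
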