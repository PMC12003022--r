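#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; stage seeds are derived from it deterministically.
#' @param simulate `TRUE` to generate synthetic inputs (default), or a list of
#'   [generator_config()] arguments; `FALSE` requires `inputs` paths.
#' @param inputs list of paths: `table`, `metadata`, `taxonomy`, `tree`,
#'   optionally `granules`.
#' @param n_perm permutations for PERMANOVA/Spec/breadth stages.
#' @param ga_population,ga_generations GA hyperparameters for EQO.
#' @param m EQO ensemble size budget.
#' @param alpha significance level used in calls.
#' @param covariates covariate columns scored by the niche stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE, inputs = NULL,
                            n_perm = 999, ga_population = 200,
                            ga_generations = 500, m = 20, alpha = 0.05,
                            covariates = c("size_mm", "settling_velocity_m_s",
                                           "density_kg_m3", "vs_fraction")) {
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 inputs = inputs, n_perm = n_perm,
                 ga_population = ga_population,
                 ga_generations = ga_generations, m = m, alpha = alpha,
                 covariates = covariates),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> physchem -> diversity -> EQO -> niche
#' statistics in dependency order, writes per-stage TSV outputs plus a
#' machine-readable `summary.json` in `out_dir`.  Every stochastic stage's
#' seed is recorded in the summary; reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()] (or a path to a JSON file of its
#'   fields).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cfg)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(...) warnings_seen <<- c(warnings_seen, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  data <- stage("inputs", {
    if (isTRUE(config$simulate) || is.list(config$simulate)) {
      gc_args <- if (is.list(config$simulate)) config$simulate else list()
      gc_args$seed <- config$seed
      gcfg <- do.call(generator_config, gc_args)
      com <- generate_community(gcfg)
      com$granules <- generate_granules(gcfg)$granules
      com
    } else {
      if (is.null(config$inputs))
        stop("simulate = FALSE requires input paths")
      md <- read_metadata(config$inputs$metadata)
      tab <- read_abundance_table(config$inputs$table,
                                  sample_hint = md$sample_id)
      tax <- read_taxonomy(config$inputs$taxonomy)
      tr <- if (!is.null(config$inputs$tree)) read_tree(config$inputs$tree)
      gr <- if (!is.null(config$inputs$granules))
        utils::read.table(config$inputs$granules, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      list(table = tab, metadata = md, taxonomy = tax, tree = tr,
           granules = gr, truth = NULL)
    }
  })
  stage("validation", {
    validate_inputs(data$table, data$metadata, data$taxonomy, data$tree)
    missing_cov <- setdiff(config$covariates, names(data$metadata))
    if (length(missing_cov))
      stop("covariate(s) required by the niche stage absent from metadata: ",
           paste(missing_cov, collapse = ", "))
  })
  md <- join_metadata(data$table, data$metadata)

  # --- physchem -----------------------------------------------------------
  phys <- NULL
  if (!is.null(data$granules)) {
    phys <- stage("physchem", granule_densities(data$granules))
    if (any(!phys$laminar))
      note("physchem: %d granule(s) outside the laminar Stokes regime (Re > 1)",
           sum(!phys$laminar))
    write_tsv(phys, file.path(config$out_dir, "densities.tsv"))
  }

  # --- diversity ----------------------------------------------------------
  alpha_seed <- config$seed + 101L
  alpha <- stage("alpha_diversity",
                 alpha_diversity(data$table, seed = alpha_seed))
  write_tsv(alpha, file.path(config$out_dir, "alpha.tsv"))
  alpha_tests <- lapply(c(richness = "richness", shannon = "shannon",
                          pielou = "pielou"), function(mv) {
    av <- anova_oneway(alpha[[mv]], md$fraction)
    fit <- stats::lm(alpha[[mv]] ~ md$size_mm)
    list(anova_f = av$f, anova_p = av$p_value,
         slope = unname(stats::coef(fit)[2]),
         slope_p = summary(fit)$coefficients[2, 4])
  })

  rt <- rarefy(data$table, seed = alpha_seed)
  bc <- stage("bray_curtis", bray_curtis(rt))
  write_square_tsv(bc, file.path(config$out_dir, "bray_curtis.tsv"))
  perm_bc <- permanova(bc, md$fraction, n_perm = config$n_perm,
                       seed = config$seed + 102L)
  uf <- NULL; perm_uf <- NULL
  if (!is.null(data$tree)) {
    uf <- stage("unifrac", unweighted_unifrac(rt, data$tree))
    write_square_tsv(uf, file.path(config$out_dir, "unifrac.tsv"))
    perm_uf <- permanova(uf, md$fraction, n_perm = config$n_perm,
                         seed = config$seed + 103L)
  }
  ord <- nmds(bc, k = 2, seed = config$seed + 104L)
  write_square_tsv(ord$points, file.path(config$out_dir, "nmds.tsv"))

  arch_trend <- stage("archaeal_trend",
    domain_proportion_trend(data$table, data$taxonomy, data$metadata,
                            covariate = "size_mm", domain = "Archaea"))

  # --- EQO ----------------------------------------------------------------
  ga <- ga_params(population_size = config$ga_population,
                  generations = config$ga_generations,
                  seed = config$seed + 105L)
  eqo_cont <- stage("eqo_continuous",
    eqo_search(data$table, covariate = md$size_mm, mode = "continuous",
               m = config$m, ga = ga))
  eqo_unif <- stage("eqo_uniform",
    eqo_search(data$table, mode = "uniform", m = config$m, ga = ga))

  # --- niche statistics ---------------------------------------------------
  spec_list <- list()
  for (i in seq_along(config$covariates)) {
    cv <- config$covariates[i]
    spec_list[[cv]] <- stage(paste0("spec_", cv),
      spec_score(data$table, data$metadata, covariate = cv,
                 n_perm = config$n_perm, seed = config$seed + 110L + i,
                 alpha = config$alpha))
  }
  spec_all <- do.call(rbind, spec_list)
  write_tsv(spec_all, file.path(config$out_dir, "spec.tsv"))
  spec_R <- if (length(spec_list) >= 2) spec_pairwise_correlation(spec_list)

  breadth <- stage("breadth",
    breadth_table(data$table, data$metadata, covariates = config$covariates,
                  n_perm = config$n_perm, seed = config$seed + 120L))
  write_tsv(breadth, file.path(config$out_dir, "breadth.tsv"))
  gen_spec <- breadth$taxon_id[breadth$classification != "neither"]
  overlap_taxa <- if (length(gen_spec) >= 2) gen_spec else
    data$table$taxon_ids[order(colSums(data$table$counts),
                               decreasing = TRUE)][1:10]
  LO <- overlap_matrix(data$table, overlap_taxa, grouping = md$fraction)
  write_square_tsv(LO, file.path(config$out_dir, "overlap.tsv"))

  # --- summary ------------------------------------------------------------
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    parameters = list(n_perm = config$n_perm, m = config$m,
                      alpha = config$alpha,
                      ga = list(population = config$ga_population,
                                generations = config$ga_generations),
                      rarefaction_seed = alpha_seed),
    alpha_diversity = alpha_tests,
    permanova = list(
      bray_curtis = perm_bc,
      unifrac = perm_uf),
    nmds_stress = ord$stress,
    eqo = list(
      continuous = list(members = eqo_cont$member_taxa,
                        objective = eqo_cont$objective,
                        seed = eqo_cont$seed),
      uniform = list(members = eqo_unif$member_taxa,
                     objective = eqo_unif$objective,
                     seed = eqo_unif$seed)),
    specific_taxa = lapply(spec_list, function(s)
      s$taxon_id[s$label == "specific"]),
    spec_pairwise_R = spec_R,
    generalists = breadth$taxon_id[breadth$classification == "generalist"],
    specialists = breadth$taxon_id[breadth$classification == "specialist"],
    overlap_taxa = overlap_taxa,
    archaeal_trend = arch_trend[c("slope", "slope_p", "anova_f", "anova_p")],
    physchem = if (!is.null(phys))
      list(mean_density_by_fraction = as.list(round(
        tapply(phys$density_kg_m3, phys$fraction, mean), 6))),
    warnings = warnings_seen)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
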