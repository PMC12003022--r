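# Small fixtures built in code; all tests use fixed seeds.

make_counts <- function(n_samples = 4, n_taxa = 6, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%02d", seq_len(n_taxa))))
  m[rowSums(m) == 0, 1] <- 1L
  m
}

make_table <- function(...) abundance_table(make_counts(...))

three_tip_tree <- function() {
  ape::read.tree(text = "((a:1,b:1):1,c:2);")
}

# metadata for the 30-sample A-J x 3 design with the four covariates
make_metadata <- function() {
  ft <- granuleco:::fraction_truth()
  md <- do.call(rbind, lapply(seq_len(10), function(f)
    data.frame(sample_id = sprintf("%s_r%d", ft$fraction[f], 1:3),
               fraction = ft$fraction[f], replicate = 1:3,
               size_mm = ft$size_mm[f],
               settling_velocity_m_s = ft$settling_velocity_m_s[f],
               density_kg_m3 = ft$density_kg_m3[f],
               vs_fraction = ft$vs_fraction[f])))
  md$complete <- TRUE
  class(md) <- c("sample_metadata", "data.frame")
  md
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
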