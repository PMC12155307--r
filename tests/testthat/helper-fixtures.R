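# Small cohorts used across test files. All fixtures are generated in code;
# nothing is read from disk except what the tests themselves write.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 30L, n_chromosomes = 3L, sites_per_chromosome = 80L,
         deleterious_fraction = 0.05, seed = 42L),
    list(...)
  )
  do.call(simulation_config, args)
}

small_bundle <- function(...) simulate_cohort(small_config(...))

# hand-built cohort: explicit genotypes, one chromosome
manual_cohort <- function(geno, qual = NULL, depth = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  sites <- data.frame(
    chrom = rep("chr01", m), pos = seq_len(m) * 10L,
    ref = rep("A", m), alt = rep("G", m),
    qual = if (is.null(qual)) rep(50, m) else qual,
    stringsAsFactors = FALSE
  )
  genotype_cohort(sites, sprintf("S%02d", seq_len(nrow(geno))), geno,
                  depth)
}

# brute-force site pi: enumerate all chromosome pairs and count differences
site_pi_bruteforce <- function(g) {
  alleles <- unlist(lapply(g[g != -1L], function(x) {
    switch(as.character(x), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  }))
  pairs <- utils::combn(length(alleles), 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}
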