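test_that("sub-threshold depth masks a genotype and zero tolerance drops the site", {
  g <- rbind(c(0L, 2L), c(1L, 0L))
  depth <- rbind(c(9L, 30L), c(30L, 30L))
  co <- manual_cohort(g, depth = depth)
  out <- apply_quality_filters(co, filter_config())
  expect_identical(ncol(out$geno), 1L)  # site 1 dropped via masking
  expect_identical(out$sites$pos, 20L)
  log <- attr(out, "filter_log")
  expect_identical(log$genotypes_masked_low_dp, 1L)
  expect_identical(log$sites_removed_missing, 1L)
})

test_that("clean cohorts pass filters unchanged and filtering is idempotent", {
  b <- small_bundle()
  once <- apply_quality_filters(b$cohort, filter_config())
  expect_identical(once$geno, b$cohort$geno)
  twice <- apply_quality_filters(once, filter_config())
  expect_identical(twice$geno, once$geno)
  expect_identical(twice$sites, once$sites)
})

test_that("low QUAL sites and planted sub-threshold depths are removed as counted", {
  b <- small_bundle()
  co <- b$cohort
  # sabotage: known low-QUAL sites and known low-depth genotypes
  set.seed(1)
  bad_qual <- sample(ncol(co$geno), 10)
  co$sites$qual[bad_qual] <- 5
  bad_dp <- setdiff(sample(ncol(co$geno), 15), bad_qual)
  co$depth[1, bad_dp] <- 3L
  out <- apply_quality_filters(co, filter_config())
  expect_identical(ncol(out$geno),
                   ncol(co$geno) - length(bad_qual) - length(bad_dp))
  expect_false(any(out$sites$pos %in% co$sites$pos[c(bad_qual, bad_dp)]))
})

test_that("severity bands partition (0, Inf) with a closed middle band", {
  expect_identical(as.character(classify_severity(c(0.5, 1, 2, 3, 3.0001, 9))),
                   c("weak", "mild", "mild", "mild", "high", "high"))
  expect_error(classify_severity(0), "RS > 0")
  expect_error(classify_severity(-1), "RS > 0")
})

test_that("the combined SIFT+RS rule admits and excludes sites correctly", {
  g <- rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  co <- manual_cohort(g)
  ann <- data.frame(
    chrom = "chr01", pos = c(10L, 20L, 30L, 40L),
    ref = "A", alt = "G",
    consequence = "missense_variant",
    sift_score = c(0.04, 0.04, 0.04, 0.06),
    sift_confidence = c("high", "low", "high", "high"),
    gene_id = "g1", stringsAsFactors = FALSE
  )
  track <- data.frame(chrom = "chr01", pos = c(10L, 20L, 40L),
                      rs = c(0.5, 2, 4))  # pos 30 absent: no RS evidence
  class(track) <- c("rs_track", "data.frame")

  catg <- identify_dsnps(co, ann, track, filter_config())
  expect_identical(catg$pos, 10L)  # low-conf, missing-RS, tolerated all out
  expect_identical(as.character(catg$severity), "weak")

  # admitting low-confidence calls brings site 20 in
  catg2 <- identify_dsnps(co, ann, track,
                          filter_config(exclude_low_confidence = FALSE))
  expect_identical(catg2$pos, c(10L, 20L))

  # strict comparison excludes sift == threshold
  ann$sift_score[1] <- 0.05
  cat_incl <- identify_dsnps(co, ann, track, filter_config())
  cat_strict <- identify_dsnps(co, ann, track,
                               filter_config(sift_inclusive = FALSE))
  expect_identical(cat_incl$pos, 10L)
  expect_identical(nrow(cat_strict), 0L)
})

test_that("catalog equals the generator's truth list exactly", {
  b <- small_bundle(seed = 3L)
  catg <- identify_dsnps(b$cohort, b$annotations, b$track, filter_config())
  expect_identical(attr(catg, "site_index"), b$truth$deleterious_sites)
})

test_that("empty annotation join advises about key mismatch", {
  b <- small_bundle()
  ann <- b$annotations
  ann$chrom <- paste0("X", ann$chrom)
  expect_error(identify_dsnps(b$cohort, ann, b$track, filter_config()),
               "annotation join is empty")
})

test_that("deleterious allele frequency counts alt alleles over 2n", {
  co <- manual_cohort(matrix(2L, nrow = 4, ncol = 1))
  catalog <- data.frame(chrom = "chr01", pos = 10L, ref = "A", alt = "G")
  fr <- deleterious_allele_frequency(co, catalog)
  expect_identical(fr$dfreq, 1)
  expect_true(fr$fixed)

  g <- matrix(0L, nrow = 10, ncol = 1); g[1, 1] <- 1L
  fr2 <- deleterious_allele_frequency(manual_cohort(g), catalog)
  expect_identical(fr2$dfreq, 0.05)  # 1 of 20 chromosomes
  expect_false(fr2$fixed)

  g[2, 1] <- -1L
  expect_error(deleterious_allele_frequency(manual_cohort(g), catalog),
               "missing genotype")
})

test_that("catalog frequencies track the truth allele frequencies", {
  b <- simulate_cohort(simulation_config(
    n_samples = 80L, n_chromosomes = 3L, sites_per_chromosome = 300L,
    deleterious_fraction = 0.08, burden_slope_per_year = 0, seed = 5L
  ))
  catg <- identify_dsnps(b$cohort, b$annotations, b$track, filter_config())
  idx <- attr(catg, "site_index")
  q <- b$truth$base_allele_freq[idx]
  n <- length(b$cohort$samples)
  se <- sqrt(pmax(q * (1 - q), 1e-4) / (2 * n))
  expect_gt(mean(abs(catg$dfreq - q) <= 4 * se), 0.9)
})

test_that("severity mix follows the configured band weights", {
  b <- simulate_cohort(simulation_config(
    n_samples = 20L, n_chromosomes = 3L, sites_per_chromosome = 1000L,
    deleterious_fraction = 0.3, seed = 13L
  ))
  catg <- identify_dsnps(b$cohort, b$annotations, b$track, filter_config())
  n <- nrow(catg)
  obs <- table(catg$severity) / n
  w <- c(weak = 0.41, mild = 0.40, high = 0.19)
  for (band in names(w)) {
    sd2 <- 2 * sqrt(w[band] * (1 - w[band]) / n)
    expect_lt(abs(obs[[band]] - w[[band]]), sd2 + 0.01, label = band)
  }
})

test_that("loss-of-function aggregation reproduces the published rows", {
  counts <- reported_class_counts()
  stats <- reported_cohort_stats()
  oat <- aggregate_lof(setNames(counts$oat, counts$class),
                       total = stats$oat$total_snps)
  expect_identical(oat$count, 1921)
  expect_identical(oat$proportion, 0.0076)
  wheat <- aggregate_lof(setNames(counts$wheat, counts$class),
                         total = stats$wheat$total_snps)
  expect_identical(wheat$count, 2616)
  expect_identical(wheat$proportion, 0.0097)
})

test_that("summarize_cohort is internally consistent on a fixture", {
  b <- small_bundle()
  cfg <- filter_config()
  catg <- identify_dsnps(b$cohort, b$annotations, b$track, cfg)
  s <- summarize_cohort(b$annotations, catg, b$cohort, cfg)
  expect_identical(sum(s$class_counts), nrow(b$cohort$sites))
  expect_identical(s$catalog$count, attr(catg, "L"))
  expect_gte(s$sift_deleterious$count, s$catalog$count)
  expect_identical(sum(s$severity_counts), s$catalog$count)
  expect_identical(sum(s$maf_spectrum), s$catalog$count)
  expect_identical(unname(s$per_chromosome$mean),
                   round(s$catalog$count / 3, 1))
})

test_that("maf_spectrum bins follow the documented edges", {
  x <- maf_spectrum(c(0, 0.01, 0.011, 0.05, 0.051, 0.49, 0.5))
  expect_identical(unname(as.integer(x[1])), 2L)   # [0, 0.01]
  expect_identical(unname(as.integer(x[2])), 2L)   # (0.01, 0.05]
  expect_identical(unname(as.integer(x[3])), 1L)   # (0.05, 0.1]
  expect_identical(unname(as.integer(x[length(x)])), 2L)
  expect_error(maf_spectrum(0.6), "0.5")
})
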