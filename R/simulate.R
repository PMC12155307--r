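#' Configuration for the synthetic selfing-crop cohort generator
#'
#' Defaults describe the cohort the generator is meant to emulate: roughly
#' 140 cultivars registered over the 1900--2019 century on a 21-chromosome
#' selfing-crop genome, with an L-shaped minor-allele-frequency spectrum,
#' near-complete homozygosity, a small fraction of deleterious sites and a
#' gentle planted increase in expected total burden over registration years.
#'
#' @param n_samples number of cultivars.
#' @param n_chromosomes number of chromosomes (default 21).
#' @param sites_per_chromosome SNP sites simulated per chromosome.
#' @param year_range integer vector \code{c(start, end)} of registration
#'   years; cultivars are assigned years uniformly over this range.
#' @param deleterious_fraction probability that a site is designated
#'   deleterious (annotated with SIFT <= 0.05, high confidence, RS > 0).
#' @param burden_slope_per_year planted linear increase in expected total
#'   mutation burden per registration year. The default 3e-4 accumulates
#'   about 0.036 of burden over the 119-year default range, comparable to
#'   the spread observed between low- and high-burden cereal cultivars.
#' @param selfing_inbreeding inbreeding-like parameter F in [0,1]:
#'   P(hom-alt) = F q + (1-F) q^2, P(het) = (1-F) 2q(1-q). F = 1 makes every
#'   carried allele homozygous.
#' @param maf_shape shape parameter a of the Beta(a, 1) law folded to
#'   [0, 0.5] used for minor allele frequencies; a < 1 gives the L-shape.
#' @param severity_weights weights of the weak/mild/high RS severity bands
#'   for deleterious sites (default 0.41/0.40/0.19).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param missing_rate proportion of genotypes masked missing (default 0).
#' @param invariant_het_fraction proportion of sites made all-heterozygous,
#'   emulating the invariant-heterozygote artifact seen in hexaploid wheat
#'   RNA-seq SNP calls (default 0).
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 140L,
                              n_chromosomes = 21L,
                              sites_per_chromosome = 500L,
                              year_range = c(1900L, 2019L),
                              deleterious_fraction = 0.02,
                              burden_slope_per_year = 3e-4,
                              selfing_inbreeding = 0.98,
                              maf_shape = 0.3,
                              severity_weights = c(weak = 0.41, mild = 0.40,
                                                   high = 0.19),
                              seed = 1L,
                              missing_rate = 0,
                              invariant_het_fraction = 0) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    sites_per_chromosome = as.integer(sites_per_chromosome),
    year_range = as.integer(year_range),
    deleterious_fraction = deleterious_fraction,
    burden_slope_per_year = burden_slope_per_year,
    selfing_inbreeding = selfing_inbreeding,
    maf_shape = maf_shape,
    severity_weights = severity_weights / sum(severity_weights),
    seed = as.integer(seed),
    missing_rate = missing_rate,
    invariant_het_fraction = invariant_het_fraction
  )
  counts <- c(cfg$n_samples, cfg$n_chromosomes, cfg$sites_per_chromosome)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("n_samples, n_chromosomes and sites_per_chromosome must be >= 1")
  }
  if (length(cfg$year_range) != 2L || cfg$year_range[1] > cfg$year_range[2]) {
    stop("year_range must be c(start, end) with start <= end")
  }
  props <- c(cfg$deleterious_fraction, cfg$missing_rate,
             cfg$invariant_het_fraction, cfg$selfing_inbreeding)
  if (any(props < 0) || any(props > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  if (cfg$maf_shape <= 0) stop("maf_shape must be positive")
  span <- diff(cfg$year_range)
  if (abs(cfg$burden_slope_per_year) * span >= 1) {
    stop("planted slope infeasible: expected burden would leave [0, 1] ",
         "over the year range (|slope| * span = ",
         signif(abs(cfg$burden_slope_per_year) * span, 3), ")")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic breeding-pool cohort with known ground truth
#'
#' Draws per-site alternate-allele frequencies from a folded Beta law
#' (L-shaped MAF spectrum), assigns registration years uniformly over the
#' configured range, and at deleterious sites couples each cultivar's
#' alternate-allele probability linearly to its registration year so that
#' the expected total burden carries the planted slope. Genotypes are drawn
#' under an inbreeding coefficient F; annotations are emitted so that the
#' designated deleterious sites are exactly those satisfying the
#' SIFT <= 0.05 (high confidence) and RS > 0 screening rule, while every
#' other site fails it in one of four ways (tolerated SIFT, non-positive RS,
#' low-confidence SIFT call, or no RS score in the track).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list of class \code{cohort_bundle} with elements
#'   \code{cohort} (a \code{\link{genotype_cohort}}), \code{annotations},
#'   \code{track}, \code{metadata} (data.frames as read by the
#'   \code{read_*} functions) and \code{truth} (planted ground truth:
#'   deleterious site indices, per-sample expected burden, planted slope,
#'   per-site base allele frequencies).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  set.seed(config$seed)
  n <- config$n_samples
  n_chr <- config$n_chromosomes
  spc <- config$sites_per_chromosome
  m <- n_chr * spc
  y0 <- config$year_range[1]
  y1 <- config$year_range[2]
  span <- y1 - y0
  s <- config$burden_slope_per_year
  f_inb <- config$selfing_inbreeding

  chrom <- rep(sprintf("chr%02d", seq_len(n_chr)), each = spc)
  pos <- as.vector(vapply(
    seq_len(n_chr),
    function(i) sort(sample.int(spc * 50L, spc)),
    integer(spc)
  ))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  samples <- sprintf("CV%03d", seq_len(n))
  years <- sample(seq.int(y0, y1), n, replace = TRUE)

  # site designations: deleterious, invariant-het, ordinary
  is_del <- runif(m) < config$deleterious_fraction
  n_inv <- floor(config$invariant_het_fraction * m)
  inv_pool <- which(!is_del)
  inv_idx <- if (n_inv > 0) sample(inv_pool, min(n_inv, length(inv_pool)))
             else integer(0)
  is_inv <- rep(FALSE, m); is_inv[inv_idx] <- TRUE

  # base alternate-allele frequencies: folded Beta(a, 1) MAF
  u <- rbeta(m, config$maf_shape, 1)
  q <- pmin(u, 1 - u)
  # keep year-coupled probabilities inside [0, 1] at deleterious sites
  if (s >= 0) q[is_del] <- pmin(q[is_del], 1 - s * span)
  else        q[is_del] <- pmax(q[is_del], -s * span)

  # per-sample, per-site alternate-allele probability
  p <- matrix(rep(q, each = n), nrow = n)
  if (any(is_del)) {
    p[, is_del] <- p[, is_del] + s * (years - y0)
  }

  r <- matrix(runif(n * m), n, m)
  p_hom <- f_inb * p + (1 - f_inb) * p^2
  p_het <- (1 - f_inb) * 2 * p * (1 - p)
  geno <- matrix(0L, n, m)
  geno[r < p_hom + p_het] <- 1L
  geno[r < p_hom] <- 2L
  if (any(is_inv)) geno[, is_inv] <- 1L

  if (config$missing_rate > 0) {
    geno[matrix(runif(n * m) < config$missing_rate, n, m)] <- -1L
  }
  depth <- matrix(10L + rpois(n * m, 25), n, m)
  depth[geno == -1L] <- 0L
  qual <- round(runif(m, 30, 100), 1)

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = qual, stringsAsFactors = FALSE)
  cohort <- genotype_cohort(sites, samples, geno, depth)

  annotations <- simulate_annotations(sites, is_del, is_inv, config)
  track <- annotations$track
  ann <- annotations$ann

  metadata <- simulate_metadata(samples, years, config)

  del_idx <- which(is_del)
  expected_burden <- if (length(del_idx)) {
    rowMeans(p[, del_idx, drop = FALSE])
  } else rep(0, n)
  truth <- list(
    deleterious_sites = del_idx,
    expected_burden = setNames(expected_burden, samples),
    planted_slope = s,
    base_allele_freq = q,
    invariant_het_sites = which(is_inv),
    years = setNames(years, samples)
  )

  structure(
    list(cohort = cohort, annotations = ann, track = track,
         metadata = metadata, truth = truth, config = config),
    class = "cohort_bundle"
  )
}

# Annotation + RS-track emission. Deleterious sites get missense consequence,
# SIFT in (0, 0.05), confidence "high" and RS > 0 from the severity-band
# mixture. Every other site fails the screen by construction.
simulate_annotations <- function(sites, is_del, is_inv, config) {
  m <- nrow(sites)
  consequence <- character(m)
  sift <- rep(NA_real_, m)
  conf <- rep(NA_character_, m)
  rs <- rep(NA_real_, m)
  in_track <- rep(TRUE, m)

  # ordinary sites: consequence mix loosely matching cereal RNA-seq cohorts
  ord <- which(!is_del & !is_inv)
  cons_pool <- c("downstream_gene_variant", "synonymous_variant",
                 "upstream_gene_variant", "missense_variant",
                 "3_prime_UTR_variant", "5_prime_UTR_variant",
                 "intron_variant", "intergenic_variant")
  cons_w <- c(0.25, 0.24, 0.16, 0.15, 0.10, 0.03, 0.02, 0.05)
  consequence[ord] <- sample(cons_pool, length(ord), TRUE, prob = cons_w)
  consequence[is_inv] <- "synonymous_variant"
  rs[c(ord, which(is_inv))] <- runif(length(ord) + sum(is_inv), -3, 3)

  # non-deleterious missense sites must fail the screen in one of four ways
  ord_mis <- ord[consequence[ord] == "missense_variant"]
  mode <- sample(c("tolerated", "rs_nonpos", "low_conf", "rs_absent"),
                 length(ord_mis), TRUE)
  sift[ord_mis] <- ifelse(mode == "tolerated",
                          runif(length(ord_mis), 0.06, 1),
                          runif(length(ord_mis), 0, 0.049))
  conf[ord_mis] <- ifelse(mode == "low_conf", "low", "high")
  rs[ord_mis][mode == "rs_nonpos"] <- runif(sum(mode == "rs_nonpos"), -3, 0)
  rs[ord_mis][mode == "tolerated" | mode == "low_conf"] <-
    runif(sum(mode %in% c("tolerated", "low_conf")), -1, 3)
  in_track[ord_mis][mode == "rs_absent"] <- FALSE

  # deleterious sites
  del <- which(is_del)
  consequence[del] <- "missense_variant"
  sift[del] <- runif(length(del), 0, 0.0499)
  conf[del] <- "high"
  band <- sample(c("weak", "mild", "high"), length(del), TRUE,
                 prob = config$severity_weights)
  rs[del] <- ifelse(band == "weak", runif(length(del), 0.001, 0.999),
             ifelse(band == "mild", runif(length(del), 1, 3),
                                    runif(length(del), 3.001, 6)))

  gene_id <- paste0("g", sprintf("%05d", ceiling(seq_len(m) / 5)))
  gene_id[consequence == "intergenic_variant"] <- NA_character_

  ann <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    consequence = consequence, sift_score = sift, sift_confidence = conf,
    gene_id = gene_id, stringsAsFactors = FALSE
  )
  track <- data.frame(chrom = sites$chrom[in_track], pos = sites$pos[in_track],
                      rs = rs[in_track], stringsAsFactors = FALSE)
  track <- track[!is.na(track$rs), , drop = FALSE]
  rownames(track) <- NULL
  class(track) <- c("rs_track", "data.frame")
  list(ann = ann, track = track)
}

# Cultivar metadata: equal-width breeding periods over the year range and a
# yield that rises with registration year (about 0.35 bu/ac per year around a
# 60 bu/ac base, sd 8), emitted as a single already-adjusted report source.
simulate_metadata <- function(samples, years, config,
                              n_periods = 10L) {
  y0 <- config$year_range[1]; y1 <- config$year_range[2]
  n_periods <- max(1L, min(n_periods, y1 - y0 + 1L))
  breaks <- seq(y0, y1, length.out = n_periods + 1L)
  period_i <- findInterval(years, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
  yield <- 60 + 0.35 * (years - y0) + rnorm(length(years), 0, 8)
  yield <- pmax(yield, 5)
  data.frame(
    cultivar = samples,
    registration_year = years,
    breeding_period = sprintf("P%02d", period_i),
    yield_source = "SIM",
    yield_raw = round(yield, 1),
    yield_unit = "bu/ac",
    adjusted_yield = round(yield, 1),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated cohort bundle to disk as standard files
#'
#' Emits a plain-text VCF 4.2 (GT:DP genotypes, per-site QUAL), tab-separated
#' annotation, RS-track and metadata tables, and a JSON ground-truth file,
#' all readable back by the \code{read_*} functions.
#'
#' @param bundle a \code{cohort_bundle} from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    rs_track = file.path(dir, "rs_track.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_cohort_vcf(bundle$cohort, paths$vcf)
  write.table(bundle$annotations, paths$annotations, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$track, paths$rs_track, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$metadata, paths$metadata, sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(
      deleterious_sites = truth$deleterious_sites,
      expected_burden = as.list(truth$expected_burden),
      planted_slope = truth$planted_slope,
      base_allele_freq = truth$base_allele_freq,
      invariant_het_sites = truth$invariant_het_sites,
      years = as.list(truth$years),
      sites_per_chromosome = as.vector(table(bundle$cohort$sites$chrom))
    ),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

# Minimal VCF 4.2 text emitter for fixtures (GT:DP, biallelic SNPs only).
# Kept in-package because the fixtures must be plain text; reading back
# through vcfR makes the round-trip a cross-parser check.
write_cohort_vcf <- function(cohort, path) {
  st <- cohort$sites
  gt_code <- c("./.", "0/0", "0/1", "1/1")
  gt <- matrix(gt_code[cohort$geno + 2L], nrow = nrow(cohort$geno))
  dp <- cohort$depth
  dp_chr <- ifelse(is.na(dp), ".", as.character(dp))
  cells <- matrix(paste(gt, dp_chr, sep = ":"), nrow = nrow(gt))
  body <- vapply(seq_len(nrow(st)), function(j) {
    paste(c(st$chrom[j], st$pos[j], ".", st$ref[j], st$alt[j],
            ifelse(is.na(st$qual[j]), ".", st$qual[j]), "PASS", ".",
            "GT:DP", cells[, j]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=burdenscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
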