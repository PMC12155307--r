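#' Quality-filter and screening configuration
#'
#' Defaults reproduce a stringent RNA-seq SNP filtering recipe for selfing
#' cereal cohorts: per-genotype depth >= 10 (lower depths are masked
#' missing), site QUAL >= 20, no missing genotypes tolerated per site
#' (\code{max_missing = 0}, the vcftools \code{--max-missing 1} convention),
#' biallelic SNPs only; deleterious screening combines SIFT <= 0.05 at high
#' confidence with GERP++ RS > 0.
#'
#' @param min_dp minimum per-genotype read depth; genotypes below it are
#'   masked missing. Genotypes with unknown depth are left untouched.
#' @param min_qual minimum site QUAL; lower-QUAL sites are removed.
#' @param max_missing maximum tolerated fraction of missing genotypes per
#'   site after depth masking (default 0).
#' @param biallelic_only kept for completeness; multi-allelic and indel
#'   records are already excluded at parse time.
#' @param sift_threshold SIFT score threshold for a deleterious call.
#' @param sift_inclusive if TRUE (default) the comparison is
#'   \code{sift <= threshold} ("0.05 or smaller", the SIFT convention);
#'   if FALSE, strictly less.
#' @param rs_threshold RS must exceed this for a deleterious call
#'   (default 0: the site must be under detectable constraint).
#' @param exclude_low_confidence drop low-confidence SIFT deleterious calls
#'   (default TRUE).
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(min_dp = 10L, min_qual = 20, max_missing = 0,
                          biallelic_only = TRUE,
                          sift_threshold = 0.05, sift_inclusive = TRUE,
                          rs_threshold = 0, exclude_low_confidence = TRUE) {
  cfg <- list(min_dp = as.integer(min_dp), min_qual = min_qual,
              max_missing = max_missing, biallelic_only = biallelic_only,
              sift_threshold = sift_threshold,
              sift_inclusive = isTRUE(sift_inclusive),
              rs_threshold = rs_threshold,
              exclude_low_confidence = isTRUE(exclude_low_confidence))
  if (!is.finite(cfg$min_qual) || !is.finite(cfg$sift_threshold) ||
      !is.finite(cfg$rs_threshold)) {
    stop("thresholds must be finite")
  }
  if (cfg$max_missing < 0 || cfg$max_missing > 1) {
    stop("max_missing must be in [0, 1]")
  }
  structure(cfg, class = "filter_config")
}

#' Apply genotype- and site-level quality filters
#'
#' Masks genotypes with read depth below \code{min_dp} as missing, removes
#' sites with QUAL below \code{min_qual}, then removes sites whose missing
#' fraction exceeds \code{max_missing}. Site order is preserved. The
#' operation is idempotent.
#'
#' @param cohort a \code{\link{genotype_cohort}}.
#' @param cfg a \code{\link{filter_config}}.
#' @return The filtered \code{genotype_cohort}, with a \code{"filter_log"}
#'   attribute recording how many genotypes were masked and how many sites
#'   were dropped at each step.
#' @export
apply_quality_filters <- function(cohort, cfg = filter_config()) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  geno <- cohort$geno
  low_dp <- !is.na(cohort$depth) & cohort$depth < cfg$min_dp & geno != -1L
  geno[low_dp] <- -1L
  depth <- cohort$depth

  qual_fail <- !is.na(cohort$sites$qual) & cohort$sites$qual < cfg$min_qual
  miss_frac <- colMeans(geno == -1L)
  miss_fail <- miss_frac > cfg$max_missing
  keep <- which(!qual_fail & !miss_fail)

  out <- genotype_cohort(cohort$sites[keep, , drop = FALSE], cohort$samples,
                         geno[, keep, drop = FALSE],
                         depth[, keep, drop = FALSE])
  attr(out, "filter_log") <- list(
    genotypes_masked_low_dp = sum(low_dp),
    sites_removed_low_qual = sum(qual_fail),
    sites_removed_missing = sum(miss_fail & !qual_fail),
    sites_in = nrow(cohort$sites), sites_out = length(keep)
  )
  if (length(keep) == 0L) message("apply_quality_filters: no sites survived")
  out
}

#' Classify deleterious severity from a GERP++ RS score
#'
#' Deleterious SNPs are banded by evolutionary constraint: weakly
#' (0 < RS < 1), mildly (1 <= RS <= 3) and highly (RS > 3) deleterious.
#' The middle band is closed so the three labels partition (0, Inf).
#'
#' @param rs numeric vector of RS scores, all > 0.
#' @return factor with levels \code{weak}, \code{mild}, \code{high}.
#' @export
classify_severity <- function(rs) {
  if (any(!is.finite(rs)) || any(rs <= 0)) {
    stop("severity is defined only for RS > 0")
  }
  out <- ifelse(rs < 1, "weak", ifelse(rs <= 3, "mild", "high"))
  factor(out, levels = c("weak", "mild", "high"))
}

#' Identify deleterious SNPs by the combined SIFT + RS rule
#'
#' A site enters the catalog when its (transcript-collapsed) SIFT score is
#' at or below the threshold with high confidence (unless low-confidence
#' calls are admitted) and its GERP++ RS score, looked up in the
#' conservation track, is strictly above the RS threshold. Sites without an
#' RS score carry no conservation evidence and are never called
#' deleterious. The deleterious allele is the alternate allele; its cohort
#' frequency and fixation flag are computed from the genotypes.
#'
#' @param cohort a quality-filtered \code{\link{genotype_cohort}}.
#' @param annotations annotation data.frame from
#'   \code{\link{read_annotations}}.
#' @param track an \code{rs_track} from \code{\link{read_rs_track}}.
#' @param cfg a \code{\link{filter_config}}.
#' @return data.frame of class \code{deleterious_catalog} with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{sift},
#'   \code{rs}, \code{severity}, \code{dfreq}, \code{fixed}, plus
#'   attributes \code{L} (catalog size) and \code{site_index} (column
#'   indices into the cohort).
#' @export
identify_dsnps <- function(cohort, annotations, track, cfg = filter_config()) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  ck <- cohort_site_key(cohort)
  ak <- site_key(annotations$chrom, annotations$pos, annotations$alt)
  ann_idx <- match(ck, ak)
  if (all(is.na(ann_idx))) {
    stop("annotation join is empty: no (chrom, pos, alt) keys match; ",
         "check that coordinates are 1-based and alt alleles agree")
  }
  sift <- annotations$sift_score[ann_idx]
  conf <- annotations$sift_confidence[ann_idx]
  rs <- rs_lookup(track, cohort$sites$chrom, cohort$sites$pos)

  sift_hit <- !is.na(sift) &
    (if (cfg$sift_inclusive) sift <= cfg$sift_threshold
     else sift < cfg$sift_threshold)
  conf_ok <- if (cfg$exclude_low_confidence) {
    is.na(conf) | conf != "low"
  } else rep(TRUE, length(conf))
  rs_hit <- !is.na(rs) & rs > cfg$rs_threshold
  hit <- which(sift_hit & conf_ok & rs_hit)

  cat_sites <- cohort$sites[hit, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  catalog <- data.frame(
    cat_sites,
    sift = sift[hit], rs = rs[hit],
    severity = if (length(hit)) classify_severity(rs[hit])
               else factor(character(0), levels = c("weak", "mild", "high")),
    stringsAsFactors = FALSE
  )
  rownames(catalog) <- NULL
  class(catalog) <- c("deleterious_catalog", "data.frame")
  attr(catalog, "L") <- length(hit)
  attr(catalog, "site_index") <- hit
  if (length(hit)) {
    fr <- deleterious_allele_frequency(cohort, catalog)
    catalog$dfreq <- fr$dfreq
    catalog$fixed <- fr$fixed
  } else {
    catalog$dfreq <- numeric(0)
    catalog$fixed <- logical(0)
  }
  catalog
}

#' Deleterious (alternate) allele frequency at catalog sites
#'
#' Frequency is the alternate-allele count over all sampled chromosomes,
#' \code{(2 n_hom_alt + n_het) / (2 n_samples)}. A catalog site is fixed
#' when the frequency is exactly 1, i.e. every assayed cultivar carries
#' only the deleterious allele. Missing genotypes are an error: the
#' screening design tolerates none.
#'
#' @param cohort a \code{genotype_cohort} containing the catalog sites.
#' @param catalog a \code{deleterious_catalog} (or any data.frame with
#'   \code{chrom}, \code{pos}, \code{alt}).
#' @return data.frame with columns \code{dfreq} and \code{fixed}, one row
#'   per catalog site.
#' @export
deleterious_allele_frequency <- function(cohort, catalog) {
  idx <- match(site_key(catalog$chrom, catalog$pos, catalog$alt),
               cohort_site_key(cohort))
  if (any(is.na(idx))) {
    stop("catalog sites absent from cohort: ",
         paste(utils::head(paste0(catalog$chrom, ":", catalog$pos)[is.na(idx)],
                           3), collapse = ", "))
  }
  g <- cohort$geno[, idx, drop = FALSE]
  if (any(g == -1L)) {
    j <- which(colSums(g == -1L) > 0)[1]
    stop("missing genotype at catalog site ", catalog$chrom[j], ":",
         catalog$pos[j], "; quality-filter with max_missing = 0 first")
  }
  n <- nrow(g)
  dfreq <- colSums(g) / (2 * n)
  data.frame(dfreq = dfreq, fixed = dfreq == 1, row.names = NULL)
}

#' Aggregate loss-of-function variant classes
#'
#' Sums the seven loss-of-function consequence classes (three STOP_, three
#' Splice_, Start_lost) from a named vector of per-class counts and
#' reports the proportion over all annotated variants.
#'
#' @param class_counts named numeric vector of per-consequence-class counts
#'   (names from \code{\link{consequence_classes}}).
#' @param total total variant count for the proportion denominator;
#'   defaults to \code{sum(class_counts)}.
#' @param digits rounding for the proportion (default 4).
#' @return list with \code{count} and \code{proportion}.
#' @export
aggregate_lof <- function(class_counts, total = sum(class_counts),
                          digits = 4) {
  bad <- setdiff(names(class_counts), consequence_classes())
  if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  count <- sum(class_counts[intersect(lof_classes(), names(class_counts))])
  list(count = unname(count),
       proportion = round(unname(count) / total, digits))
}

#' Minor-allele-frequency spectrum bin counts
#'
#' Bins are [0, 0.01], (0.01, 0.05], then 0.05-wide bins up to 0.5, the
#' binning used for L-shape spectrum summaries.
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @return named integer vector of bin counts.
#' @export
maf_spectrum <- function(maf) {
  if (any(maf < 0 | maf > 0.5 + 1e-12)) stop("MAF must lie in [0, 0.5]")
  breaks <- c(0, 0.01, seq(0.05, 0.5, by = 0.05))
  cut_f <- cut(maf, breaks = breaks, include.lowest = TRUE)
  table(cut_f)
}

# min/max/mean (1 decimal) of per-chromosome site counts; chromosomes with
# no sites count as zero when the full chromosome set is supplied.
per_chromosome_stats <- function(chrom, chromosomes = sort(unique(chrom))) {
  counts <- table(factor(chrom, levels = chromosomes))
  list(counts = counts, min = min(counts), max = max(counts),
       mean = round(mean(counts), 1))
}

#' Cohort-level screening summary
#'
#' Reproduces the headline numbers of a deleterious-variant screen:
#' per-consequence-class counts, the loss-of-function aggregate, SIFT-only
#' deleterious counts, the combined SIFT+RS catalog count, fixed-site
#' count, per-chromosome catalog counts, and the catalog MAF spectrum.
#' Proportions are over the total annotated SNP count, rounded to 4
#' decimals (6 for the fixed proportion).
#'
#' @param annotations annotation data.frame (one row per site).
#' @param catalog a \code{deleterious_catalog}.
#' @param cohort the quality-filtered \code{genotype_cohort}.
#' @param cfg a \code{\link{filter_config}} (for the SIFT rule).
#' @return list of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(annotations, catalog, cohort,
                             cfg = filter_config()) {
  total <- nrow(cohort$sites)
  class_counts <- table(factor(annotations$consequence,
                               levels = consequence_classes()))
  lof <- aggregate_lof(setNames(as.numeric(class_counts),
                                names(class_counts)), total = total)

  sift <- annotations$sift_score
  conf <- annotations$sift_confidence
  sift_hit <- !is.na(sift) &
    (if (cfg$sift_inclusive) sift <= cfg$sift_threshold
     else sift < cfg$sift_threshold)
  conf_ok <- if (cfg$exclude_low_confidence) is.na(conf) | conf != "low"
             else TRUE
  sift_del <- sum(sift_hit & conf_ok)

  L <- attr(catalog, "L")
  n_fixed <- sum(catalog$fixed)
  maf <- pmin(catalog$dfreq, 1 - catalog$dfreq)
  chroms <- sort(unique(cohort$sites$chrom))

  structure(list(
    total_snps = total,
    class_counts = class_counts,
    lof = lof,
    sift_deleterious = list(count = sift_del,
                            proportion = round(sift_del / total, 4)),
    catalog = list(count = L, proportion = round(L / total, 4)),
    fixed = list(count = n_fixed,
                 proportion = round(n_fixed / total, 6)),
    per_chromosome = per_chromosome_stats(catalog$chrom, chroms),
    severity_counts = table(catalog$severity),
    maf_spectrum = maf_spectrum(maf),
    maf_le_0.05 = sum(maf <= 0.05),
    maf_le_0.01 = sum(maf <= 0.01)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("  total SNPs:            ", x$total_snps, "\n")
  cat("  loss-of-function:      ", x$lof$count,
      " (prop ", x$lof$proportion, ")\n", sep = "")
  cat("  SIFT-deleterious:      ", x$sift_deleterious$count,
      " (prop ", x$sift_deleterious$proportion, ")\n", sep = "")
  cat("  SIFT+RS catalog:       ", x$catalog$count,
      " (prop ", x$catalog$proportion, ")\n", sep = "")
  cat("  fixed dSNPs:           ", x$fixed$count,
      " (prop ", x$fixed$proportion, ")\n", sep = "")
  cat("  per-chromosome dSNPs:   min ", x$per_chromosome$min, ", max ",
      x$per_chromosome$max, ", mean ", x$per_chromosome$mean, "\n", sep = "")
  cat("  severity: ", paste(names(x$severity_counts), x$severity_counts,
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
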