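#' Per-site nucleotide diversity
#'
#' The unbiased per-site pairwise diversity for a biallelic site among n
#' diploids: with N = 2n called chromosomes and alternate-allele count c,
#' \deqn{\pi = 2 c (N - c) / (N (N - 1)),}
#' the fraction of distinct chromosome pairs that differ (vcftools
#' \code{--site-pi} semantics). Missing genotypes are dropped, shrinking N.
#'
#' @param g integer vector of genotype codes \{-1, 0, 1, 2\} for one site.
#' @return The site diversity in [0, 1].
#' @export
site_pi <- function(g) {
  g <- g[g != -1L]
  n <- length(g)
  if (n < 2L) stop("site_pi needs at least 2 called diploid samples")
  bign <- 2 * n
  c_alt <- sum(g)
  2 * c_alt * (bign - c_alt) / (bign * (bign - 1))
}

# Vectorised site_pi over the columns of a genotype matrix (no missing).
site_pi_columns <- function(geno) {
  n_called <- colSums(geno != -1L)
  if (any(n_called < 2L)) stop("site_pi needs at least 2 called samples")
  g0 <- geno
  g0[g0 == -1L] <- 0L
  bign <- 2 * n_called
  c_alt <- colSums(g0)
  2 * c_alt * (bign - c_alt) / (bign * (bign - 1))
}

#' Nucleotide diversity by breeding period
#'
#' For each breeding period, computes the mean per-site diversity across
#' each chromosome for the period's members (or, with
#' \code{grouping = "cumulative"}, all members registered up to and
#' including the period), then the grand mean and standard deviation
#' across chromosomes. An OLS trend of the period grand means on the
#' period index 1..K is attached. Periods with fewer than 2 members have
#' undefined diversity: they are reported as NA and excluded from the
#' trend.
#'
#' @param cohort a \code{\link{genotype_cohort}}.
#' @param metadata metadata data.frame with \code{cultivar} and
#'   \code{breeding_period}.
#' @param grouping \code{"per_period"} (default; each period's registrants
#'   only) or \code{"cumulative"}.
#' @return list of class \code{period_diversity}: \code{periods} (one row
#'   per period: label, n members, mean and SD of per-chromosome mean pi),
#'   \code{per_chromosome} (periods x chromosomes matrix) and
#'   \code{trend} (a \code{trend_fit} on the period index).
#' @export
diversity_by_period <- function(cohort, metadata,
                                grouping = c("per_period", "cumulative")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(cohort, "genotype_cohort"))
  miss <- setdiff(cohort$samples, metadata$cultivar)
  if (length(miss)) {
    stop("cultivars without metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  md <- metadata[match(cohort$samples, metadata$cultivar), ]
  periods <- sort(unique(md$breeding_period))
  chroms <- sort(unique(cohort$sites$chrom))
  chrom_f <- factor(cohort$sites$chrom, levels = chroms)

  per_chrom <- matrix(NA_real_, length(periods), length(chroms),
                      dimnames = list(periods, chroms))
  n_members <- integer(length(periods))
  for (k in seq_along(periods)) {
    members <- if (grouping == "cumulative") {
      md$breeding_period <= periods[k]
    } else {
      md$breeding_period == periods[k]
    }
    n_members[k] <- sum(md$breeding_period == periods[k])
    if (sum(members) < 2L) next
    pi_all <- site_pi_columns(cohort$geno[members, , drop = FALSE])
    per_chrom[k, ] <- tapply(pi_all, chrom_f, mean)
  }
  grand <- rowMeans(per_chrom)
  sds <- apply(per_chrom, 1, sd)
  tab <- data.frame(
    period = periods, index = seq_along(periods), n_members = n_members,
    mean_pi = grand, sd_pi = sds, row.names = NULL, stringsAsFactors = FALSE
  )
  ok <- !is.na(tab$mean_pi)
  trend <- if (sum(ok) >= 3L && var(tab$index[ok]) > 0) {
    fit_trend(tab$index[ok], tab$mean_pi[ok],
              response = "mean_pi", predictor = "period_index")
  } else NULL
  structure(list(periods = tab, per_chromosome = per_chrom,
                 grouping = grouping, trend = trend),
            class = "period_diversity")
}

#' Genotype principal component analysis
#'
#' PCA of the samples-by-sites dosage matrix under the standard
#' allele-frequency normalization: each site is centered by twice its
#' sample alternate-allele frequency p and scaled by sqrt(p(1 - p));
#' monomorphic sites are dropped; the eigendecomposition of the resulting
#' sample-by-sample covariance (scaled by the site count) gives sample
#' coordinates and variance proportions. Missing genotypes are
#' mean-imputed with a message. For reproducible orientation, each
#' eigenvector's largest-magnitude entry is made positive.
#'
#' @param cohort a \code{\link{genotype_cohort}}.
#' @param n_components number of leading components to return.
#' @return list of class \code{genotype_pca}: \code{coords} (samples x
#'   components), \code{eigenvalues} (all), \code{varprop} (variance
#'   proportions of the returned components), \code{n_sites_used}.
#' @export
genotype_pca <- function(cohort, n_components = 10L) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  g <- cohort$geno
  storage.mode(g) <- "double"
  if (any(g == -1)) {
    message("genotype_pca: mean-imputing ", sum(g == -1),
            " missing genotype(s)")
    g[g == -1] <- NA_real_
    mu <- colMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- mu[na_idx[, 2]]
  }
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites for PCA")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  m <- ncol(x)
  cov_s <- tcrossprod(x) / m
  eig <- eigen(cov_s, symmetric = TRUE)
  k <- min(n_components, length(cohort$samples))
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- cohort$samples
  colnames(vecs) <- paste0("PC", seq_len(k))
  pos <- pmax(eig$values, 0)
  structure(list(
    coords = vecs,
    eigenvalues = eig$values,
    varprop = pos[seq_len(k)] / sum(pos),
    n_sites_used = m
  ), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca> ", nrow(x$coords), " samples, ", x$n_sites_used,
      " sites; variance proportions: ",
      paste(signif(x$varprop[seq_len(min(5, length(x$varprop)))], 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
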