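#' Construct a genotype cohort
#'
#' The in-memory container for a biallelic SNP cohort: a site table, an
#' ordered sample list, and samples-by-sites genotype and read-depth
#' matrices. Genotypes are coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, -1 = missing.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single bases), \code{qual} (site QUAL, may be
#'   NA). Positions must be strictly increasing within each chromosome.
#' @param samples character vector of cultivar identifiers.
#' @param geno integer matrix, \code{length(samples)} rows by
#'   \code{nrow(sites)} columns, values in \{-1, 0, 1, 2\}.
#' @param depth integer matrix of per-genotype read depth, same shape as
#'   \code{geno}; NA where depth is unknown.
#' @return An object of class \code{genotype_cohort}.
#' @export
genotype_cohort <- function(sites, samples, geno, depth = NULL) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols)) {
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(sites)) {
    stop("genotype matrix must be samples x sites (",
         length(samples), " x ", nrow(sites), ")")
  }
  bad <- setdiff(unique(as.vector(geno)), c(-1L, 0L, 1L, 2L))
  bad <- bad[!is.na(bad)]
  if (length(bad)) stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  if (nrow(sites) > 0) {
    if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L)) {
      stop("all sites must be single-base biallelic SNPs")
    }
    ord_ok <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
    if (!all(unlist(ord_ok))) {
      stop("positions must be strictly increasing within each chromosome")
    }
  }
  if (is.null(depth)) {
    depth <- matrix(NA_integer_, nrow(geno), ncol(geno))
  } else {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(geno))) stop("depth matrix shape mismatch")
  }
  dimnames(geno) <- list(samples, NULL)
  dimnames(depth) <- list(samples, NULL)
  rownames(sites) <- NULL
  structure(
    list(sites = sites, samples = samples, geno = geno, depth = depth),
    class = "genotype_cohort"
  )
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat("<genotype_cohort> ", length(x$samples), " samples x ",
      nrow(x$sites), " sites on ", length(unique(x$sites$chrom)),
      " chromosome(s)\n", sep = "")
  miss <- mean(x$geno == -1L)
  cat("  missing genotype fraction: ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_cohort <- function(x) c(length(x$samples), nrow(x$sites))

# Canonical site key used for all joins: chromosome, position, alt allele.
site_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

cohort_site_key <- function(cohort) {
  site_key(cohort$sites$chrom, cohort$sites$pos, cohort$sites$alt)
}

# Subset a cohort to site indices (keeps order given).
subset_sites <- function(cohort, idx) {
  genotype_cohort(
    sites = cohort$sites[idx, , drop = FALSE],
    samples = cohort$samples,
    geno = cohort$geno[, idx, drop = FALSE],
    depth = cohort$depth[, idx, drop = FALSE]
  )
}
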