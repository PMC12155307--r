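#' Estimate per-cultivar mutation burdens at catalog sites
#'
#' For each sample, with L the catalog size, n_hom the number of catalog
#' loci homozygous for the deleterious (alternate) allele and n_het the
#' number heterozygous:
#' \deqn{hom = n_{hom} / (2L), \quad het = n_{het} / (2L), \quad
#'       total = (2 n_{hom} + n_{het}) / (2L) = 2\,hom + het.}
#' The total burden is the per-locus deleterious allele dosage; it reaches
#' 1 when a sample is homozygous deleterious at every catalog locus.
#'
#' @param cohort a quality-filtered \code{\link{genotype_cohort}}.
#' @param catalog a \code{deleterious_catalog} with L >= 1.
#' @param metadata optional metadata data.frame; when given, registration
#'   year and adjusted yield are joined onto the result.
#' @return data.frame of class \code{burden_estimates} with one row per
#'   sample: \code{cultivar}, \code{n_hom}, \code{n_het}, \code{L},
#'   \code{hom_burden}, \code{het_burden}, \code{total_burden}.
#' @export
estimate_burdens <- function(cohort, catalog, metadata = NULL) {
  L <- attr(catalog, "L")
  if (is.null(L)) L <- nrow(catalog)
  if (L == 0L) stop("empty catalog: no deleterious loci to score")
  idx <- match(site_key(catalog$chrom, catalog$pos, catalog$alt),
               cohort_site_key(cohort))
  g <- cohort$geno[, idx, drop = FALSE]
  if (any(g == -1L)) {
    w <- which(g == -1L, arr.ind = TRUE)[1, ]
    stop("missing genotype for sample ", cohort$samples[w[1]],
         " at catalog site ", catalog$chrom[w[2]], ":", catalog$pos[w[2]])
  }
  n_hom <- rowSums(g == 2L)
  n_het <- rowSums(g == 1L)
  out <- data.frame(
    cultivar = cohort$samples,
    n_hom = n_hom, n_het = n_het, L = L,
    hom_burden = n_hom / (2 * L),
    het_burden = n_het / (2 * L),
    # = (2 n_hom + n_het) / (2L); written so the identity holds to the bit
    total_burden = 2 * (n_hom / (2 * L)) + n_het / (2 * L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    j <- match(out$cultivar, metadata$cultivar)
    out$registration_year <- metadata$registration_year[j]
    if ("adjusted_yield" %in% names(metadata)) {
      out$adjusted_yield <- metadata$adjusted_yield[j]
    }
  }
  class(out) <- c("burden_estimates", "data.frame")
  out
}

#' Ranked burden report
#'
#' Sorts burden estimates by a chosen burden statistic (ties broken by
#' cultivar id, so the order is stable), optionally restricted to a
#' registration-year window, with top-k / bottom-k extraction. Cohort
#' mean, minimum and maximum of the chosen burden are attached as the
#' \code{"cohort_stats"} attribute.
#'
#' @param estimates a \code{burden_estimates} data.frame.
#' @param by which burden to rank on: \code{"total_burden"} (default),
#'   \code{"het_burden"} or \code{"hom_burden"}.
#' @param decreasing sort direction (default TRUE: highest burden first).
#' @param top_k,bottom_k optional; keep only the k highest- or
#'   lowest-burden cultivars (mutually exclusive).
#' @param released_after,released_before optional registration-year window
#'   (exclusive bounds); requires a \code{registration_year} column.
#' @return The sorted (and possibly truncated) data.frame.
#' @export
burden_table <- function(estimates,
                         by = c("total_burden", "het_burden", "hom_burden"),
                         decreasing = TRUE,
                         top_k = NULL, bottom_k = NULL,
                         released_after = NULL, released_before = NULL) {
  by <- match.arg(by)
  if (!is.null(top_k) && !is.null(bottom_k)) {
    stop("give top_k or bottom_k, not both")
  }
  x <- estimates
  if (!is.null(released_after) || !is.null(released_before)) {
    if (!"registration_year" %in% names(x)) {
      stop("year filter needs a registration_year column ",
           "(pass metadata to estimate_burdens)")
    }
    if (!is.null(released_after)) x <- x[x$registration_year > released_after, ]
    if (!is.null(released_before)) x <- x[x$registration_year < released_before, ]
  }
  stats <- c(mean = mean(x[[by]]), min = min(x[[by]]), max = max(x[[by]]))
  if (!is.null(bottom_k)) decreasing <- FALSE
  if (!is.null(top_k)) decreasing <- TRUE
  ord <- order(x[[by]], x$cultivar, decreasing = c(decreasing, FALSE),
               method = "radix")
  x <- x[ord, , drop = FALSE]
  k <- if (!is.null(top_k)) top_k else bottom_k
  if (!is.null(k)) x <- utils::head(x, k)
  rownames(x) <- NULL
  attr(x, "cohort_stats") <- stats
  x
}

#' @export
print.burden_estimates <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (cl in intersect(c("hom_burden", "het_burden", "total_burden"),
                       names(y))) {
    if (is.numeric(y[[cl]])) y[[cl]] <- round(y[[cl]], digits)
  }
  print(y, ...)
  invisible(x)
}
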