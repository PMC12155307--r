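#' Read a multi-sample SNP VCF into a genotype cohort
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and assembles the biallelic-SNP
#' records into a \code{\link{genotype_cohort}}. Indel and multi-allelic
#' records are excluded; the number excluded is recorded in the
#' \code{"n_excluded"} attribute and reported as a message. All retained
#' records are kept regardless of QUAL or depth -- quality filtering is a
#' separate step (\code{\link{apply_quality_filters}}).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param region optional chromosome name; only records on that chromosome
#'   are returned.
#' @return A \code{genotype_cohort}; depth is NA where the DP field is
#'   absent.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns")
  samples <- colnames(vcf@gt)[-1L]

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  if (n_excluded > 0) {
    message("read_vcf: excluded ", n_excluded,
            " non-biallelic-SNP record(s)")
  }
  keep <- which(snp)
  if (!is.null(region)) keep <- keep[fix[keep, "CHROM"] == region]

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  has_dp <- any(grepl("DP", vcf@gt[, "FORMAT"], fixed = TRUE))
  dp_raw <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  } else NULL

  geno <- t(decode_gt(gt_raw[keep, , drop = FALSE]))
  depth <- if (is.null(dp_raw)) NULL else {
    d <- t(dp_raw[keep, , drop = FALSE]); storage.mode(d) <- "integer"; d
  }
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  sites <- data.frame(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep], qual = qual, stringsAsFactors = FALSE
  )
  out <- genotype_cohort(sites, samples, geno, depth)
  attr(out, "n_excluded") <- n_excluded
  out
}

# Map GT strings to codes {-1,0,1,2}; phased and unphased accepted.
decode_gt <- function(gt) {
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
             "./." = -1L, ".|." = -1L, "." = -1L)
  out <- codes[gt]
  out[is.na(gt)] <- -1L
  unknown <- is.na(out) & !is.na(gt)
  if (any(unknown)) {
    stop("unrecognised GT value(s): ",
         paste(utils::head(unique(gt[unknown]), 5), collapse = ", "))
  }
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a per-variant functional annotation table
#'
#' Reads a tab-separated annotation table with columns \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{consequence},
#' \code{sift_score}, \code{sift_confidence}, \code{gene_id}. Tables may
#' carry several transcript rows per site; these are collapsed to one row
#' per (chrom, pos, alt) key. The default collapse keeps the row with the
#' minimum SIFT score (carrying its confidence label), a conservative
#' stand-in for canonical-transcript selection; \code{collapse = "first"}
#' keeps the first row instead.
#'
#' @param path path to the TSV file.
#' @param collapse transcript-collapse rule, \code{"min_sift"} (default) or
#'   \code{"first"}.
#' @return data.frame with one row per site key.
#' @export
read_annotations <- function(path, collapse = c("min_sift", "first")) {
  collapse <- match.arg(collapse)
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "consequence",
            "sift_score", "sift_confidence", "gene_id")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(ann) == 0) return(ann)
  bad <- setdiff(unique(ann$consequence), consequence_classes())
  bad <- bad[!is.na(bad)]
  if (length(bad)) {
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(ann$sift_score) &
          (ann$sift_score < 0 | ann$sift_score > 1))) {
    stop("sift_score out of [0, 1]")
  }
  key <- site_key(ann$chrom, ann$pos, ann$alt)
  if (anyDuplicated(key)) {
    pick <- switch(collapse,
      min_sift = {
        ord <- order(key, ifelse(is.na(ann$sift_score), Inf, ann$sift_score))
        ord[!duplicated(key[ord])]
      },
      first = which(!duplicated(key))
    )
    ann <- ann[sort(pick), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Read a GERP++ RS conservation track
#'
#' Tab-separated table with columns \code{chrom}, \code{pos} (1-based, to
#' match VCF coordinates) and \code{rs}. Positions absent from the track
#' carry no conservation evidence: lookups return NA, never 0.
#'
#' @param path path to the TSV file.
#' @return data.frame of class \code{rs_track}.
#' @export
read_rs_track <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(chrom = "character"))
  need <- c("chrom", "pos", "rs")
  if (length(setdiff(need, names(tr)))) {
    stop("RS track lacks columns: ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  }
  if (anyDuplicated(paste(tr$chrom, tr$pos))) {
    stop("duplicate (chrom, pos) rows in RS track")
  }
  class(tr) <- c("rs_track", "data.frame")
  tr
}

#' Look up RS scores by position
#'
#' @param track an \code{rs_track}.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return Numeric vector of RS scores, NA where the position is absent
#'   from the track (absence is unknown conservation, not RS = 0).
#' @export
rs_lookup <- function(track, chrom, pos) {
  idx <- match(paste(chrom, pos), paste(track$chrom, track$pos))
  track$rs[idx]
}

#' Read a cultivar metadata table
#'
#' Tab-separated table with columns \code{cultivar},
#' \code{registration_year}, \code{breeding_period}, and optionally
#' \code{yield_source}, \code{yield_raw}, \code{yield_unit},
#' \code{adjusted_yield}. Breeding-period labels must order consistently
#' with registration years (periods are year intervals).
#'
#' @param path path to the TSV file.
#' @return data.frame, one row per cultivar.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "registration_year", "breeding_period")
  if (length(setdiff(need, names(md)))) {
    stop("metadata lacks columns: ",
         paste(setdiff(need, names(md)), collapse = ", "))
  }
  if (anyDuplicated(md$cultivar)) stop("duplicate cultivar ids in metadata")
  check_period_order(md)
  md
}

# Periods must be non-interleaving year intervals whose label sort order
# matches their year order.
check_period_order <- function(md) {
  per <- sort(unique(md$breeding_period))
  rng <- lapply(per, function(p) {
    range(md$registration_year[md$breeding_period == p])
  })
  if (length(per) > 1L) {
    for (k in seq_len(length(per) - 1L)) {
      if (rng[[k]][2] > rng[[k + 1L]][1]) {
        stop("breeding_period ordering inconsistent with registration years",
             " between ", per[k], " and ", per[k + 1L])
      }
    }
  }
  invisible(TRUE)
}

#' Validate that cohort, annotation, track and metadata inputs join
#'
#' Checks that annotation keys match cohort sites, that the RS track covers
#' at least one cohort site, and that every cohort sample has a metadata
#' row.
#'
#' @param cohort a \code{genotype_cohort}.
#' @param annotations annotation data.frame.
#' @param track an \code{rs_track}.
#' @param metadata metadata data.frame.
#' @return Invisibly, a list of join counts.
#' @export
validate_inputs <- function(cohort, annotations, track, metadata) {
  ck <- cohort_site_key(cohort)
  ak <- site_key(annotations$chrom, annotations$pos, annotations$alt)
  n_ann <- sum(ck %in% ak)
  n_rs <- sum(!is.na(rs_lookup(track, cohort$sites$chrom, cohort$sites$pos)))
  miss_md <- setdiff(cohort$samples, metadata$cultivar)
  if (length(miss_md)) {
    stop("samples missing from metadata: ",
         paste(utils::head(miss_md, 5), collapse = ", "))
  }
  if (n_ann == 0) stop("no annotation keys match cohort sites; ",
                       "check (chrom, pos, alt) conventions")
  invisible(list(n_sites = nrow(cohort$sites), n_annotated = n_ann,
                 n_with_rs = n_rs, n_samples = length(cohort$samples)))
}
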