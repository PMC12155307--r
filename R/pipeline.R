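#' Run the full screening and burden pipeline
#'
#' Orchestrates the stages simulate (optional) -> read -> validate ->
#' quality filter -> deleterious screen -> burden estimation -> diversity
#' and PCA -> trend tests, writing every stage's table plus a manifest of
#' row counts and md5 checksums into a run directory. A stage failure
#' stops the run with the stage name in the error.
#'
#' @param config a named list (or path to a YAML file readable by
#'   \pkg{yaml}) with elements:
#'   \describe{
#'     \item{out_dir}{run directory (created; required).}
#'     \item{simulate}{optional list of \code{\link{simulation_config}}
#'       arguments; when present a fixture is generated under
#'       \code{out_dir/fixture} and used as input.}
#'     \item{vcf, annotations, rs_track, metadata}{input paths (required
#'       unless \code{simulate} is given).}
#'     \item{tpm}{optional path to a genes x samples TPM matrix (TSV,
#'       first column gene id).}
#'     \item{filter}{optional list of \code{\link{filter_config}}
#'       arguments.}
#'     \item{grouping}{diversity grouping, \code{"per_period"} (default)
#'       or \code{"cumulative"}.}
#'   }
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    fixture_dir <- file.path(config$out_dir, "fixture")
    stage("simulate", {
      bundle <- simulate_cohort(do.call(simulation_config, config$simulate))
      write_fixture(bundle, fixture_dir)
    })
    config$vcf <- file.path(fixture_dir, "cohort.vcf")
    config$annotations <- file.path(fixture_dir, "annotations.tsv")
    config$rs_track <- file.path(fixture_dir, "rs_track.tsv")
    config$metadata <- file.path(fixture_dir, "metadata.tsv")
  }

  cohort <- stage("read_vcf", read_vcf(config$vcf))
  ann <- stage("read_annotations", read_annotations(config$annotations))
  track <- stage("read_rs_track", read_rs_track(config$rs_track))
  meta <- stage("read_metadata", read_metadata(config$metadata))
  stage("validate", validate_inputs(cohort, ann, track, meta))

  fcfg <- do.call(filter_config, as.list(config$filter %||% list()))
  filtered <- stage("quality_filter", apply_quality_filters(cohort, fcfg))
  catalog <- stage("screen", identify_dsnps(filtered, ann, track, fcfg))
  summary_ <- stage("summarize",
                    summarize_cohort(ann, catalog, filtered, fcfg))
  burdens <- stage("burden", estimate_burdens(filtered, catalog, meta))
  grouping <- config$grouping %||% "per_period"
  diversity <- stage("diversity",
                     diversity_by_period(filtered, meta, grouping))
  pca <- stage("pca", genotype_pca(filtered))
  trends <- stage("trends", trend_suite(burdens, meta))
  expr_fit <- if (!is.null(config$tpm)) {
    stage("expression", {
      tpm <- as.matrix(read.delim(config$tpm, row.names = 1,
                                  check.names = FALSE))
      expression_trend(tpm, meta)
    })
  } else NULL

  out <- config$out_dir
  files <- c(
    catalog = write_tsv(as.data.frame(catalog), file.path(out, "catalog.tsv")),
    burdens = write_tsv(as.data.frame(burdens), file.path(out, "burdens.tsv")),
    diversity = write_tsv(diversity$periods, file.path(out, "diversity.tsv")),
    pca = write_tsv(data.frame(cultivar = rownames(pca$coords),
                               pca$coords, check.names = FALSE),
                    file.path(out, "pca.tsv")),
    trends = write_tsv(as.data.frame(trends), file.path(out, "trends.tsv"))
  )
  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(summary_to_list(summary_), summary_path,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, summary = summary_path)
  if (!is.null(expr_fit)) {
    p <- file.path(out, "expression_trend.tsv")
    files <- c(files, expression = write_tsv(
      as.data.frame.trend_fit(expr_fit), p))
  }

  manifest <- data.frame(
    file = basename(unname(files)),
    rows = vapply(files, function(f) length(readLines(f)) - 1L, integer(1)),
    md5 = unname(tools::md5sum(unname(files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = filtered, catalog = catalog, summary = summary_,
                 burdens = burdens, diversity = diversity, pca = pca,
                 trends = trends, expression = expr_fit,
                 manifest = manifest, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

summary_to_list <- function(s) {
  list(
    total_snps = s$total_snps,
    class_counts = as.list(s$class_counts),
    lof = s$lof,
    sift_deleterious = s$sift_deleterious,
    catalog = s$catalog,
    fixed = s$fixed,
    per_chromosome = list(min = s$per_chromosome$min,
                          max = s$per_chromosome$max,
                          mean = s$per_chromosome$mean),
    severity_counts = as.list(s$severity_counts),
    maf_spectrum = as.list(s$maf_spectrum),
    maf_le_0.05 = s$maf_le_0.05,
    maf_le_0.01 = s$maf_le_0.01
  )
}
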