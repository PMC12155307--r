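#' Ordinary least-squares trend of a per-sample statistic
#'
#' Fits y ~ x by OLS (via \code{stats::lm}) and reports the slope, its
#' standard error, the two-sided t-test of slope = 0, and R-squared.
#' Pairs with a missing value in either variable are dropped with a
#' message. A response with zero variance is a degenerate fit: it is
#' returned with slope 0, R-squared 0, p = 1 and \code{degenerate = TRUE}
#' rather than an error, since a flat response is a meaningful "no trend"
#' outcome.
#'
#' @param x numeric predictor (e.g. registration year or yield).
#' @param y numeric response (e.g. total burden).
#' @param response,predictor names recorded in the result.
#' @return list of class \code{trend_fit}: \code{response},
#'   \code{predictor}, \code{n}, \code{slope}, \code{intercept},
#'   \code{se}, \code{t}, \code{p}, \code{r_squared}, \code{degenerate}.
#' @export
fit_trend <- function(x, y, response = "y", predictor = "x") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(!ok) > 0) {
    message("fit_trend: dropping ", sum(!ok), " incomplete pair(s)")
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fit_trend needs at least 3 complete pairs")
  if (var(x) == 0) stop("predictor has zero variance")
  if (var(y) == 0) {
    return(structure(list(
      response = response, predictor = predictor, n = n,
      slope = 0, intercept = mean(y), se = 0, t = NA_real_, p = 1,
      r_squared = 0, degenerate = TRUE
    ), class = "trend_fit"))
  }
  fit <- lm(y ~ x)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  structure(list(
    response = response, predictor = predictor, n = n,
    slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
    se = co["x", "Std. Error"], t = co["x", "t value"],
    p = co["x", "Pr(>|t|)"], r_squared = sm$r.squared,
    degenerate = FALSE
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> ", x$response, " ~ ", x$predictor, " (n = ", x$n, ")\n",
      "  slope ", signif(x$slope, 4), " (se ", signif(x$se, 3),
      "), p = ", format.pval(x$p, digits = 3),
      ", R2 = ", signif(x$r_squared, 3),
      if (x$degenerate) "  [degenerate: flat response]" else "",
      "\n", sep = "")
  invisible(x)
}

as.data.frame.trend_fit <- function(x, ...) {
  data.frame(response = x$response, predictor = x$predictor, n = x$n,
             slope = x$slope, intercept = x$intercept, se = x$se,
             t = x$t, p = x$p, r_squared = x$r_squared,
             degenerate = x$degenerate, stringsAsFactors = FALSE)
}

#' Trend tests of the three burdens on year and yield
#'
#' Runs the six regressions \{total, heterozygous, homozygous\} burden on
#' \{registration year, adjusted yield\}. Samples without a yield are
#' dropped from the yield fits (with a message). P-values are nominal; no
#' multiple-testing correction is applied across the six fits.
#'
#' @param burdens a \code{burden_estimates} data.frame.
#' @param metadata metadata with \code{cultivar}, \code{registration_year}
#'   and \code{adjusted_yield}.
#' @return data.frame with one row per fit (class \code{trend_suite}).
#' @export
trend_suite <- function(burdens, metadata) {
  j <- match(burdens$cultivar, metadata$cultivar)
  if (any(is.na(j))) {
    stop("cultivars missing from metadata: ",
         paste(utils::head(burdens$cultivar[is.na(j)], 5), collapse = ", "))
  }
  year <- metadata$registration_year[j]
  yield <- if ("adjusted_yield" %in% names(metadata)) {
    metadata$adjusted_yield[j]
  } else rep(NA_real_, length(j))
  responses <- c(total = "total_burden", het = "het_burden",
                 hom = "hom_burden")
  rows <- list()
  for (rn in names(responses)) {
    y <- burdens[[responses[rn]]]
    rows[[paste0(rn, "_year")]] <- as.data.frame.trend_fit(
      fit_trend(year, y, response = responses[rn], predictor = "year"))
    if (any(is.finite(yield))) {
      rows[[paste0(rn, "_yield")]] <- as.data.frame.trend_fit(
        fit_trend(yield, y, response = responses[rn], predictor = "yield"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_suite", "data.frame")
  out
}

#' Harmonize a yield across report sources via bridge cultivars
#'
#' A cultivar reported only in source B is rescaled onto source A's scale
#' through cultivars present in both reports: each bridge gives the
#' candidate (target_B / bridge_B) x bridge_A, and candidates are
#' aggregated across bridges. With \code{method = "mean_of_candidates"}
#' (default) the result is the arithmetic mean of the per-bridge
#' candidates; \code{"ratio_of_means"} scales by the ratio of bridge
#' means instead. The two agree whenever all bridge ratios are equal.
#'
#' @param target_yield the cultivar's yield in source B (positive).
#' @param bridges data.frame with columns \code{yield_b} and
#'   \code{yield_a}: each bridge cultivar's yields in sources B and A.
#' @param method aggregation rule across bridges.
#' @return The adjusted yield on source A's scale.
#' @export
adjust_yield <- function(target_yield, bridges,
                         method = c("mean_of_candidates", "ratio_of_means")) {
  method <- match.arg(method)
  if (!is.data.frame(bridges) || nrow(bridges) == 0L) {
    stop("empty bridge set: need at least one cultivar in both reports")
  }
  if (!all(c("yield_b", "yield_a") %in% names(bridges))) {
    stop("bridges must have columns yield_b and yield_a")
  }
  if (any(bridges$yield_b <= 0) || any(bridges$yield_a <= 0) ||
      target_yield <= 0) {
    stop("yields must be positive")
  }
  switch(method,
    mean_of_candidates = mean(target_yield / bridges$yield_b *
                                bridges$yield_a),
    ratio_of_means = target_yield / mean(bridges$yield_b) *
      mean(bridges$yield_a)
  )
}

#' Convert a grain yield between lb/ac and bu/ac
#'
#' Standard bushel weights: 32 lb for oats, 60 lb for wheat.
#'
#' @param value yield value.
#' @param crop \code{"oat"} or \code{"wheat"}.
#' @param from unit of \code{value}, \code{"lb/ac"} or \code{"bu/ac"}.
#' @return yield in the other unit.
#' @export
convert_yield_unit <- function(value, crop = c("oat", "wheat"),
                               from = c("lb/ac", "bu/ac")) {
  crop <- match.arg(crop)
  from <- match.arg(from)
  lb_per_bu <- c(oat = 32, wheat = 60)[[crop]]
  if (from == "lb/ac") value / lb_per_bu else value * lb_per_bu
}

#' Trend of mean expression of catalog-associated genes on year
#'
#' Averages TPM across the supplied genes for each sample and regresses
#' the per-sample mean on registration year.
#'
#' @param tpm numeric matrix, genes x samples (column names are cultivar
#'   ids), restricted to the genes associated with catalog sites.
#' @param metadata metadata with \code{cultivar} and
#'   \code{registration_year}.
#' @return A \code{trend_fit} of mean TPM on year.
#' @export
expression_trend <- function(tpm, metadata) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) == 0L) stop("empty gene set")
  j <- match(colnames(tpm), metadata$cultivar)
  if (any(is.na(j))) {
    stop("TPM columns missing from metadata: ",
         paste(utils::head(colnames(tpm)[is.na(j)], 5), collapse = ", "))
  }
  mean_tpm <- colMeans(tpm)
  fit_trend(metadata$registration_year[j], mean_tpm,
            response = "mean_tpm", predictor = "year")
}
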