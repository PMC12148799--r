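#' Bundle one site's results for aggregation
#'
#' A light container pairing a site label and protocol with whatever metric
#' results were computed for it. Only `calibration` is required by the
#' cohort summary; the remaining slots ride along into serialized reports.
#'
#' @param site site label.
#' @param protocol protocol name (must match across aggregated reports).
#' @param calibration a [measure_rods()] curve.
#' @param fit optional [fit_piecewise()] result (computed from `calibration`
#'   when omitted).
#' @param uniformity,cnr,geometry,mtf,ct_numbers optional metric results.
#' @return list of class `site_report`.
#' @export
site_report <- function(site, protocol, calibration, fit = NULL,
                        uniformity = NULL, cnr = NULL, geometry = NULL,
                        mtf = NULL, ct_numbers = NULL) {
  if (is.null(fit)) fit <- fit_piecewise(calibration)
  structure(list(site = site, protocol = protocol, calibration = calibration,
                 fit = fit, uniformity = uniformity, cnr = cnr,
                 geometry = geometry, mtf = mtf, ct_numbers = ct_numbers),
            class = "site_report")
}

#' Multi-site cohort summary
#'
#' Combines site reports sharing one protocol into the cross-institution
#' summary: per-RED median and sample sd of HU across sites, the maximum
#' absolute z-score per RED (the outlier screen), and the high-branch
#' calibration slope aggregated both ways — as mean and sd of the per-site
#' slopes and as a single pooled ordinary-least-squares fit on all sites'
#' points — since either convention is defensible for small cohorts.
#'
#' @param reports list of [site_report()]s (>= 3, same protocol).
#' @return list of class `cohort_summary` with `protocol`, `n_sites`,
#'   `per_red` (data frame: `red`, `median_hu`, `sd_hu`, `max_abs_z`),
#'   `slope_mean`, `slope_sd`, `slope_pooled`, `intercept_pooled` (RED/HU).
#' @export
summarize_cohort <- function(reports) {
  stopifnot(length(reports) >= 3L)
  protocols <- vapply(reports, function(r) r$protocol %||% NA_character_, "")
  if (length(unique(protocols)) != 1L) {
    stop("reports mix protocols: ", paste(unique(protocols), collapse = ", "))
  }
  reds <- reports[[1L]]$calibration$points$red
  hu_mat <- vapply(reports, function(r) {
    p <- r$calibration$points
    if (!isTRUE(all.equal(p$red, reds))) stop("reports disagree on RED values")
    p$mean_hu
  }, numeric(length(reds)))

  per_red <- data.frame(
    red = reds,
    median_hu = apply(hu_mat, 1L, stats::median),
    sd_hu = apply(hu_mat, 1L, stats::sd),
    max_abs_z = apply(hu_mat, 1L, function(x) {
      if (stats::sd(x) == 0) NA_real_ else max_abs_zscore(x)
    })
  )

  slopes <- vapply(reports, function(r) r$fit$slope_high, 0.0)
  hi <- reds >= 1
  pooled <- stats::lm(red ~ hu, data = data.frame(
    red = rep(reds[hi], ncol(hu_mat)),
    hu = as.vector(hu_mat[hi, ])
  ))

  structure(list(
    protocol = protocols[1L],
    n_sites = length(reports),
    per_red = per_red,
    slope_mean = mean(slopes),
    slope_sd = stats::sd(slopes),
    slope_pooled = unname(stats::coef(pooled)[2L]),
    intercept_pooled = unname(stats::coef(pooled)[1L]),
    sd_convention = "across-site sample sd (n-1); within-site ROI sd not folded in"
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s, %d sites\n", x$protocol, x$n_sites))
  print(x$per_red, row.names = FALSE, digits = 4)
  cat(sprintf("high-branch slope: %.1f +/- %.1f e-6 RED/HU (site mean), %.1f e-6 (pooled)\n",
              x$slope_mean * 1e6, x$slope_sd * 1e6, x$slope_pooled * 1e6))
  invisible(x)
}

#' Export a cohort summary
#'
#' JSON serializes the whole summary losslessly; CSV writes the calibration
#' table (one row per RED).
#'
#' @param summary a [summarize_cohort()] result.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
export_report <- function(summary, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  } else {
    utils::write.csv(summary$per_red, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON cohort summary
#'
#' @param path path written by [export_report()].
#' @return a `cohort_summary`.
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_red <- as.data.frame(obj$per_red)
  structure(obj, class = "cohort_summary")
}
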