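#' Summary statistics for a per-sphere metric
#'
#' Mean, median, standard deviation and coefficient of variation
#' (CV = SD / sample mean, dimensionless) over per-microdomain values.
#' Under `rule = "mam_positive_only"` the values whose `mam_positive` flag is
#' FALSE are omitted before computing anything: microdomains without
#' mitochondria show no MAM, and treating their area as zero instead of
#' missing would distort the mean. The SD uses the sample (n - 1)
#' denominator by default; `sd_type = "population"` is available for
#' sensitivity checks.
#'
#' @param values numeric vector of per-sphere values.
#' @param rule `"all"` or `"mam_positive_only"`.
#' @param mam_positive logical vector parallel to `values`; required for the
#'   `mam_positive_only` rule.
#' @param metric_name label carried into reports.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return A `summary_stats` list: `metric, inclusion_rule, n, mean, median,
#'   sd, cv`. With n = 1 the SD and CV are NA; with mean 0 the CV is NA.
#' @examples
#' summarize_metric(c(107, 87, 127))$cv
#' @export
summarize_metric <- function(values, rule = c("all", "mam_positive_only"),
                             mam_positive = NULL,
                             metric_name = "metric",
                             sd_type = c("sample", "population")) {
  rule <- match.arg(rule)
  sd_type <- match.arg(sd_type)
  values <- as.numeric(values)
  if (rule == "mam_positive_only") {
    if (is.null(mam_positive) || length(mam_positive) != length(values)) {
      stop("rule 'mam_positive_only' needs a mam_positive flag per value")
    }
    values <- values[as.logical(mam_positive)]
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    stop(sprintf("no values left to summarize under rule '%s'", rule))
  }
  m <- mean(values)
  s <- if (n > 1) {
    if (sd_type == "sample") stats::sd(values)
    else sqrt(mean((values - m)^2))
  } else NA_real_
  cv <- if (!is.na(s) && m != 0) s / m else NA_real_
  structure(list(metric = metric_name, inclusion_rule = rule, n = n,
                 mean = m, median = stats::median(values), sd = s, cv = cv),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("%s [%s]: n = %d, mean = %.4g, median = %.4g, sd = %.4g, cv = %.2f\n",
              x$metric, x$inclusion_rule, x$n, x$mean, x$median,
              ifelse(is.na(x$sd), NA, x$sd), ifelse(is.na(x$cv), NA, x$cv)))
  invisible(x)
}

summary_stats_row <- function(s) {
  data.frame(metric = s$metric, inclusion_rule = s$inclusion_rule, n = s$n,
             mean = s$mean, median = s$median, sd = s$sd, cv = s$cv)
}

#' Write per-sphere and summary CSVs
#'
#' `per_sphere.csv` holds one row per microdomain (`sphere_id, asd_nm,
#' n_pm_vertices, er_volume_nm3, has_mito, mam_area_total_nm2,
#' n_proximity_events`; MAM area is empty, not zero, for mitochondrion-free
#' spheres). `summary.csv` holds one row per metric: ER volume and ASD over
#' all spheres, MAM area over MAM-positive spheres only. `provenance.json`
#' records radius, seed, thresholds and package version so a rerun with the
#' same inputs is byte-identical.
#'
#' @param per_sphere data.frame as produced by [analyze_microdomains()].
#' @param dir output directory (created if missing).
#' @param provenance named list merged into `provenance.json`.
#' @return Invisible list of written paths.
#' @export
report_microdomains <- function(per_sphere, dir, provenance = list()) {
  if (nrow(per_sphere) < 1) stop("need at least one per-sphere record")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_path <- file.path(dir, "per_sphere.csv")
  sum_path <- file.path(dir, "summary.csv")
  prov_path <- file.path(dir, "provenance.json")

  utils::write.csv(per_sphere, per_path, row.names = FALSE, na = "")

  summaries <- summarize_microdomains(per_sphere)
  utils::write.csv(do.call(rbind, lapply(summaries, summary_stats_row)),
                   sum_path, row.names = FALSE, na = "")

  prov <- c(provenance,
            list(software = "microdomain3d",
                 version = as.character(utils::packageVersion("microdomain3d"))))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(per_sphere = per_path, summary = sum_path,
                 provenance = prov_path))
}

#' Standard metric summaries for a per-sphere table
#'
#' @param per_sphere data.frame from [analyze_microdomains()].
#' @param sd_type passed to [summarize_metric()].
#' @return Named list of `summary_stats`: `er_volume`, `asd`, `mam_area`
#'   (the last only when any sphere is MAM-positive).
#' @export
summarize_microdomains <- function(per_sphere, sd_type = "sample") {
  out <- list(
    er_volume = summarize_metric(per_sphere$er_volume_nm3, "all",
                                 metric_name = "er_volume_nm3",
                                 sd_type = sd_type),
    asd = summarize_metric(per_sphere$asd_nm, "all", metric_name = "asd_nm",
                           sd_type = sd_type))
  pos <- per_sphere$has_mito & !is.na(per_sphere$mam_area_total_nm2)
  if (any(pos)) {
    out$mam_area <- summarize_metric(per_sphere$mam_area_total_nm2,
                                     "mam_positive_only", mam_positive = pos,
                                     metric_name = "mam_area_nm2",
                                     sd_type = sd_type)
  }
  out
}
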