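#' Image and dose accuracy assessment
#'
#' Voxelwise difference statistics, cumulative dose-volume histograms and
#' D_x metrics, the relative accuracy error
#' `Acc_x = |D_x - D_x^GT| / D_x^GT x 100`, rank-sum testing, signed
#' dose-difference maps and study-report assembly.
#'
#' @name evaluation
NULL

#' Voxelwise difference statistics
#'
#' Mean, population standard deviation (divide by n), min and max of
#' `a - b` restricted to a region.
#'
#' @param a,b `ct_volume`s on the same grid.
#' @param region mask `ct_volume` (nonempty).
#' @return list of class `diff_stats`: `mean`, `std`, `min`, `max`, `n`.
#' @export
diff_stats <- function(a, b, region) {
  stop_grid_mismatch(a, b)
  stop_grid_mismatch(a, region)
  if (!any(region$data)) stop("empty region")
  d <- (a$data - b$data)[region$data]
  structure(list(mean = mean(d),
                 std = sqrt(mean((d - mean(d))^2)),
                 min = min(d), max = max(d), n = length(d)),
            class = "diff_stats")
}

#' @export
print.diff_stats <- function(x, ...) {
  cat(sprintf("diff: %.3f +/- %.3f (range %.3f .. %.3f, n = %d)\n",
              x$mean, x$std, x$min, x$max, x$n))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' `V(d)` = fraction of structure voxels receiving at least dose `d`,
#' evaluated at bin edges `0, bw, 2 bw, ...` up to the maximum dose.
#'
#' @param dose dose `ct_volume` (Gy).
#' @param mask structure mask `ct_volume` (nonempty).
#' @param bin_gy bin width in Gy, default 0.05.
#' @return list of class `dvh`: `dose` (bin edges, Gy) and `volume`
#'   (fraction in `[0, 1]`, non-increasing, starts at 1).
#' @export
cumulative_dvh <- function(dose, mask, bin_gy = 0.05) {
  stop_grid_mismatch(dose, mask)
  if (!any(mask$data)) stop("empty structure mask")
  dv <- dose$data[mask$data]
  edges <- seq(0, max(dv) + bin_gy, by = bin_gy)
  vol <- vapply(edges, function(e) mean(dv >= e), numeric(1))
  structure(list(dose = edges, volume = vol, doses = dv), class = "dvh")
}

#' Dose received by at least x percent of the structure
#'
#' `D_x = max(d : V(d) >= x/100)` with linear interpolation between DVH bin
#' edges; `D_100` is the structure minimum dose.
#'
#' @param dvh a `dvh`.
#' @param x percent volume, in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  if (x == 100) return(min(dvh$doses))
  v <- x / 100
  ok <- dvh$volume >= v
  if (!any(ok)) return(dvh$dose[1])
  i <- max(which(ok))
  if (i == length(dvh$dose)) return(dvh$dose[i])
  # interpolate within the bin where V crosses v
  v0 <- dvh$volume[i]; v1 <- dvh$volume[i + 1]
  if (v1 == v0) return(dvh$dose[i])
  dvh$dose[i] + (dvh$dose[i + 1] - dvh$dose[i]) * (v0 - v) / (v0 - v1)
}

#' Relative accuracy error
#'
#' `Acc = |d - d_gt| / d_gt x 100` (percent).
#'
#' @param d evaluated dose metric (Gy).
#' @param d_gt ground-truth dose metric (Gy, > 0).
#' @return percent error.
#' @export
accuracy_error <- function(d, d_gt) {
  if (any(d_gt <= 0)) stop("ground-truth dose must be positive")
  abs(d - d_gt) / d_gt * 100
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Mann-Whitney U with midrank ties; exact two-sided p when
#' `min(n, m) <= 8` and there are no ties, otherwise normal approximation
#' with tie and continuity correction (via [stats::wilcox.test()]).
#'
#' @param a,b numeric samples (nonempty).
#' @return list of class `rank_sum_result`: `U`, `p`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal-approximation"),
            class = "rank_sum_result")
}

#' Signed dose-difference map
#'
#' @param a,b dose `ct_volume`s on the same grid.
#' @param region optional mask for the extremes (default whole grid).
#' @return list: `map` (`ct_volume`, `a - b`), `min`, `max` over region.
#' @export
dose_difference_map <- function(a, b, region = NULL) {
  stop_grid_mismatch(a, b)
  m <- a
  m$data <- a$data - b$data
  m$kind <- "dose-difference"
  sel <- if (is.null(region)) rep(TRUE, length(m$data)) else region$data
  list(map = m, min = min(m$data[sel]), max = max(m$data[sel]))
}

# D95/D98/D100 + Acc vs a ground-truth set of metrics
dose_metrics <- function(dose, mask, bin_gy = 0.05) {
  dvh <- cumulative_dvh(dose, mask, bin_gy)
  xs <- c(95, 98, 100)
  d <- vapply(xs, function(x) dose_at_volume(dvh, x), numeric(1))
  names(d) <- paste0("D", xs)
  d
}

#' Assemble the study report
#'
#' Collects, for every configuration and PTV, the image-difference
#' statistics, the D95/D98/D100 metrics of the uncorrected/corrected/GT
#' dose volumes, the relative accuracy errors versus ground truth, the
#' rank-sum comparison of corrected vs GT PTV dose, and the
#' dose-difference extremes over the body.
#'
#' @param datasets named list (per configuration) with elements
#'   `uncorrected`, `corrected`, `gt` (HU `ct_volume`s), `body` and
#'   `metal` masks.
#' @param plans named list (per configuration) of per-PTV lists with
#'   elements `ptv` (mask), `plan`, `fluence`, and `doses` (named list
#'   `uncorrected`, `corrected`, `gt` of dose volumes).
#' @param config named list of provenance entries (seeds, config hash);
#'   stored verbatim.
#' @param bin_gy DVH bin width.
#' @return list of class `study_report`.
#' @export
evaluate_study <- function(datasets, plans, config = list(), bin_gy = 0.05) {
  image <- list(); dose <- list()
  for (cfg in names(datasets)) {
    ds <- datasets[[cfg]]
    for (need in c("uncorrected", "corrected", "gt", "body"))
      if (is.null(ds[[need]]))
        stop("missing artifact '", need, "' for configuration ", cfg)
    region <- ds$body
    if (!is.null(ds$metal)) {
      region$data <- region$data & !ds$metal$data
    }
    image[[cfg]] <- list(
      uncorrected_vs_gt = diff_stats(ds$uncorrected, ds$gt, region),
      corrected_vs_gt = diff_stats(ds$corrected, ds$gt, region))
    pl <- plans[[cfg]]
    if (is.null(pl)) stop("missing artifact 'plans' for configuration ", cfg)
    dose[[cfg]] <- lapply(pl, function(p) {
      m_unc <- dose_metrics(p$doses$uncorrected, p$ptv, bin_gy)
      m_cor <- dose_metrics(p$doses$corrected, p$ptv, bin_gy)
      m_gt <- dose_metrics(p$doses$gt, p$ptv, bin_gy)
      dd_unc <- dose_difference_map(p$doses$gt, p$doses$uncorrected, ds$body)
      dd_cor <- dose_difference_map(p$doses$gt, p$doses$corrected, ds$body)
      rs <- rank_sum_test(p$doses$corrected$data[p$ptv$data],
                          p$doses$gt$data[p$ptv$data])
      list(metrics = list(uncorrected = m_unc, corrected = m_cor, gt = m_gt),
           acc = list(uncorrected = accuracy_error(m_unc, m_gt),
                      corrected = accuracy_error(m_cor, m_gt)),
           diff_extremes = list(
             uncorrected = c(min = dd_unc$min, max = dd_unc$max),
             corrected = c(min = dd_cor$min, max = dd_cor$max)),
           rank_sum = list(U = rs$U, p = rs$p, method = rs$method))
    })
  }
  structure(list(image = image, dose = dose, provenance = config),
            class = "study_report")
}

#' Flatten a study report's accuracy errors to a table
#'
#' One row per configuration x PTV x dataset x metric, shaped like the
#' usual Acc_x summary table (values in percent, reported to 2 decimals in
#' the CSV written by [write_report()]).
#'
#' @param report a `study_report`.
#' @return data.frame with columns `configuration`, `ptv`, `dataset`,
#'   `metric`, `acc_percent`.
#' @export
report_acc_table <- function(report) {
  rows <- list()
  for (cfg in names(report$dose)) for (ptv in names(report$dose[[cfg]])) {
    acc <- report$dose[[cfg]][[ptv]]$acc
    for (dsn in names(acc)) for (m in names(acc[[dsn]])) {
      rows[[length(rows) + 1]] <- data.frame(
        configuration = cfg, ptv = ptv, dataset = dsn,
        metric = sub("^D", "Acc", m),
        acc_percent = unname(acc[[dsn]][m]))
    }
  }
  do.call(rbind, rows)
}

#' Write a study report to JSON and CSV
#'
#' The JSON is machine-readable and deterministic given identical inputs
#' (fixed float formatting, no timestamps); the CSV mirrors the accuracy
#' table with Acc values rounded to 2 decimals.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_deep(report), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tab <- report_acc_table(report)
  tab$acc_percent <- sprintf("%.2f", tab$acc_percent)
  csv <- file.path(dir, "accuracy.csv")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  invisible(c(json, csv))
}

# strip S3 classes recursively so jsonlite serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (cfg in names(x$image)) {
    im <- x$image[[cfg]]
    cat(sprintf("  %s image diff vs GT: uncorrected %.1f +/- %.1f HU, corrected %.1f +/- %.1f HU\n",
                cfg, im$uncorrected_vs_gt$mean, im$uncorrected_vs_gt$std,
                im$corrected_vs_gt$mean, im$corrected_vs_gt$std))
  }
  tab <- report_acc_table(x)
  worst <- tab[order(-tab$acc_percent), ][1, ]
  cat(sprintf("  36-entry accuracy table; worst: %s %s %s %s = %.2f%%\n",
              worst$configuration, worst$ptv, worst$dataset, worst$metric,
              worst$acc_percent))
  invisible(x)
}
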