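# Filter comparison metrics: confusion counts against Monte Carlo truth,
# ROC curves over threshold sweeps, ROI noise statistics and RSP accuracy.

#' Confusion counts of a filter against Monte Carlo truth
#'
#' Rejection is the positive call: true positives are secondaries
#' (nuclear-elastic, nuclear-inelastic or fragment histories) correctly
#' rejected, false negatives secondaries accepted, true negatives primaries
#' accepted, false positives primaries rejected. Sensitivity is the
#' fraction of secondaries rejected, specificity the fraction of primaries
#' retained.
#'
#' @param mask Filter mask (`accept` logical, one row per event).
#' @param labels Truth labels (`primary` or any secondary label); events
#'   labelled `"unknown"` raise an error.
#' @return List of class `confusion` with `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`.
#' @export
confusion <- function(mask, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(mask)) stop("confusion: labels and mask differ in length")
  if (any(is.na(labels)) || any(labels == "unknown"))
    stop("confusion: events without truth labels cannot be evaluated")
  sec <- labels != "primary"
  rej <- !mask$accept
  out <- list(tp = sum(sec & rej), fn = sum(sec & !rej),
              tn = sum(!sec & !rej), fp = sum(!sec & rej))
  out$sensitivity <- if (out$tp + out$fn > 0) out$tp / (out$tp + out$fn) else NA_real_
  out$specificity <- if (out$tn + out$fp > 0) out$tn / (out$tn + out$fp) else NA_real_
  structure(out, class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d FN %d TN %d FP %d | sensitivity %.3f specificity %.3f\n",
              x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity))
  invisible(x)
}

#' ROC curve of a filter family over a threshold sweep
#'
#' Evaluates sensitivity and specificity at each threshold of the chosen
#' filter family. For the sigma filter the pixel statistics are computed
#' once and reused across thresholds; for the likelihood filter a
#' [prior_predict()] result must be supplied (or `prior` given, from which
#' it is computed once).
#'
#' @param events Labelled event `data.frame`.
#' @param family `"sigma"` or `"prior"`.
#' @param thresholds Threshold grid: `sigma_t` values (default 0.5 to 10 by
#'   0.5) or `Pt` values (default 0.05 to 0.95 by 0.05).
#' @param prediction Precomputed [prior_predict()] result (prior family).
#' @param prior An [rsp_image()], used when `prediction` is missing.
#' @param ... Further arguments to [sigma_filter()] / [prior_filter()].
#' @return `data.frame` with `threshold`, `sensitivity`, `specificity` and
#'   `fpr` (= 1 - specificity), ordered by threshold.
#' @export
roc_curve <- function(events, family = c("sigma", "prior"), thresholds = NULL,
                      prediction = NULL, prior = NULL, ...) {
  family <- match.arg(family)
  labels <- as.character(events$label)
  if (any(labels == "unknown")) stop("roc_curve: unlabelled events")
  if (!any(labels != "primary")) {
    warning("roc_curve: no secondaries in the truth; sensitivity undefined")
  }
  if (is.null(thresholds))
    thresholds <- if (family == "sigma") seq(0.5, 10, by = 0.5) else seq(0.05, 0.95, by = 0.05)
  if (length(thresholds) < 2) stop("roc_curve: need at least two thresholds")
  if (family == "sigma") {
    pr <- .sigma_prepare(events, ...)
    masks <- lapply(thresholds, function(s) .sigma_apply(pr, s))
  } else {
    if (is.null(prediction)) {
      if (is.null(prior)) stop("roc_curve: prior or prediction required for the prior family")
      prediction <- prior_predict(events, prior, ...)
    }
    masks <- lapply(thresholds, function(p)
      prior_filter(events, prior = NULL, Pt = p, prediction = prediction))
  }
  res <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    cf <- confusion(masks[[i]], labels)
    data.frame(threshold = thresholds[i], sensitivity = cf$sensitivity,
               specificity = cf$specificity)
  }))
  res$fpr <- 1 - res$specificity
  res
}

#' Mean noise in a circular region of interest
#'
#' @param map A `tomo_grid` (noise or RSP map).
#' @param center ROI centre `c(x, y)` in mm.
#' @param diameter ROI diameter in mm (default 20).
#' @return Mean of the map over the disk.
#' @export
roi_noise <- function(map, center = c(0, 0), diameter = 20) {
  r <- diameter / 2
  if (center[1] - r < min(map$x) - map$pixel / 2 ||
      center[1] + r > max(map$x) + map$pixel / 2 ||
      center[2] - r < min(map$y) - map$pixel / 2 ||
      center[2] + r > max(map$y) + map$pixel / 2)
    stop("roi_noise: ROI extends outside the map")
  dx <- outer(map$x - center[1], rep(1, length(map$y)))
  dy <- outer(rep(1, length(map$x)), map$y - center[2])
  disk <- dx^2 + dy^2 <= r^2
  if (!any(disk)) return(map$values[which.min(dx^2 + dy^2)])
  mean(map$values[disk])
}

#' RSP accuracy table over phantom inserts
#'
#' Mean and standard deviation of the reconstructed RSP in a cylindrical
#' ROI centred on each insert, with the percent error against the
#' reference RSP and the mean absolute percentage error (MAPE) of the
#' reconstruction.
#'
#' @param tomo A `tomo_grid` RSP map (central slice).
#' @param inserts `data.frame` with `x`, `y`, `rsp` (reference) and
#'   optionally `name`.
#' @param roi_diameter ROI diameter in mm (default 8).
#' @return `data.frame` with one row per insert (`name`, `reference`,
#'   `measured`, `sd`, `pct_error`); the MAPE is attached as attribute
#'   `"mape"`.
#' @export
rsp_error_table <- function(tomo, inserts, roi_diameter = 8) {
  r <- roi_diameter / 2
  rows <- lapply(seq_len(nrow(inserts)), function(i) {
    cx <- inserts$x[i]; cy <- inserts$y[i]
    if (cx - r < min(tomo$x) || cx + r > max(tomo$x) ||
        cy - r < min(tomo$y) || cy + r > max(tomo$y))
      stop("rsp_error_table: insert ROI outside the grid")
    dx <- outer(tomo$x - cx, rep(1, length(tomo$y)))
    dy <- outer(rep(1, length(tomo$x)), tomo$y - cy)
    disk <- dx^2 + dy^2 <= r^2
    vals <- tomo$values[disk]
    data.frame(
      name = if (!is.null(inserts$name)) inserts$name[i] else sprintf("insert-%d", i),
      reference = inserts$rsp[i],
      measured = mean(vals), sd = stats::sd(vals),
      pct_error = 100 * (mean(vals) - inserts$rsp[i]) / inserts$rsp[i]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "mape") <- mean(abs(out$pct_error))
  out
}
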