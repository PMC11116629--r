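#' Normalize ventricular areas to the negative-control mean
#'
#' The regeneration-kinetics readout: at each timepoint, every larva's
#' fluorescent ventricular area is expressed as a percentage of the control
#' group's mean at that timepoint, so the control mean is pinned to exactly
#' 100. Outliers are flagged first with the ROUT method (Q, per group and
#' timepoint, [rout_outliers()]) and excluded from the control mean (and from
#' downstream summaries); flagged rows keep their normalized value for
#' inspection.
#'
#' @param areas data.frame with columns `well, group, timepoint, area_um2`
#'   (e.g. from [segment_plate()]; extra columns are carried along).
#' @param control_group reference group label.
#' @param rout_q ROUT false-discovery level Q (default 0.01, i.e. Q = 1%);
#'   `NULL` disables outlier removal.
#' @return the input with `normalized_area` (% of control mean) and
#'   `outlier_flag` columns; the per-timepoint control means are attached as
#'   attribute `"control_means"`.
#' @export
normalize_to_control <- function(areas, control_group = "negative_control",
                                 rout_q = 0.01) {
  required <- c("well", "group", "timepoint", "area_um2")
  miss <- setdiff(required, names(areas))
  if (length(miss)) stop("areas lacks column(s): ", paste(miss, collapse = ", "))
  if (!control_group %in% areas$group)
    stop("control group not present: ", control_group)
  areas$outlier_flag <- FALSE
  if (!is.null(rout_q)) {
    for (g in unique(areas$group)) {
      for (tp in unique(areas$timepoint)) {
        sel <- which(areas$group == g & areas$timepoint == tp)
        if (length(sel) >= 3)
          areas$outlier_flag[sel] <-
            rout_outliers(areas$area_um2[sel], Q = rout_q)$outlier_flag
      }
    }
  }
  tps <- unique(areas$timepoint)
  ctrl_means <- setNames(numeric(length(tps)), tps)
  areas$normalized_area <- NA_real_
  for (tp in tps) {
    ctrl <- areas$group == control_group & areas$timepoint == tp &
      !areas$outlier_flag
    if (!any(ctrl)) stop("no non-outlier control larvae at timepoint ", tp)
    m <- mean(areas$area_um2[ctrl])
    if (m == 0) stop("control mean is zero at timepoint ", tp)
    ctrl_means[tp] <- m
    sel <- areas$timepoint == tp
    areas$normalized_area[sel] <- 100 * areas$area_um2[sel] / m
  }
  attr(areas, "control_means") <- ctrl_means
  areas
}

#' Longitudinal per-larva trajectories
#'
#' Reshapes a kinetics table into one row per well with one column per
#' timepoint. Larvae lost between timepoints (dropout is expected in a live
#' longitudinal assay) keep `NA` gaps, never imputed values; a dropout report
#' is attached.
#'
#' @param kinetics table from [normalize_to_control()].
#' @param value column to spread (default `"normalized_area"`).
#' @return wide data.frame `well, group, <TP1>, <TP2>, ...`, with attribute
#'   `"dropout"` (wells missing at least one timepoint and the number of
#'   gaps).
#' @export
track_larvae <- function(kinetics, value = "normalized_area") {
  stopifnot(value %in% names(kinetics))
  tps <- unique(kinetics$timepoint)
  wells <- unique(kinetics[, c("well", "group")])
  wide <- wells
  for (tp in tps) {
    sub <- kinetics[kinetics$timepoint == tp, c("well", value)]
    names(sub)[2] <- tp
    wide <- merge(wide, sub, by = "well", all.x = TRUE, sort = FALSE)
  }
  gaps <- rowSums(is.na(wide[, tps, drop = FALSE]))
  attr(wide, "dropout") <- data.frame(well = wide$well[gaps > 0],
                                      n_missing = gaps[gaps > 0])
  wide
}

#' Group-level kinetics summary
#'
#' Mean, standard error of the mean and n of the normalized area per group
#' and timepoint — the numbers behind a regeneration-kinetics graph.
#'
#' @inheritParams track_larvae
#' @param exclude_outliers drop ROUT-flagged larvae (default `TRUE`).
#' @return data.frame `group, timepoint, mean, sem, n`; `sem` is `NA` for
#'   single-larva cells.
#' @export
summarize_kinetics <- function(kinetics, value = "normalized_area",
                               exclude_outliers = TRUE) {
  stopifnot(nrow(kinetics) > 0, value %in% names(kinetics))
  if (exclude_outliers && "outlier_flag" %in% names(kinetics))
    kinetics <- kinetics[!kinetics$outlier_flag, ]
  out <- list()
  for (g in unique(kinetics$group)) {
    for (tp in unique(kinetics$timepoint)) {
      x <- kinetics[[value]][kinetics$group == g & kinetics$timepoint == tp]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, timepoint = tp, mean = mean(x),
        sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Plot regeneration kinetics
#'
#' Mean +/- SEM of the normalized area per group across timepoints.
#'
#' @param summary table from [summarize_kinetics()].
#' @param file optional PNG path; when given, the plot is written there.
#' @return the summary, invisibly.
#' @export
plot_kinetics <- function(summary, file = NULL) {
  if (!is.null(file)) {
    png(file, width = 700, height = 500)
    on.exit(dev.off(), add = TRUE)
  }
  tps <- sort(unique(summary$timepoint))
  groups <- unique(summary$group)
  xs <- seq_along(tps)
  ylim <- range(c(summary$mean - summary$sem, summary$mean + summary$sem),
                na.rm = TRUE)
  plot(NA, xlim = range(xs) + c(-0.2, 0.2), ylim = ylim, xaxt = "n",
       xlab = "timepoint", ylab = "normalized area (% of control)",
       main = "Regeneration kinetics")
  axis(1, at = xs, labels = tps)
  for (i in seq_along(groups)) {
    sub <- summary[summary$group == groups[i], ]
    sub <- sub[match(tps, sub$timepoint), ]
    lines(xs, sub$mean, col = i, type = "b", pch = 19)
    ok <- !is.na(sub$sem)
    if (any(ok))
      arrows(xs[ok], sub$mean[ok] - sub$sem[ok],
             xs[ok], sub$mean[ok] + sub$sem[ok],
             angle = 90, code = 3, length = 0.04, col = i)
  }
  legend("bottomright", legend = groups, col = seq_along(groups),
         lty = 1, pch = 19, bty = "n")
  invisible(summary)
}
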