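# Video-tracking tremor metric. Wild-type flies wall-follow in a circular
# arena; tremorous flies lose the wall and accumulate in the middle, so the
# fraction of frames spent inside a central disc (radius 74.3% of the arena
# radius by default) serves as an indirect tremor severity score.

#' Chamber geometry for the center-occupancy metric
#'
#' @param xc,yc Arena center coordinates (same units as the trajectory).
#' @param radius Arena radius (> 0).
#' @param inner_ratio Fraction of the arena radius defining the central disc;
#'   default 0.743. The ratio is the scale-free quantity, so it is the primary
#'   parameter.
#' @param inner_radius Optional absolute radius of the central disc,
#'   overriding \code{inner_ratio}; provided for literal reproduction of
#'   analyses stated as an absolute distance threshold.
#' @return Object of class \code{"chamber_geometry"}.
#' @export
chamber_geometry <- function(xc, yc, radius, inner_ratio = 0.743,
                             inner_radius = NULL) {
  stopifnot(is.numeric(radius), radius > 0)
  if (is.null(inner_radius)) {
    if (inner_ratio <= 0 || inner_ratio >= 1)
      stop("inner_ratio must be in (0, 1)")
    inner_radius <- inner_ratio * radius
  }
  if (inner_radius >= radius)
    stop("inner radius must be smaller than the arena radius")
  structure(list(xc = xc, yc = yc, radius = radius,
                 inner_radius = inner_radius),
            class = "chamber_geometry")
}

#' Fraction of frames spent in the central disc
#'
#' The occupancy is the fraction of observed frames whose squared distance to
#' the chamber center is strictly below the squared inner radius: frames
#' exactly on the circle count as outside. Frames with missing coordinates
#' (tracking dropouts) are excluded from both numerator and denominator, so
#' the metric is a fraction of observed time.
#'
#' @param traj Data frame with columns \code{frame}, \code{x}, \code{y}
#'   (one fly).
#' @param geom A \code{\link{chamber_geometry}} object.
#' @return Occupancy fraction in \[0, 1\].
#' @export
center_occupancy <- function(traj, geom) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (!all(c("x", "y") %in% names(traj))) stop("trajectory needs x and y columns")
  ok <- is.finite(traj$x) & is.finite(traj$y)
  if (!any(ok)) stop("empty trajectory (no observed frames)")
  d2 <- (traj$x[ok] - geom$xc)^2 + (traj$y[ok] - geom$yc)^2
  mean(d2 < geom$inner_radius^2)
}

#' Restrict a trajectory to the analysis window
#'
#' Keeps the last \code{keep_last_s} seconds of a \code{total_s}-second
#' recording (default: last 5 of 10 minutes), i.e. frames with time in
#' \[\code{total_s - keep_last_s}, \code{total_s}). Frame indices are 0-based
#' and converted to time at \code{fps} frames per second.
#'
#' @param traj Data frame with a \code{frame} column (strictly increasing per
#'   fly).
#' @param total_s Nominal recording length in seconds (default 600).
#' @param keep_last_s Length of the retained terminal window (default 300).
#' @param fps Frame rate (default 30).
#' @return The windowed trajectory.
#' @export
analysis_window <- function(traj, total_s = 600, keep_last_s = 300, fps = 30) {
  if (keep_last_s > total_s) stop("keep_last_s cannot exceed total_s")
  if (!"frame" %in% names(traj)) stop("trajectory needs a frame column")
  tsec <- traj$frame / fps
  if (length(tsec) == 0L || max(tsec) + 1 / fps < keep_last_s)
    stop("recording shorter than the requested window")
  traj[tsec >= total_s - keep_last_s & tsec < total_s, , drop = FALSE]
}

#' Compare tremor severity (center occupancy) across genotypes
#'
#' Kruskal-Wallis across genotypes with Dunn's comparisons against the
#' control, plus per-genotype boxplot statistics (median and quartiles) of
#' the per-fly occupancies.
#'
#' @param occ Data frame with columns \code{fly_id}, \code{genotype} and
#'   \code{occupancy}, one row per fly.
#' @param control Control genotype label.
#' @param dunn_method Adjustment family for Dunn's comparisons.
#' @return Object of class \code{"tremor_report"}.
#' @export
compare_tremor <- function(occ, control, dunn_method = "bonferroni") {
  if (!all(c("genotype", "occupancy") %in% names(occ)))
    stop("need columns genotype and occupancy")
  samples <- split(occ$occupancy, occ$genotype)
  if (length(samples) < 2L) stop("need at least 2 genotypes")
  kw <- kruskal_wallis(samples)
  dunn <- dunn_posthoc(samples, control, method = dunn_method)
  qs <- t(vapply(samples, stats::quantile, numeric(3), probs = c(.25, .5, .75)))
  summary <- data.frame(genotype = names(samples), n = lengths(samples),
                        q1 = qs[, 1L], median = qs[, 2L], q3 = qs[, 3L],
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summary, kruskal_wallis = kw, dunn = dunn,
                 control = control),
            class = "tremor_report")
}

#' @export
print.tremor_report <- function(x, ...) {
  cat("Center-occupancy (tremor) comparison, control:", x$control, "\n")
  s <- x$summary
  s[c("q1", "median", "q3")] <- lapply(s[c("q1", "median", "q3")], round, 3)
  print(s, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$kruskal_wallis$H, x$kruskal_wallis$df, x$kruskal_wallis$p_value))
  dn <- x$dunn
  dn$p_raw <- signif(dn$p_raw, 4); dn$p_adj <- signif(dn$p_adj, 4)
  print(dn, row.names = FALSE)
  invisible(x)
}
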