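# Heat-induced seizure time-courses and bang-sensitivity recovery analysis.
# Seizure state is scored every 5 s over a 2-minute exposure (24 bins per
# fly); bang-sensitivity severity is the time to regain standing posture
# after mechanical shock.

#' Seizure incidence per time bin
#'
#' Proportion of flies seizing per 5-s bin, computed within each replicate
#' group, then averaged across groups with the standard error of the mean.
#'
#' @param tc Data frame with columns \code{fly_id}, \code{genotype},
#'   \code{replicate} and binary state columns \code{bin_0}..\code{bin_23}.
#' @param genotype Optional label to restrict to one genotype.
#' @return List with \code{per_replicate} (replicate x bin proportion matrix
#'   per genotype) and \code{summary}, a data frame genotype / bin / time_s /
#'   mean / sem.
#' @export
incidence_curve <- function(tc, genotype = NULL) {
  bins <- grep("^bin_", names(tc), value = TRUE)
  if (length(bins) == 0L) stop("no bin_* columns found")
  bins <- bins[order(as.integer(sub("bin_", "", bins)))]
  states <- as.matrix(tc[bins])
  if (anyNA(states) || !all(states %in% c(0, 1)))
    stop("seizure states must be 0/1")
  if (!is.null(genotype)) {
    keep <- tc$genotype %in% genotype
    if (!any(keep)) stop("genotype not found")
    tc <- tc[keep, , drop = FALSE]; states <- states[keep, , drop = FALSE]
  }
  key <- interaction(tc$genotype, tc$replicate, drop = TRUE)
  per_rep <- rowsum(states, key) / as.vector(table(key))
  geno_of <- tapply(as.character(tc$genotype), key, `[`, 1L)

  summaries <- lapply(split(seq_len(nrow(per_rep)), geno_of[rownames(per_rep)]),
    function(idx) {
      m <- per_rep[idx, , drop = FALSE]
      means <- colMeans(m)
      sems <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) / sqrt(nrow(m)) else rep(NA_real_, ncol(m))
      data.frame(bin = seq_along(means) - 1L,
                 time_s = seq_along(means) * 5,
                 mean = unname(means), sem = unname(sems))
    })
  summary <- do.call(rbind, Map(cbind,
    genotype = names(summaries), summaries))
  rownames(summary) <- NULL
  list(per_replicate = per_rep, replicate_genotype = geno_of, summary = summary)
}

#' Compare seizure incidence time-courses between genotypes
#'
#' Builds the replicate x time-bin proportion table and fits the two-way
#' repeated-measures ANOVA (genotype between, time bin within, replicate
#' group as subject) with Holm-Sidak per-bin comparisons.
#'
#' @param tc Data frame as in \code{\link{incidence_curve}}, containing at
#'   least two genotypes with balanced replicate counts.
#' @param genotypes Optional subset of genotype labels to compare.
#' @inheritParams rm_anova_two_way
#' @return An \code{\link{rm_anova_two_way}} result.
#' @export
compare_incidence <- function(tc, genotypes = NULL, sphericity = "none") {
  ic <- incidence_curve(tc, genotype = genotypes)
  per_rep <- ic$per_replicate
  geno <- ic$replicate_genotype[rownames(per_rep)]
  long <- data.frame(
    genotype = rep(geno, times = ncol(per_rep)),
    subject = rep(rownames(per_rep), times = ncol(per_rep)),
    time = rep(seq_len(ncol(per_rep)) - 1L, each = nrow(per_rep)),
    y = as.vector(per_rep))
  rm_anova_two_way(long, sphericity = sphericity)
}

#' Summary of bang-sensitivity recovery times
#'
#' The median treats right-censored flies (not recovered when observation
#' ended) as larger than every observed time; when the median itself falls in
#' the censored region it is reported as \code{NA}. The recovered fraction
#' counts uncensored recovery times at or below the horizon, out of all
#' flies.
#'
#' @param times Per-fly recovery times in seconds (>= 0).
#' @param censored Logical vector: TRUE for flies not recovered by the end of
#'   observation (default all FALSE).
#' @param horizon_s Horizon for the recovered fraction, in seconds (> 0).
#' @return List with \code{median_s}, \code{fraction_recovered},
#'   \code{percent_recovered} (1 decimal) and \code{n}.
#' @export
recovery_summary <- function(times, censored = rep(FALSE, length(times)),
                             horizon_s) {
  if (length(times) == 0L) stop("need at least one fly")
  if (any(times < 0) || anyNA(times)) stop("recovery times must be >= 0")
  if (horizon_s <= 0) stop("horizon must be positive")
  if (any(censored) && any(!censored) && min(times[censored]) < max(times[!censored]))
    stop("censoring bound must be at least the largest observed time")
  ordered_times <- ifelse(censored, Inf, times)
  med <- stats::median(ordered_times)
  frac <- mean(!censored & times <= horizon_s)
  list(median_s = if (is.finite(med)) med else NA_real_,
       fraction_recovered = frac,
       percent_recovered = round(100 * frac, 1),
       n = length(times))
}

#' Compare recovery-time distributions of two groups
#'
#' Mann-Whitney U test on per-fly recovery times. Censored flies enter at
#' their censoring time (the observation horizon), which ranks them as tied
#' maxima; midranks make this well-defined.
#'
#' @param times_a,times_b Recovery times of the two groups.
#' @param censored_a,censored_b Optional censoring flags.
#' @param ... Passed to \code{\link{mann_whitney_u}}.
#' @return The \code{\link{mann_whitney_u}} result plus group medians.
#' @export
compare_recovery <- function(times_a, times_b,
                             censored_a = rep(FALSE, length(times_a)),
                             censored_b = rep(FALSE, length(times_b)), ...) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  mw <- mann_whitney_u(times_a, times_b, ...)
  mw$median_a <- stats::median(ifelse(censored_a, Inf, times_a))
  mw$median_b <- stats::median(ifelse(censored_b, Inf, times_b))
  mw
}
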