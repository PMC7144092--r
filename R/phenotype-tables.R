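# Penetrance, viability and fertility tables: categorical phenotype scoring
# of a deficiency screen, analyzed with Fisher's exact test per trait and a
# Bonferroni-adjusted significance threshold across the screened deficiencies.

#' Penetrance of a trait
#'
#' @param affected Number of flies showing the trait.
#' @param scored Number of flies scored (>= 1).
#' @return Percentage, rounded to 1 decimal.
#' @examples
#' penetrance(39, 44)  # 88.6
#' @export
penetrance <- function(affected, scored) {
  if (any(scored < 1)) stop("must score at least one fly")
  if (any(affected < 0 | affected > scored))
    stop("affected must lie in [0, scored]")
  round(100 * affected / scored, 1)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Inverse of \code{\link{penetrance}}: recovers the affected count from a
#' sample size and a percentage printed to 1 decimal, rounding half away from
#' zero (the convention evidently used to produce such tables). The
#' \code{consistent} flag reports whether the reconstructed count reproduces
#' the printed percentage; a FALSE flag indicates a typo or a different
#' denominator in the source table.
#'
#' @param n Sample size (>= 1). Vectorized.
#' @param percent Printed percentage in \[0, 100\].
#' @return Data frame with columns \code{count} and \code{consistent}.
#' @examples
#' reconstruct_counts(150, 70.0)  # count 105, consistent
#' @export
reconstruct_counts <- function(n, percent) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(percent < 0 | percent > 100)) stop("percent must be in [0, 100]")
  count <- floor(n * percent / 100 + 0.5)   # half away from zero (all values >= 0)
  data.frame(count = count,
             consistent = penetrance(count, n) == round(percent, 1))
}

#' Viability and fertility percentages
#'
#' @param total_progeny Total male progeny scored.
#' @param mutant_class Count in the mutant class.
#' @param total_tested Males tested for fertility.
#' @param fertile Males that produced progeny.
#' @return List with \code{percent_mutant} and \code{percent_fertile}, each
#'   to 1 decimal (NA when the corresponding total is absent).
#' @export
viability_fertility_summary <- function(total_progeny = NULL, mutant_class = NULL,
                                        total_tested = NULL, fertile = NULL) {
  pm <- pf <- NA_real_
  if (!is.null(total_progeny)) {
    if (any(total_progeny == 0)) stop("zero total progeny")
    if (any(mutant_class < 0 | mutant_class > total_progeny)) stop("invalid class count")
    pm <- round(100 * mutant_class / total_progeny, 1)
  }
  if (!is.null(total_tested)) {
    if (any(total_tested == 0)) stop("zero flies tested")
    if (any(fertile < 0 | fertile > total_tested)) stop("invalid fertile count")
    pf <- round(100 * fertile / total_tested, 1)
  }
  list(percent_mutant = pm, percent_fertile = pf)
}

#' Fisher screen report for a penetrance table
#'
#' For each screened record and each trait, tests the affected/unaffected
#' split against the control record with \code{\link{fisher_exact}} and flags
#' significance at the Bonferroni-adjusted threshold \code{alpha / m}, where
#' \code{m} is the number of screened (non-control) records.
#'
#' @param records Data frame with columns \code{label}, \code{scored} and one
#'   affected-count column per trait (e.g. \code{wings}, \code{thorax}).
#' @param control Single-row data frame with the same columns: the comparison
#'   group.
#' @param traits Names of the affected-count columns (default
#'   \code{c("wings", "thorax")}).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame of class \code{"screen_report"}: label, trait, counts,
#'   penetrance, odds ratio, p-value, significance flag; the Bonferroni
#'   threshold is attached as attribute \code{"threshold"}.
#' @export
screen_report <- function(records, control, traits = c("wings", "thorax"),
                          alpha = 0.05) {
  need <- c("label", "scored", traits)
  if (!all(need %in% names(records)) || !all(need %in% names(control)))
    stop("records and control must have columns ", paste(need, collapse = ", "))
  if (nrow(control) != 1L) stop("control must be a single record")
  m <- nrow(records)
  if (m < 1L) stop("need at least one screened record")
  thr <- bonferroni_threshold(alpha, m)
  rows <- list()
  for (i in seq_len(m)) {
    for (tr in traits) {
      aff <- records[[tr]][i]; n <- records$scored[i]
      caff <- control[[tr]][1L]; cn <- control$scored[1L]
      ft <- fisher_exact(aff, n - aff, caff, cn - caff)
      rows[[length(rows) + 1L]] <- data.frame(
        label = records$label[i], trait = tr,
        affected = aff, scored = n,
        percent = penetrance(aff, n),
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        significant = ft$p_value < thr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  class(out) <- c("screen_report", class(out))
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Deficiency screen: %d records, Bonferroni threshold %.6f\n",
              attr(x, "m"), attr(x, "threshold")))
  y <- as.data.frame(x)
  y$p_value <- signif(y$p_value, 4)
  y$odds_ratio <- signif(y$odds_ratio, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
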