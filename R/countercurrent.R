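# Benzer countercurrent assay: the climbing index and a binomial generative
# model of the apparatus. Flies start in tube 0, are given a fixed number of
# climb opportunities (default 5), and the final tube number counts their
# successes, so the climbing index estimates the per-trial climb probability.

#' Climbing index of a countercurrent run
#'
#' \eqn{CI = \sum_i N_i \cdot i / (5 \sum_i N_i)} over tubes 0..5, where
#' \eqn{N_i} is the number of flies ending in tube \eqn{i}. Ranges from 0
#' (no fly ever climbed) to 1 (every fly climbed in all five trials).
#'
#' @param counts Integer vector of length 6: flies per tube 0..5.
#' @return The climbing index, a number in \[0, 1\].
#' @examples
#' climbing_index(c(2, 4, 6, 4, 2, 2))  # 0.46
#' @export
climbing_index <- function(counts) {
  counts <- .check_tube_counts(counts)
  n_trials <- length(counts) - 1L
  tubes <- seq_along(counts) - 1
  sum(counts * tubes) / (n_trials * sum(counts))
}

.check_tube_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("tube counts must be non-negative integers")
  if (length(counts) != 6L) stop("expected counts for exactly 6 tubes (0..5)")
  if (sum(counts) == 0) stop("zero flies counted")
  as.numeric(counts)
}

#' Simulate one countercurrent run
#'
#' Each fly independently receives \code{trials} Bernoulli climb opportunities
#' with success probability \code{p}; its final tube is the number of
#' successes, so tube counts follow a multinomial with Binomial(trials, p)
#' cell probabilities. With \code{dropout = TRUE}, a fly stops being tested
#' after its first failure (final tube = initial run of successes), the
#' alternative reading of the transfer protocol. Optional per-fly
#' heterogeneity draws each fly's probability from a Beta distribution with
#' mean \code{p} and precision \code{kappa}.
#'
#' @param p Per-trial climb probability.
#' @param n_flies Number of flies in the run (default 20).
#' @param trials Number of climb opportunities (default 5).
#' @param dropout Stop testing a fly after its first failure (default FALSE).
#' @param kappa Beta precision for per-fly heterogeneity in \code{p};
#'   \code{NULL} (default) for a homogeneous cohort.
#' @return Named integer vector \code{N0..N5} of flies per tube.
#' @export
simulate_countercurrent <- function(p, n_flies = 20, trials = 5,
                                    dropout = FALSE, kappa = NULL) {
  stopifnot(p >= 0, p <= 1, n_flies >= 1, trials >= 1)
  pf <- if (is.null(kappa)) rep(p, n_flies)
        else stats::rbeta(n_flies, p * kappa, (1 - p) * kappa)
  if (!dropout) {
    tube <- stats::rbinom(n_flies, trials, pf)
  } else {
    draws <- matrix(stats::rbinom(n_flies * trials, 1L, rep(pf, trials)),
                    nrow = n_flies)
    # length of the initial run of successes
    tube <- apply(draws, 1L, function(z) {
      f <- which(z == 0L)
      if (length(f)) f[1L] - 1L else trials
    })
  }
  counts <- tabulate(tube + 1L, nbins = trials + 1L)
  names(counts) <- paste0("N", 0:trials)
  counts
}

#' Estimate the per-trial climb probability from tube counts
#'
#' Under the binomial model the maximum-likelihood estimate of the climb
#' probability equals the climbing index; the interval is a Wilson score
#' interval treating the run as \code{5 * sum(N)} Bernoulli trials.
#'
#' @param counts Tube counts \code{N0..N5}.
#' @param conf Confidence level (default 0.95).
#' @return List with \code{p_hat}, \code{ci} (length-2 vector) and \code{n}
#'   (effective Bernoulli trials).
#' @export
estimate_climb_prob <- function(counts, conf = 0.95) {
  counts <- .check_tube_counts(counts)
  p_hat <- climbing_index(counts)
  n <- (length(counts) - 1L) * sum(counts)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(p_hat = p_hat, ci = c(max(0, centre - half), min(1, centre + half)), n = n)
}

#' Compare climbing ability across genotypes
#'
#' Computes a climbing index per replicate run, then a Kruskal-Wallis test
#' across genotypes with Dunn's post hoc comparisons against the control.
#'
#' @param runs Data frame with columns \code{genotype}, \code{replicate} and
#'   \code{N0}..\code{N5} (one countercurrent run per row).
#' @param control Genotype label of the control group.
#' @param dunn_method Adjustment family for Dunn's comparisons.
#' @return Object of class \code{"climb_report"}: per-genotype median CI and
#'   replicate count, the Kruskal-Wallis result and Dunn's table.
#' @export
compare_climbing <- function(runs, control, dunn_method = "bonferroni") {
  tube_cols <- paste0("N", 0:5)
  if (!all(c("genotype", tube_cols) %in% names(runs)))
    stop("runs must have columns genotype, N0..N5")
  ci <- apply(as.matrix(runs[tube_cols]), 1L, climbing_index)
  samples <- split(ci, runs$genotype)
  if (length(samples) < 2L) stop("need at least 2 genotypes")
  if (!control %in% names(samples)) stop("control label not found")
  kw <- kruskal_wallis(samples)
  dunn <- dunn_posthoc(samples, control, method = dunn_method)
  summary <- data.frame(
    genotype = names(samples),
    n_replicates = lengths(samples),
    median_ci = vapply(samples, stats::median, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summary, kruskal_wallis = kw, dunn = dunn,
                 control = control, per_replicate = ci),
            class = "climb_report")
}

#' @export
print.climb_report <- function(x, ...) {
  cat("Countercurrent climbing comparison (control:", x$control, ")\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$kruskal_wallis$H, x$kruskal_wallis$df, x$kruskal_wallis$p_value))
  dn <- x$dunn
  dn$p_raw <- signif(dn$p_raw, 4); dn$p_adj <- signif(dn$p_adj, 4)
  print(dn, row.names = FALSE)
  invisible(x)
}
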