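# Core statistical machinery: exact and rank-based tests plus multiplicity
# adjustments. Everything here is implemented from first principles (the
# surrounding modules delegate to these); base-R equivalents are used only as
# independent oracles in the test suite.

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact conditional test of association in a 2x2 table, with the two-sided
#' p-value computed by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables sharing the observed margins
#' whose probability does not exceed that of the observed table. This is the
#' dominant convention in statistics packages; note that other two-sided
#' definitions (e.g. doubling the smaller tail) exist and give different
#' values.
#'
#' The table is laid out as \code{rbind(c(a, b), c(c, d))}: row 1 is the group
#' of interest (affected, unaffected), row 2 the control.
#'
#' @param a,b,c,d Non-negative integer counts, or \code{a} may be a 2x2 matrix
#'   (then \code{b}, \code{c}, \code{d} must be missing).
#' @return A list with components \code{odds_ratio} (the sample odds ratio
#'   \eqn{ad/bc}; \code{Inf} when \eqn{bc = 0} and \eqn{ad > 0}; \code{NaN}
#'   with \code{or_undefined = TRUE} when both products are 0) and
#'   \code{p_value} (two-sided exact p).
#' @examples
#' fisher_exact(105, 45, 40, 4)$p_value  # ~0.0052
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(is.null(b), is.null(c), is.null(d), all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cnt <- c(a, b, c, d)
  if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be four non-negative integers")
  if (sum(cnt) == 0L)
    stop("all-zero table")
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)

  m1 <- a + b          # row-1 margin
  m2 <- c + d          # row-2 margin
  n1 <- a + c          # column-1 margin
  n  <- m1 + m2
  kmin <- max(0, n1 - m2)
  kmax <- min(m1, n1)
  k <- kmin:kmax
  # hypergeometric log-probabilities of every margin-preserving table
  logp <- lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(n, n1)
  rel <- exp(logp - max(logp))
  obs <- rel[k == a]
  # relative tolerance guards against tables that are equal in exact
  # arithmetic but differ in the last floating-point bit
  p <- sum(rel[rel <= obs * (1 + 1e-7)]) / sum(rel)
  p <- min(1, max(0, p))

  ad <- a * d; bc <- b * c
  or_undefined <- (ad == 0 && bc == 0)
  or <- if (or_undefined) NaN else if (bc == 0) Inf else ad / bc

  list(odds_ratio = or, p_value = p, or_undefined = or_undefined)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise type I error rate, in (0, 1).
#' @param m Number of comparisons in the family (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_threshold(0.05, 11)  # 0.004545...
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("m must be a positive integer")
  alpha / m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with raw p-values sorted ascending,
#' \eqn{padj_{(i)} = \min_{j \ge i} \{ p_{(j)} m / j \}} clipped to 1, returned
#' in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to \code{length(p)}, may be larger when some
#'   family members were not tested.
#' @return Adjusted p-values, same order and length as \code{p}.
#' @export
bh_adjust <- function(p, m = length(p)) {
  .check_pvalues(p, m)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)          # largest first
  i <- n:1                                   # ranks of the sorted values
  adj <- pmin(1, cummin(m / i * p[o]))
  adj[order(o)]
}

#' Holm-Sidak step-down adjustment
#'
#' With p-values sorted ascending, \eqn{padj_{(i)} = \max_{j \le i}
#' \{ 1 - (1 - p_{(j)})^{m - j + 1} \}}, clipped to \[0, 1\] and returned in
#' input order. Controls the family-wise error rate; uniformly more powerful
#' than Holm-Bonferroni under independence.
#'
#' @inheritParams bh_adjust
#' @export
holm_sidak_adjust <- function(p, m = length(p)) {
  .check_pvalues(p, m)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- cummax(1 - (1 - p[o])^(m - seq_len(n) + 1))
  adj <- pmin(1, pmax(0, adj))
  adj[order(o)]
}

.check_pvalues <- function(p, m) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m cannot be smaller than the number of p-values")
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. Ties receive midranks and the normal
#' approximation includes the tie-corrected variance and (by default) a
#' continuity correction. For small samples the null distribution of U is
#' obtained by exact enumeration of all assignments of the pooled observations
#' to the two groups, which remains valid under ties.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Use the enumeration path; default enumerates when
#'   \code{length(x) + length(y) <= 12}.
#' @param correct Apply the continuity correction on the normal path.
#' @return List with \code{U} (statistic for \code{x}), \code{p_value}
#'   (two-sided) and \code{method} ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y, exact = NULL, correct = TRUE) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (is.null(exact)) exact <- n <= 12L
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (exact) {
    idx <- utils::combn(n, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    Uperm <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }

  tie <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  dev <- U - mu
  cc <- if (correct) sign(dev) * 0.5 else 0
  z <- (dev - cc) / sqrt(sigma2)
  if (dev == 0) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal")
}

#' Kruskal-Wallis one-way ANOVA on ranks
#'
#' @param samples Named list of non-empty numeric vectors, one per group.
#' @return List with \code{H} (tie-corrected statistic), \code{df} and
#'   \code{p_value} from the chi-squared reference.
#' @export
kruskal_wallis <- function(samples) {
  .check_groups(samples)
  k <- length(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), lengths(samples))
  n <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(samples)) - 3 * (n + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (n^3 - n)
  H <- if (C > 0) H / C else 0           # all observations identical
  df <- k - 1
  list(H = H, df = df, p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

.check_groups <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(samples) == 0L)) stop("every group must be non-empty")
  if (anyNA(unlist(samples, use.names = FALSE)))
    stop("missing values are not supported")
}

#' Dunn's post hoc test against a control group
#'
#' Follows a Kruskal-Wallis test: z statistics from differences in mean pooled
#' ranks with the tie-corrected pooled variance, adjusted across the
#' control-vs-group comparisons. The adjustment family defaults to Bonferroni
#' over the k - 1 comparisons.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param control Name of the control group in \code{samples}.
#' @param method Multiplicity adjustment: \code{"bonferroni"} (default),
#'   \code{"sidak"} or \code{"none"}.
#' @return Data frame with one row per control-vs-group comparison: group,
#'   mean rank difference, z, raw and adjusted p.
#' @export
dunn_posthoc <- function(samples, control,
                         method = c("bonferroni", "sidak", "none")) {
  .check_groups(samples)
  method <- match.arg(method)
  if (is.null(names(samples)) || !control %in% names(samples))
    stop("control label not found among groups")
  k <- length(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(names(samples), lengths(samples))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(samples)
  tie <- table(x)
  v0 <- n * (n + 1) / 12 - sum(tie^3 - tie) / (12 * (n - 1))
  others <- setdiff(names(samples), control)
  ncomp <- length(others)
  res <- lapply(others, function(lab) {
    se <- sqrt(v0 * (1 / ni[[control]] + 1 / ni[[lab]]))
    diff <- rbar[[control]] - rbar[[lab]]
    z <- if (se > 0) diff / se else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    data.frame(group = lab, mean_rank_diff = diff, z = z, p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- switch(method,
    bonferroni = pmin(1, res$p_raw * ncomp),
    sidak      = 1 - (1 - res$p_raw)^ncomp,
    none       = res$p_raw)
  rownames(res) <- NULL
  res
}

#' Two-way repeated-measures ANOVA (one between, one within factor)
#'
#' Classical univariate mixed-design decomposition for a balanced layout:
#' genotype is the between-subjects factor, the repeatedly observed unit
#' (replicate group of flies) is the subject, and time bin is the within
#' factor. The genotype effect is tested against subjects-within-genotype;
#' time and the interaction against the residual. Greenhouse-Geisser
#' correction of the within-factor degrees of freedom is available but off by
#' default.
#'
#' Per-time-bin pairwise genotype comparisons (Welch t on the subject values
#' at that bin) are returned with Holm-Sidak adjustment across all
#' bin-by-pair comparisons.
#'
#' @param data Data frame with columns \code{genotype}, \code{subject},
#'   \code{time} and \code{y} (response, e.g. a proportion in \[0, 1\]).
#'   The design must be balanced and completely crossed; unbalanced input is
#'   rejected, not imputed.
#' @param sphericity \code{"none"} (default) or \code{"greenhouse-geisser"}.
#' @param posthoc Compute the per-bin pairwise comparisons (default TRUE).
#' @return List of class \code{"rm_anova"}: an \code{anova} data frame with
#'   rows genotype, time, interaction (SS, df, MS, F, p), the
#'   Greenhouse-Geisser epsilon when requested, and (optionally) a
#'   \code{posthoc} data frame.
#' @export
rm_anova_two_way <- function(data, sphericity = c("none", "greenhouse-geisser"),
                             posthoc = TRUE) {
  sphericity <- match.arg(sphericity)
  need <- c("genotype", "subject", "time", "y")
  if (!all(need %in% names(data))) stop("data must have columns ", paste(need, collapse = ", "))
  if (anyNA(data[need])) stop("missing values are not supported")
  data$genotype <- factor(data$genotype)
  data$subject <- interaction(data$genotype, data$subject, drop = TRUE)
  data$time <- factor(data$time)

  a <- nlevels(data$genotype)
  t <- nlevels(data$time)
  # balance: every subject observed at every time, equal subjects per genotype
  tab <- table(data$subject, data$time)
  subj_per_g <- table(data$genotype) / t
  if (any(tab != 1L) || length(unique(subj_per_g)) != 1L)
    stop("design must be balanced (equal replicates per genotype, complete time crossing)")
  s <- as.integer(subj_per_g[1L])
  if (a < 2L) stop("need at least 2 genotypes")
  if (s < 2L) stop("need at least 2 subjects per genotype")

  y <- data$y
  grand <- mean(y)
  m_g  <- tapply(y, data$genotype, mean)
  m_t  <- tapply(y, data$time, mean)
  m_s  <- tapply(y, data$subject, mean)
  m_gt <- tapply(y, list(data$genotype, data$time), mean)

  ss_total   <- sum((y - grand)^2)
  ss_between <- t * sum((m_s - grand)^2)
  ss_g       <- s * t * sum((m_g - grand)^2)
  ss_subj    <- ss_between - ss_g
  ss_t       <- a * s * sum((m_t - grand)^2)
  ss_gt      <- s * sum((m_gt - outer(m_g, m_t, "+") + grand)^2)
  ss_err     <- ss_total - ss_between - ss_t - ss_gt

  df_g <- a - 1; df_subj <- a * (s - 1)
  df_t <- t - 1; df_gt <- (a - 1) * (t - 1); df_err <- a * (s - 1) * (t - 1)
  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_g <- ms(ss_g, df_g); ms_subj <- ms(ss_subj, df_subj)
  ms_t <- ms(ss_t, df_t); ms_gt <- ms(ss_gt, df_gt); ms_err <- ms(ss_err, df_err)

  f_g  <- if (ms_subj > 0) ms_g / ms_subj else if (ss_g == 0) 0 else Inf
  f_t  <- if (ms_err > 0) ms_t / ms_err else if (ss_t == 0) 0 else Inf
  f_gt <- if (ms_err > 0) ms_gt / ms_err else if (ss_gt == 0) 0 else Inf

  eps <- 1
  if (sphericity == "greenhouse-geisser") {
    # pooled within-genotype covariance of the subject x time layout
    wide <- matrix(y[order(data$subject, data$time)], ncol = t, byrow = TRUE)
    gidx <- data$genotype[order(data$subject, data$time)][seq(1, nrow(data), by = t)]
    wc <- Reduce(`+`, lapply(split.data.frame(wide, gidx), function(w) {
      (nrow(w) - 1) * stats::cov(w)
    })) / (a * (s - 1))
    C <- diag(t) - 1 / t
    S <- C %*% wc %*% C
    eps <- sum(diag(S))^2 / ((t - 1) * sum(S * S))
    eps <- min(1, max(1 / (t - 1), eps))
  }

  p_g  <- if (is.finite(f_g)) stats::pf(f_g, df_g, df_subj, lower.tail = FALSE) else 0
  p_t  <- if (is.finite(f_t)) stats::pf(f_t, df_t * eps, df_err * eps, lower.tail = FALSE) else 0
  p_gt <- if (is.finite(f_gt)) stats::pf(f_gt, df_gt * eps, df_err * eps, lower.tail = FALSE) else 0

  anova_tab <- data.frame(
    term = c("genotype", "subjects_within", "time", "genotype:time", "residual"),
    SS = c(ss_g, ss_subj, ss_t, ss_gt, ss_err),
    df = c(df_g, df_subj, df_t, df_gt, df_err),
    MS = c(ms_g, ms_subj, ms_t, ms_gt, ms_err),
    F  = c(f_g, NA, f_t, f_gt, NA),
    p  = c(p_g, NA, p_t, p_gt, NA),
    stringsAsFactors = FALSE)

  out <- list(anova = anova_tab, epsilon = eps,
              F_genotype = f_g, F_time = f_t, F_interaction = f_gt,
              p_genotype = p_g, p_time = p_t, p_interaction = p_gt)

  if (posthoc && a >= 2L) {
    pairs <- utils::combn(levels(data$genotype), 2L, simplify = FALSE)
    rows <- list()
    for (tb in levels(data$time)) {
      sub <- data[data$time == tb, ]
      for (pr in pairs) {
        y1 <- sub$y[sub$genotype == pr[1L]]
        y2 <- sub$y[sub$genotype == pr[2L]]
        v1 <- stats::var(y1); v2 <- stats::var(y2)
        se <- sqrt(v1 / s + v2 / s)
        if (se > 0) {
          tstat <- (mean(y1) - mean(y2)) / se
          df_w <- (v1 / s + v2 / s)^2 /
            ((v1 / s)^2 / (s - 1) + (v2 / s)^2 / (s - 1))
          p <- 2 * stats::pt(-abs(tstat), df_w)
        } else {
          tstat <- 0; p <- 1
        }
        rows[[length(rows) + 1L]] <- data.frame(
          time = tb, group1 = pr[1L], group2 = pr[2L],
          t = tstat, p_raw = p, stringsAsFactors = FALSE)
      }
    }
    ph <- do.call(rbind, rows)
    ph$p_adj <- holm_sidak_adjust(ph$p_raw)
    out$posthoc <- ph
  }
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA\n")
  tab <- x$anova
  tab$SS <- signif(tab$SS, 5); tab$MS <- signif(tab$MS, 5)
  tab$F <- signif(tab$F, 5); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  if (x$epsilon < 1)
    cat(sprintf("Greenhouse-Geisser epsilon: %.4f\n", x$epsilon))
  invisible(x)
}
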