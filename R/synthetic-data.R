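# Synthetic-assay generators. Each generator emulates the statistical
# structure one pipeline stage assumes (not the biophysics of the assay), and
# is deterministic given a seed, so every stage is testable offline with
# known ground truth. Defaults mirror the study designs: ~3 replicate groups
# of ~20 flies in the countercurrent assay, 30 fps / 10 min recordings,
# 3 groups of 30 flies scored every 5 s for 2 min in the seizure assay, and
# 4 biological replicates per condition in the counts stage.

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#' @param seed Integer seed, or NULL to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

#' Generate countercurrent tube counts
#'
#' Simulates replicate runs of the countercurrent assay for one genotype via
#' \code{\link{simulate_countercurrent}}.
#'
#' @param p Per-trial climb probability.
#' @param n_replicates Number of replicate runs (default 3).
#' @param n_flies Flies per run (default 20).
#' @param genotype Genotype label for the output.
#' @param seed Optional integer seed.
#' @param ... Passed to \code{\link{simulate_countercurrent}}.
#' @return Data frame: genotype, replicate, N0..N5.
#' @export
gen_countercurrent <- function(p, n_replicates = 3, n_flies = 20,
                               genotype = "genotype", seed = NULL, ...) {
  with_seed(seed, {
    runs <- t(vapply(seq_len(n_replicates),
                     function(i) simulate_countercurrent(p, n_flies, ...),
                     numeric(6)))
    data.frame(genotype = genotype, replicate = seq_len(n_replicates),
               runs, stringsAsFactors = FALSE)
  })
}

#' Generate arena trajectories
#'
#' Two movement regimes designed solely so the center-occupancy metric
#' separates them; the dynamics are a modeling device, not fly biomechanics.
#' \itemize{
#'   \item \code{wall}: wall-following — an angular random walk at radial
#'     position Normal(0.9 R, 0.02 R) clipped to the arena, so the fly
#'     essentially never enters the central disc.
#'   \item \code{tremor}: uncoordinated wandering — a mean-reverting (AR(1))
#'     walk about the chamber center, clipped at the wall. With reversion
#'     \code{phi} and stationary s.d. \code{wander_sd} (default 0.35 R) the
#'     stationary occupancy of the 0.743 R disc is
#'     \eqn{1 - \exp(-0.743^2 / (2 \cdot 0.35^2)) \approx 0.9}.
#'   \item \code{mixture}: each fly is tremor-type with probability
#'     \code{mixture_weight}, else wall-type.
#' }
#'
#' @param mode One of \code{"wall"}, \code{"tremor"}, \code{"mixture"}.
#' @param n_flies Number of flies (default 1).
#' @param duration_s Recording length in seconds (default 600).
#' @param fps Frame rate (default 30).
#' @param radius Arena radius (default 100, arbitrary units; center at 0,0).
#' @param wall_sd Radial s.d. of the wall-follower, as fraction of R.
#' @param phi AR(1) reversion coefficient of the tremor walk.
#' @param wander_sd Stationary s.d. of the tremor walk, fraction of R.
#' @param mixture_weight Probability a fly is tremor-type in mixture mode.
#' @param seed Optional integer seed.
#' @return Data frame: fly_id, frame (0-based), x, y.
#' @export
gen_trajectory <- function(mode = c("wall", "tremor", "mixture"), n_flies = 1,
                           duration_s = 600, fps = 30, radius = 100,
                           wall_sd = 0.02, phi = 0.95, wander_sd = 0.35,
                           mixture_weight = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(duration_s * fps)
  with_seed(seed, {
    one_fly <- function(fmode) {
      if (fmode == "wall") {
        theta <- cumsum(stats::rnorm(n, 0, 0.1))
        r <- pmin(radius, pmax(0, stats::rnorm(n, 0.9 * radius, wall_sd * radius)))
        cbind(x = r * cos(theta), y = r * sin(theta))
      } else {
        s_innov <- wander_sd * radius * sqrt(1 - phi^2)
        x <- stats::filter(stats::rnorm(n, 0, s_innov), phi, "recursive")
        y <- stats::filter(stats::rnorm(n, 0, s_innov), phi, "recursive")
        d <- sqrt(x^2 + y^2)
        scl <- ifelse(d > radius, radius / d, 1)   # clip at the wall
        cbind(x = as.numeric(x * scl), y = as.numeric(y * scl))
      }
    }
    fmodes <- switch(mode,
      wall = rep("wall", n_flies),
      tremor = rep("tremor", n_flies),
      mixture = ifelse(stats::runif(n_flies) < mixture_weight, "tremor", "wall"))
    out <- lapply(seq_len(n_flies), function(i) {
      xy <- one_fly(fmodes[i])
      data.frame(fly_id = i, frame = seq_len(n) - 1L,
                 x = xy[, "x"], y = xy[, "y"])
    })
    do.call(rbind, out)
  })
}

#' Generate seizure time-courses
#'
#' Per-fly seizure onset is exponential with the given hazard; the fly is
#' scored as seizing at every 5-s assessment at or after onset (onset-only
#' model, no remission within the window). Final-bin incidence is therefore
#' \eqn{1 - e^{-120 \cdot hazard}} in expectation.
#'
#' @param hazard Onset hazard per second (>= 0).
#' @param n_replicates Replicate groups (default 3).
#' @param n_flies Flies per group (default 30).
#' @param n_bins Number of 5-s assessment bins (default 24, i.e. 2 min).
#' @param bin_s Bin width in seconds (default 5).
#' @param genotype Genotype label.
#' @param temperature Assay temperature, metadata only (default 37).
#' @param seed Optional integer seed.
#' @return Data frame: fly_id, genotype, replicate, temperature,
#'   bin_0..bin_{n_bins-1}.
#' @export
gen_seizure <- function(hazard, n_replicates = 3, n_flies = 30, n_bins = 24,
                        bin_s = 5, genotype = "genotype", temperature = 37,
                        seed = NULL) {
  if (hazard < 0) stop("hazard must be >= 0")
  with_seed(seed, {
    ntot <- n_replicates * n_flies
    onset <- if (hazard == 0) rep(Inf, ntot) else stats::rexp(ntot, hazard)
    assess <- seq_len(n_bins) * bin_s
    states <- outer(onset, assess, function(o, t) as.integer(o <= t))
    colnames(states) <- paste0("bin_", seq_len(n_bins) - 1L)
    data.frame(fly_id = seq_len(ntot), genotype = genotype,
               replicate = rep(seq_len(n_replicates), each = n_flies),
               temperature = temperature, states,
               stringsAsFactors = FALSE)
  })
}

#' Generate bang-sensitivity recovery times
#'
#' Log-normal recovery times, right-censored at an observation horizon.
#'
#' @param n Number of flies.
#' @param meanlog,sdlog Log-normal parameters (times in seconds).
#' @param horizon_s Observation horizon; flies with later recovery are
#'   recorded at the horizon with \code{censored = TRUE}. NULL for no
#'   censoring.
#' @param genotype Genotype label.
#' @param seed Optional integer seed.
#' @return Data frame: fly_id, genotype, time_s, censored.
#' @export
gen_recovery <- function(n, meanlog, sdlog, horizon_s = NULL,
                         genotype = "genotype", seed = NULL) {
  if (sdlog <= 0) stop("sdlog must be positive")
  with_seed(seed, {
    t <- stats::rlnorm(n, meanlog, sdlog)
    cens <- rep(FALSE, n)
    if (!is.null(horizon_s)) {
      cens <- t > horizon_s
      t[cens] <- horizon_s
    }
    data.frame(fly_id = seq_len(n), genotype = genotype,
               time_s = t, censored = cens, stringsAsFactors = FALSE)
  })
}

#' Generate a penetrance table
#'
#' Binomial affected counts per trait for a set of genotypes.
#'
#' @param labels Genotype/deficiency labels.
#' @param scored Flies scored per genotype (recycled).
#' @param penetrance_wings,penetrance_thorax Per-genotype trait penetrances
#'   in \[0, 1\] (recycled).
#' @param seed Optional integer seed.
#' @return Data frame: label, scored, wings, thorax (affected counts).
#' @export
gen_phenotypes <- function(labels, scored, penetrance_wings, penetrance_thorax,
                           seed = NULL) {
  k <- length(labels)
  scored <- rep_len(scored, k)
  pw <- rep_len(penetrance_wings, k)
  pt <- rep_len(penetrance_thorax, k)
  if (any(pw < 0 | pw > 1 | pt < 0 | pt > 1)) stop("penetrance must be in [0, 1]")
  with_seed(seed, data.frame(
    label = labels, scored = scored,
    wings = stats::rbinom(k, scored, pw),
    thorax = stats::rbinom(k, scored, pt),
    stringsAsFactors = FALSE))
}

#' Generate a counts matrix with spiked fold changes
#'
#' Negative-binomial counts for a two-condition design with sample-specific
#' size factors and known spiked log2 fold changes:
#' \eqn{K_{gj} \sim NB(mean = s_j q_g 2^{lfc_g [j \in B]}, dispersion)}.
#' By default one gene ("gene_gsts1_like") is spiked at log2FC = -1 in the
#' second condition, mimicking a 2-fold down-regulated glutathione
#' S-transferase. Baseline means are drawn log-uniformly on
#' \code{base_mean_range}; true size factors are log-normal with geometric
#' mean 1.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_cond Replicates per condition (default 4).
#' @param conditions Two condition labels (default c("control", "mutant")).
#' @param dispersion NB dispersion, scalar or per-gene (default 0.05).
#' @param base_mean_range Range of baseline normalized means (default
#'   c(10, 10000), log-uniform).
#' @param sf_sdlog Log-normal s.d. of the true size factors (default 0.15).
#' @param spike_log2fc Named numeric vector of spiked log2 fold changes
#'   (applied in the second condition); names become gene ids. Default one
#'   gene at -1. Use \code{numeric(0)} for a fully null matrix.
#' @param seed Optional integer seed.
#' @return List: \code{counts} (genes x samples), \code{design} (sample,
#'   condition, replicate), \code{truth} (gene, log2fc of spiked genes),
#'   \code{size_factors} (true values).
#' @export
gen_counts <- function(n_genes = 2000, n_per_cond = 4,
                       conditions = c("control", "mutant"),
                       dispersion = 0.05, base_mean_range = c(10, 10000),
                       sf_sdlog = 0.15,
                       spike_log2fc = c(gene_gsts1_like = -1),
                       seed = NULL) {
  stopifnot(length(conditions) == 2L, n_per_cond >= 2L,
            all(dispersion > 0), length(spike_log2fc) <= n_genes)
  with_seed(seed, {
    nsamp <- 2L * n_per_cond
    sf <- exp(stats::rnorm(nsamp, 0, sf_sdlog))
    sf <- sf / exp(mean(log(sf)))                   # geometric mean 1
    q <- exp(stats::runif(n_genes, log(base_mean_range[1]), log(base_mean_range[2])))
    lfc <- numeric(n_genes)
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    if (length(spike_log2fc)) {
      idx <- seq_along(spike_log2fc)                # spiked genes lead the matrix
      lfc[idx] <- unname(spike_log2fc)
      if (!is.null(names(spike_log2fc))) genes[idx] <- names(spike_log2fc)
    }
    cond <- rep(conditions, each = n_per_cond)
    mu <- outer(q, sf) * 2^(lfc %o% as.numeric(cond == conditions[2]))
    disp <- rep_len(dispersion, n_genes)
    counts <- matrix(stats::rnbinom(n_genes * nsamp, mu = mu,
                                    size = rep(1 / disp, nsamp)),
                     nrow = n_genes)
    rownames(counts) <- genes
    colnames(counts) <- paste0(cond, "_", rep(seq_len(n_per_cond), 2L))
    design <- data.frame(sample = colnames(counts), condition = cond,
                         replicate = rep(seq_len(n_per_cond), 2L),
                         stringsAsFactors = FALSE)
    truth <- data.frame(gene = genes[lfc != 0], log2fc = lfc[lfc != 0],
                        stringsAsFactors = FALSE)
    names(sf) <- colnames(counts)
    list(counts = counts, design = design, truth = truth, size_factors = sf)
  })
}
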