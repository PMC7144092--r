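# Shared fixtures and small independent oracles used across test files.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "modscreen")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

# deficiency screen rows as printed: label, n scored, wings %, thorax %
screen_rows <- data.frame(
  label = c("Df(3R)Exel6164", "Df(2R)BSC335", "Df(2R)BSC856", "Df(2R)BSC271",
            "Df(2R)BSC273", "Df(3L)BSC157", "Df(2R)BSC132", "Df(1)Exel6254",
            "Df(1)Exel6245", "Df(3R)by10", "Df(2R)BSC433"),
  scored = c(72, 59, 68, 67, 66, 150, 51, 34, 26, 57, 56),
  wings_percent = c(95.8, 91.5, 77.9, 94.0, 92.4, 94.7, 68.6, 91.2, 23.1, 89.5, 12.5),
  thorax_percent = c(62.5, 86.4, 83.8, 77.6, 90.9, 70.0, 9.8, 94.2, 80.8, 91.2, 35.7),
  stringsAsFactors = FALSE)
screen_control <- data.frame(label = "No deficiency", scored = 44,
                             wings_percent = 88.6, thorax_percent = 90.9,
                             stringsAsFactors = FALSE)

# independent two-sided Fisher oracle built on the hypergeometric density
# (probability-mass convention), distinct from the package's lchoose path
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; n1 <- a + c; n <- a + b + c + d
  k <- max(0, n1 - (c + d)):min(m1, n1)
  dens <- stats::dhyper(k, m1, c + d, n1)
  sum(dens[dens <= dens[k == a] * (1 + 1e-7)])
}

# brute-force U distribution by explicit loop over subsets (used to check the
# enumeration path independently of the vectorized combn code)
u_enumeration_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1, simplify = FALSE)
  us <- vapply(sets, function(s) sum(r[s]) - n1 * (n1 + 1) / 2, numeric(1))
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}
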