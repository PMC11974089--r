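# Brute-force statistical oracles, written independently of the package's
# code paths, for checking test statistics on tiny tables.

oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

oracle_wilcox_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - mu) / sqrt(v)
  list(statistic = W, p = 2 * pnorm(-abs(z)))
}

oracle_kruskal_h <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_dunn_z <- function(values, groups, a, b) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  (rb[[a]] - rb[[b]]) /
    sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

oracle_spearman <- function(x, y) {
  r <- cor(rank(x), rank(y))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Stejskal-Tanner forward signal for an arbitrary symmetric tensor, written
# without reusing the package's synthesizer
oracle_signal <- function(gtab, D, s0 = 1000) {
  quad <- vapply(seq_along(gtab$bvals), function(i) {
    g <- gtab$bvecs[i, ]
    drop(t(g) %*% D %*% g)
  }, 0)
  s0 * exp(-gtab$bvals * quad)
}

# small uniform-tensor DWI "acquisition" of shape dims
uniform_dwi <- function(D, gtab, dims = c(3, 3, 2), s0 = 1000) {
  sig <- oracle_signal(gtab, D, s0)
  arr <- array(rep(sig, each = prod(dims)), c(dims, length(sig)))
  list(signal = arr, gtab = gtab, affine = diag(4))
}

oracle_fa <- function(D) {
  lam <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (sum(lam^2) == 0) return(0)
  sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
}

sym_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0) {
  matrix(c(dxx, dxy, dxz, dxy, dyy, dyz, dxz, dyz, dzz), 3, 3)
}

# default-parameter cohort spec with only the seed changed
seeded_spec <- local({
  base <- cohort_spec()
  function(seed) { base$seed <- as.integer(seed); base }
})
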