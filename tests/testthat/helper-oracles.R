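# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive second implementation, kept separate
# from the package code paths it checks.

# Weir & Cockerham (1984) per-locus components, scalar textbook form:
# written from the published formulas with explicit sums over the two
# populations, one locus at a time.
oracle_wc_site <- function(geno1, geno2) {
  pops <- list(geno1[!is.na(geno1)], geno2[!is.na(geno2)])
  r <- 2
  n <- vapply(pops, length, numeric(1))
  if (any(n < 2)) return(c(a = NA, b = NA, c = NA))
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# brute-force Q_PC on one trait: explicit loops, no shared code
oracle_qpc <- function(trait, K, test_pcs, neutral_pcs) {
  n <- length(trait)
  Tm <- (diag(n) - matrix(1 / n, n, n))[1:(n - 1), ]
  Kc <- Tm %*% K %*% t(Tm)
  ee <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  zc <- as.vector(Tm %*% trait)
  cm <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    cm[m] <- sum(ee$vectors[, m] * zc) / sqrt(ee$values[m])
  }
  va <- mean(cm[neutral_pcs]^2)
  Fm <- cm[test_pcs]^2 / va
  p <- 1 - pf(Fm, 1, length(neutral_pcs))
  list(F = Fm, p = p, va = va)
}

# complete-enumeration two-sided Fisher p for table [[a,b],[c,d]]
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  xs <- max(0, k - m2):min(m1, k)
  probs <- dhyper(xs, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive median-of-ratios size factors, loop form, rescaled to geomean 1
oracle_size_factors <- function(counts) {
  pos <- apply(counts, 1, function(x) all(x > 0))
  geo <- apply(counts[pos, , drop = FALSE], 1,
               function(x) exp(mean(log(x))))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f[j] <- median(counts[pos, j] / geo)
  }
  f / exp(mean(log(f)))
}

# shared fixture: small structured panel + eigen, cached per session
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_cluster = c(16, 12, 8), n_loci = 600, seed = 42)
      g <- simulate_genotypes(cfg)
      eig <- pc_sets(conditional_eigen(standardized_kinship(g)))
      cache <<- list(cfg = cfg, g = g, eig = eig)
    }
    cache
  }
})

# fake eigen object with a prescribed spectrum, for PC-partition rules
fake_eigen <- function(values) {
  structure(
    list(values = values, usable = values > 0,
         vectors = diag(length(values)),
         Tmat = NULL, K = NULL, K_cond = NULL,
         samples = paste0("s", seq_len(length(values) + 1)),
         provenance = "toy", test_pcs = NULL, neutral_pcs = NULL),
    class = "kinship_eigen"
  )
}
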