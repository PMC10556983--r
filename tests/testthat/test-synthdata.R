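test_that("genotype simulator is deterministic and respects the selfing model", {
  cfg <- sim_config(n_per_cluster = c(8, 6), n_loci = 200, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$loci, g2$loci)

  cfg0 <- sim_config(n_per_cluster = c(8, 6), n_loci = 200,
                     selfing_het_rate = 0, seed = 7)
  g0 <- simulate_genotypes(cfg0)
  expect_false(any(g0$dosage == 1))

  # heterozygous calls appear at roughly the configured rate
  cfg_het <- sim_config(n_per_cluster = c(30, 30), n_loci = 2000,
                        selfing_het_rate = 0.05, seed = 8)
  gh <- simulate_genotypes(cfg_het)
  expect_equal(mean(gh$dosage == 1), 0.05, tolerance = 0.1)
})

test_that("near-zero divergence parameter yields near-zero realized FST", {
  cfg <- sim_config(n_per_cluster = c(40, 40), n_loci = 5000,
                    fst_per_cluster = c(0.001, 0.001), seed = 11)
  g <- simulate_genotypes(cfg)
  pops <- split(g$samples$sample, g$samples$cluster)
  theta <- fst_wc(g, pops[[1]], pops[[2]])
  expect_lt(abs(theta), 0.02)
  # and per-locus components agree with the independent oracle
  for (l in 1:10) {
    o <- oracle_wc_site(g$dosage[1:40, l], g$dosage[41:80, l])
    m <- qpcscan:::wc_components(g$dosage[1:40, l, drop = FALSE],
                                 g$dosage[41:80, l, drop = FALSE])
    expect_equal(unname(o), c(m$a, m$b, m$c), tolerance = 1e-12)
  }
})

test_that("realized FST is monotone in the configured divergence", {
  thetas <- vapply(c(0.05, 0.2, 0.5), function(f) {
    cfg <- sim_config(n_per_cluster = c(30, 30), n_loci = 3000,
                      fst_per_cluster = c(f, f), seed = 13)
    g <- simulate_genotypes(cfg)
    pops <- split(g$samples$sample, g$samples$cluster)
    fst_wc(g, pops[[1]], pops[[2]])
  }, numeric(1))
  expect_true(all(diff(thetas) > 0))
})

test_that("neutral trait simulator realizes the kinship covariance", {
  f <- small_panel()
  eig <- f$eig
  va <- 2.5
  z <- simulate_traits(eig, trait_truth(va_true = va), 4000, seed = 3)
  expect_identical(z, simulate_traits(eig, trait_truth(va_true = va), 4000,
                                      seed = 3))
  zc <- eig$Tmat %*% z
  emp <- tcrossprod(zc) / ncol(zc)
  target <- va * eig$K_cond
  rel_err <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel_err, 0.10)

  # zero variance, no shifts -> constant traits
  z0 <- simulate_traits(eig, trait_truth(va_true = 0), 5, seed = 1)
  expect_true(all(abs(apply(z0, 2, sd)) < 1e-12))

  # a PC1 shift moves the mean projection by delta
  delta <- 4
  sh <- trait_truth(1, shifts = tibble::tibble(trait = 1:200, pc = 1L,
                                               delta = delta))
  zs <- simulate_traits(eig, sh, 200, seed = 5)
  proj <- as.vector(crossprod(eig$vectors[, 1], eig$Tmat %*% zs))
  expect_equal(mean(proj), delta, tolerance = 0.15)

  expect_error(simulate_traits(eig, trait_truth(1,
    shifts = tibble::tibble(trait = 1L, pc = 999L, delta = 1)), 2),
    "exceeds")
})

test_that("expression count simulator has the stated design and moments", {
  cfg <- sim_config(n_per_cluster = c(2, 2), n_reps = 3, seed = 9)
  con <- matrix(0, 4, 5, dimnames = list(paste0("a", 1:4), paste0("g", 1:5)))
  pla <- con
  ex <- simulate_expression_counts(con, pla, cfg)
  expect_equal(nrow(ex$meta), 4 * 2 * 3)
  expect_equal(dim(ex$counts), c(5, 24))
  expect_true(all(c("inland", "coastal") %in% ex$meta$site))
  expect_false(anyDuplicated(ex$meta[c("accession", "site", "replicate")]) > 0)

  # zero plastic trait -> equal expected counts at both sites (up to the
  # shared site effect, which we disable)
  cfg_ns <- sim_config(n_per_cluster = c(2, 2), n_reps = 200,
                       site_effect_sd = 0, nb_dispersion = 0, seed = 10)
  ex2 <- simulate_expression_counts(con, pla, cfg_ns)
  m <- tapply(colMeans(ex2$counts), ex2$meta$site, mean)
  expect_equal(unname(m["inland"]), unname(m["coastal"]), tolerance = 0.05)

  # Poisson limit: variance/mean of replicate counts -> 1
  reps <- ex2$counts[1, ex2$meta$site == "inland" & ex2$meta$accession == "a1"]
  expect_gt(length(reps), 150)
  expect_equal(var(reps) / mean(reps), 1, tolerance = 0.35)

  # dispersed counts are overdispersed
  cfg_nb <- sim_config(n_per_cluster = c(2, 2), n_reps = 200,
                       site_effect_sd = 0, nb_dispersion = 0.5, seed = 10)
  ex3 <- simulate_expression_counts(con, pla, cfg_nb)
  reps3 <- ex3$counts[1, ex3$meta$site == "inland" & ex3$meta$accession == "a1"]
  expect_gt(var(reps3) / mean(reps3), 2)
})

test_that("all-sites simulator marks fixed differences and masks reproducibly", {
  cfg <- sim_config(n_per_cluster = c(6, 6), seed = 21)
  s1 <- simulate_sites(cfg, window_len = 500, n_windows = 2, theta = 0.02,
                       missing_rate = 0.2, n_fixed_diff = 4)
  s2 <- simulate_sites(cfg, window_len = 500, n_windows = 2, theta = 0.02,
                       missing_rate = 0.2, n_fixed_diff = 4)
  expect_identical(s1$alt, s2$alt)
  expect_identical(s1$called, s2$called)
  truth <- attr(s1, "truth")
  expect_length(truth$fixed_diff, 4)
  # fixed sites: pop1 all ref, pop2 all alt among called
  p1 <- s1$samples$sample[s1$samples$pop == "pop1"]
  p2 <- s1$samples$sample[s1$samples$pop == "pop2"]
  for (site in truth$fixed_diff) {
    expect_equal(sum(s1$alt[p1, site]), 0)
    expect_equal(sum(s1$alt[p2, site]), sum(s1$called[p2, site]))
  }
  # theta = 0 -> all invariant -> pi 0
  s0 <- simulate_sites(cfg, window_len = 500, n_windows = 1, theta = 0,
                       missing_rate = 0)
  pw <- pi_window(s0, p1, make_windows(s0, 500))
  expect_equal(pw$pi, 0)
})

test_that("orthogroup simulator honors the polarization probability", {
  og1 <- simulate_orthogroups(5000, p_coastal_ancestral = 0.5, seed = 2)
  af <- ancestral_fraction(og1)
  se <- sd(af$values) / sqrt(length(af$values))
  expect_lt(abs(af$estimate - 0.5), 3 * se)

  og_all <- simulate_orthogroups(50, p_coastal_ancestral = 1, seed = 3)
  expect_equal(ancestral_fraction(og_all)$estimate, 1.0)

  og_small <- simulate_orthogroups(30, sites_per_group = c(1L, 2L), seed = 4)
  expect_error(ancestral_fraction(og_small), "filter")
})
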