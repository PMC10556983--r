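# small builders for exact hand-enumerated examples
two_pop_sites <- function(mask_one = FALSE) {
  # 4 diploids (2 per pop), 10 sites; site 1 is a fixed difference
  called <- matrix(2L, 4, 10)
  alt <- matrix(0L, 4, 10)
  alt[3:4, 1] <- 2L
  if (mask_one) {
    called[1, 1] <- 0L
  }
  site_calls(tibble::tibble(chrom = "c", pos = 1:10), called, alt,
             tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            pop = rep(c("A", "B"), each = 2)))
}

test_that("pi reproduces the hand-enumerated all-sites example", {
  # within pop spanning the fixed difference: dosages 0 and 2
  called <- matrix(2L, 2, 10)
  alt <- matrix(0L, 2, 10)
  alt[2, 1] <- 2L
  sc <- site_calls(tibble::tibble(chrom = "c", pos = 1:10), called, alt,
                   tibble::tibble(sample = c("x", "y")))
  w <- make_windows(sc, 100)
  pw <- pi_window(sc, c("x", "y"), w)
  # site 1: 4 alleles, 2 alt -> 4 differing pairs of C(4,2)=6; 10 sites
  expect_equal(pw$diff_sum, 4)
  expect_equal(pw$comp_sum, 60)
  expect_equal(pw$pi, 4 / 60)
  # masking one diploid at the variant site leaves 1 comparison, 0 diffs
  sc2 <- sc
  sc2$called[1, 1] <- 0L
  sc2$alt[1, 1] <- 0L
  pw2 <- pi_window(sc2, c("x", "y"), w)
  expect_equal(pw2$diff_sum, 0)
  expect_equal(pw2$comp_sum, 1 + 9 * 6)
})

test_that("D_XY reproduces its hand example and is symmetric", {
  sc <- two_pop_sites()
  w <- make_windows(sc, 100)
  d <- dxy_window(sc, c("a1", "a2"), c("b1", "b2"), w)
  expect_equal(d$diff_sum, 16)
  expect_equal(d$comp_sum, 160)
  expect_equal(d$dxy, 0.1)
  d2 <- dxy_window(sc, c("b1", "b2"), c("a1", "a2"), w)
  expect_equal(d2$dxy, d$dxy)
  # identical monomorphic pops diverge by zero
  sc0 <- sc
  sc0$alt[] <- 0L
  expect_equal(dxy_window(sc0, c("a1", "a2"), c("b1", "b2"), w)$dxy, 0)
})

test_that("adding invariant called sites dilutes pi and D_XY exactly", {
  sc <- two_pop_sites()
  w10 <- make_windows(sc, 100)
  d10 <- dxy_window(sc, c("a1", "a2"), c("b1", "b2"), w10)
  # same data with 10 more invariant sites
  called <- cbind(sc$called, matrix(2L, 4, 10))
  alt <- cbind(sc$alt, matrix(0L, 4, 10))
  sc20 <- site_calls(tibble::tibble(chrom = "c", pos = 1:20), called, alt,
                     sc$samples)
  d20 <- dxy_window(sc20, c("a1", "a2"), c("b1", "b2"), make_windows(sc20, 100))
  expect_equal(d20$diff_sum, d10$diff_sum)          # diffs unchanged
  expect_equal(d20$dxy, d10$dxy * d10$comp_sum / d20$comp_sum)
  expect_lt(d20$dxy, d10$dxy)
})

test_that("windows with zero comparisons report missing, never zero", {
  called <- matrix(0L, 2, 5)
  alt <- matrix(0L, 2, 5)
  sc <- site_calls(tibble::tibble(chrom = "c", pos = 1:5), called, alt,
                   tibble::tibble(sample = c("x", "y")))
  pw <- suppressWarnings(pi_window(sc, c("x", "y"), make_windows(sc, 100)))
  expect_true(is.na(pw$pi))
  expect_equal(pw$comp_sum, 0)
})

test_that("Weir-Cockerham FST: fixed difference gives theta 1; components match the oracle", {
  d1 <- matrix(0, 5, 8)
  d2 <- matrix(2, 5, 8)
  g <- genotype_matrix(rbind(d1, d2),
    tibble::tibble(chrom = "c", pos = 1:8, ref = "A", alt = "T"),
    tibble::tibble(sample = sprintf("s%02d", 1:10)))
  expect_equal(fst_wc(g, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10)), 1)
  # random datasets vs the scalar textbook oracle
  withr::with_seed(51, {
    for (rep in 1:20) {
      dos <- matrix(sample(0:2, 10 * 20, replace = TRUE), 10, 20)
      dos[sample(length(dos), 15)] <- NA
      m <- qpcscan:::wc_components(dos[1:5, , drop = FALSE],
                                   dos[6:10, , drop = FALSE])
      for (l in sample(20, 5)) {
        o <- oracle_wc_site(dos[1:5, l], dos[6:10, l])
        if (all(is.na(o))) {
          expect_true(is.na(m$a[l]))
        } else {
          expect_equal(unname(o), c(m$a[l], m$b[l], m$c[l]), tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("a randomly split panmictic population has near-zero FST", {
  withr::with_seed(53, {
    p <- runif(2000, 0.1, 0.9)
    dos <- matrix(rbinom(100 * 2000, 2, rep(p, each = 100)), 100, 2000)
  })
  g <- genotype_matrix(dos,
    tibble::tibble(chrom = "c", pos = 1:2000, ref = "A", alt = "T"),
    tibble::tibble(sample = sprintf("s%03d", 1:100)))
  theta <- fst_wc(g, sprintf("s%03d", 1:50), sprintf("s%03d", 51:100))
  expect_lt(abs(theta), 0.01)
})

test_that("window statistics are ratios of sums, not means of ratios", {
  called <- matrix(2L, 2, 2)
  alt <- rbind(c(1L, 0L), c(2L, 1L))  # two variant sites, unequal tallies
  sc <- site_calls(tibble::tibble(chrom = "c", pos = 1:2), called, alt,
                   tibble::tibble(sample = c("x", "y")))
  pw <- suppressWarnings(pi_window(sc, c("x", "y"), make_windows(sc, 100)))
  per_site <- c((3 * 1) / 6, (1 * 3) / 6)
  expect_equal(pw$pi, sum(c(3, 3)) / 12)
  expect_equal(pw$pi, mean(per_site))  # equal here because comps are equal...
  alt2 <- rbind(c(1L, 0L), c(2L, 0L))
  sc2 <- site_calls(tibble::tibble(chrom = "c", pos = 1:2), called, alt2,
                    tibble::tibble(sample = c("x", "y")))
  sc2$called[2, 2] <- 0L
  pw2 <- suppressWarnings(pi_window(sc2, c("x", "y"), make_windows(sc2, 100)))
  site1 <- 3 * 1 / choose(4, 2)
  site2 <- 0 / choose(2, 2)
  expect_false(isTRUE(all.equal(pw2$pi, mean(c(site1, site2)))))
  expect_equal(pw2$pi, 3 / (choose(4, 2) + choose(2, 2)))
})

test_that("feature aggregation sums intervals before the ratio", {
  sc <- two_pop_sites()
  feats <- tibble::tibble(
    gene_id = "g1", feature = c("CDS", "CDS"),
    chrom = "c", start = c(0L, 5L), end = c(3L, 8L))
  fs <- feature_stats(sc, feats, pops = list(A = c("a1", "a2"),
                                             B = c("b1", "b2")))
  dxy_row <- fs[fs$stat == "dxy", ]
  # 6 covered sites incl. the fixed difference: 16 diffs over 6*16 comps
  expect_equal(dxy_row$diff_sum, 16)
  expect_equal(dxy_row$comp_sum, 96)
  expect_equal(dxy_row$value, 16 / 96)
  # a feature equal to the whole window matches the window statistic
  all_feat <- tibble::tibble(gene_id = "g1", feature = "gene",
                             chrom = "c", start = 0L, end = 100L)
  fs_all <- feature_stats(sc, all_feat, pops = list(A = c("a1", "a2"),
                                                    B = c("b1", "b2")))
  w <- dxy_window(sc, c("a1", "a2"), c("b1", "b2"), make_windows(sc, 100))
  expect_equal(fs_all$value[fs_all$stat == "dxy"], w$dxy)
  # empty features -> empty output; uncovered feature -> missing value
  expect_equal(nrow(feature_stats(sc, feats[0, ], pops = list(A = "a1"))), 0)
  far <- tibble::tibble(gene_id = "g2", feature = "CDS",
                        chrom = "c", start = 50L, end = 60L)
  fs_far <- feature_stats(sc, far, pops = list(A = c("a1", "a2")))
  expect_true(all(is.na(fs_far$value)))
})

test_that("gene-set comparisons detect a shifted set and report SEs", {
  withr::with_seed(57, {
    vals <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:200),
      value = c(rnorm(100, 0.5, 0.1), rnorm(100, 0.3, 0.1)))
  })
  sets <- list(CDE = sprintf("g%03d", 1:100), NDE = sprintf("g%03d", 101:200))
  cmp <- compare_gene_sets(vals, sets)
  expect_lt(tidy(cmp)$adj.p.value[1], 1e-6)
  s <- cmp$summary
  expect_equal(s$se, c(sd(vals$value[1:100]) / 10, sd(vals$value[101:200]) / 10),
               tolerance = 1e-10)
  expect_error(compare_gene_sets(vals, list(A = "g001", B = "g001")),
               "disjoint")
})
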