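#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data module in one validated list.
#' Defaults emulate the study system the package targets: three genetic
#' clusters of a highly selfing grass (86 accessions split 53/22/11), a
#' desk-scale neutral SNP panel of 5,000 loci, three replicates per accession
#' at each of two transplant sites, and near-complete homozygosity.
#'
#' @param n_per_cluster Integer vector: accessions per genetic cluster.
#' @param n_loci Number of neutral SNPs to simulate.
#' @param fst_per_cluster Balding-Nichols divergence parameter of each cluster
#'   from the shared ancestral pool; all in (0, 1).
#' @param selfing_het_rate Expected per-site fraction of heterozygous calls in
#'   an individual. Selfers are modelled as drawn homozygotes with this small
#'   residual heterozygosity.
#' @param n_reps Replicates per accession x site.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson counts.
#' @param site_effect_sd SD of the per-site log2 offset shared by all genes.
#' @param gxe_sd SD of residual gene x site log2 noise (beyond the plastic
#'   trait).
#' @param va Additive genetic variance of simulated neutral traits.
#' @param seed Integer seed; identical configs generate identical data.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_cluster = c(53L, 22L, 11L),
                       n_loci = 5000L,
                       fst_per_cluster = 0.25,
                       selfing_het_rate = 0.01,
                       n_reps = 3L,
                       nb_dispersion = 0.1,
                       site_effect_sd = 0.5,
                       gxe_sd = 0,
                       va = 1,
                       seed = 1L) {
  if (length(fst_per_cluster) == 1L) {
    fst_per_cluster <- rep(fst_per_cluster, length(n_per_cluster))
  }
  stopifnot(length(fst_per_cluster) == length(n_per_cluster))
  if (any(n_per_cluster < 2)) abort("each cluster needs n >= 2 accessions.")
  if (any(fst_per_cluster <= 0 | fst_per_cluster >= 1)) {
    abort("`fst_per_cluster` values must lie in (0, 1).")
  }
  assert_fraction(selfing_het_rate, "selfing_het_rate")
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  if (n_loci < 2 || n_reps < 1) abort("`n_loci` >= 2 and `n_reps` >= 1 required.")
  structure(
    list(n_per_cluster = as.integer(n_per_cluster),
         n_loci = as.integer(n_loci),
         fst_per_cluster = as.numeric(fst_per_cluster),
         selfing_het_rate = selfing_het_rate,
         n_reps = as.integer(n_reps),
         nb_dispersion = nb_dispersion,
         site_effect_sd = site_effect_sd,
         gxe_sd = gxe_sd,
         va = va,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate structured selfing genotypes
#'
#' Draws per-cluster allele frequencies under the Balding-Nichols F-model
#' (Beta around an ancestral frequency, spread set by the cluster's FST) and
#' then samples individuals as selfing homozygotes: each dosage is
#' `2 * Bernoulli(p_cluster)` except for a `selfing_het_rate` fraction of
#' heterozygous calls. Loci monomorphic across all samples are removed.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with cluster labels attached.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$n_per_cluster)
  n <- sum(config$n_per_cluster)
  L <- config$n_loci
  with_seed_(derive_seed(config$seed, 1L), {
    p_anc <- runif(L, 0.05, 0.95)
    dosage <- matrix(NA_real_, n, L)
    cluster <- rep(paste0("cluster", seq_len(k)), config$n_per_cluster)
    row0 <- 0L
    for (cc in seq_len(k)) {
      f <- config$fst_per_cluster[cc]
      nc <- config$n_per_cluster[cc]
      p_cl <- rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      allele <- matrix(rbinom(nc * L, 1L, rep(p_cl, each = nc)), nc, L)
      dos <- 2 * allele
      if (config$selfing_het_rate > 0) {
        het <- matrix(rbinom(nc * L, 1L, config$selfing_het_rate), nc, L) == 1L
        dos[het] <- 1
      }
      dosage[row0 + seq_len(nc), ] <- dos
      row0 <- row0 + nc
    }
  })
  poly <- apply(dosage, 2, function(x) length(unique(x)) > 1L)
  if (!any(poly)) {
    abort("simulation produced no polymorphic loci; adjust the config.")
  }
  dosage <- dosage[, poly, drop = FALSE]
  loci <- tibble::tibble(
    chrom = "Chr01",
    pos = which(poly) * 50L,
    ref = "A", alt = "T"
  )
  samples <- tibble::tibble(
    sample = sprintf("acc%03d", seq_len(n)),
    cluster = cluster
  )
  genotype_matrix(dosage, loci, samples, provenance = "simulated")
}

#' Ground-truth description of simulated traits
#'
#' @param va_true Additive genetic variance of the neutral model.
#' @param shifts Tibble (or data frame) with columns `trait`, `pc`, `delta`:
#'   trait indices receiving a mean shift of `delta` along eigenvector `pc` of
#'   the conditional kinship matrix. Traits absent from `shifts` are neutral.
#' @return A list of class `trait_truth`.
#' @export
trait_truth <- function(va_true = 1,
                        shifts = tibble::tibble(trait = integer(),
                                                pc = integer(),
                                                delta = numeric())) {
  shifts <- tibble::as_tibble(shifts)
  stopifnot(all(c("trait", "pc", "delta") %in% names(shifts)))
  if (va_true < 0) abort("`va_true` must be >= 0.")
  if (nrow(shifts) && any(shifts$pc < 1)) abort("shift `pc` indices start at 1.")
  structure(list(va_true = va_true, shifts = shifts), class = "trait_truth")
}

#' Simulate traits under the neutral kinship model
#'
#' Neutral traits are multivariate normal with covariance
#' `va_true * K_cond` in the mean-centered space: `z_c = U Lambda^{1/2} w
#' sqrt(va_true)` with `w` standard normal. Selected traits are additionally
#' shifted by `delta` along the chosen eigenvector. Traits are lifted back to
#' accession space (the test is translation invariant, so the lift adds an
#' arbitrary constant).
#'
#' @param eigen A [conditional_eigen()] result.
#' @param truth A [trait_truth()].
#' @param n_traits Number of traits to generate.
#' @param seed Integer seed.
#' @return Matrix accessions x traits, rownames = sample ids.
#' @export
simulate_traits <- function(eigen, truth, n_traits, seed = 1L) {
  stopifnot(inherits(eigen, "kinship_eigen"), inherits(truth, "trait_truth"))
  lam <- eigen$values
  U <- eigen$vectors
  m <- length(lam)
  if (nrow(truth$shifts) && any(truth$shifts$pc > m)) {
    abort("shift `pc` index exceeds the number of available PCs.")
  }
  zc <- with_seed_(seed, {
    W <- matrix(rnorm(m * n_traits), m, n_traits)
    U %*% (sqrt(pmax(lam, 0)) * W) * sqrt(truth$va_true)
  })
  if (nrow(truth$shifts)) {
    for (i in seq_len(nrow(truth$shifts))) {
      s <- truth$shifts[i, ]
      zc[, s$trait] <- zc[, s$trait] + s$delta * U[, s$pc]
    }
  }
  # lift: choose z with z_head = z_c and sum(z) = 0, so that T z = z_c
  z <- rbind(zc, -colSums(zc))
  rownames(z) <- eigen$samples
  colnames(z) <- sprintf("trait%04d", seq_len(n_traits))
  z
}

#' Simulate two-site expression counts from trait matrices
#'
#' For accession `i`, site `s` and gene `g` the log2 mean is
#' `baseline_g + constitutive_ig + (+/- 1/2) plastic_ig + site_effect_s`
#' (the plastic effect is split evenly so the coastal - inland difference of
#' log2 means equals the plastic trait exactly; the coastal site gets the
#' `+1/2` share). Counts are negative binomial with the configured
#' dispersion; `nb_dispersion = 0` gives Poisson counts.
#'
#' @param constitutive,plastic Accession x gene trait matrices (same shape).
#' @param config A [sim_config()]; uses `n_reps`, `nb_dispersion`,
#'   `site_effect_sd`, `gxe_sd` and `seed`.
#' @param baseline Per-gene baseline log2 expression (recycled; default 5).
#' @return List with `counts` (genes x samples integer matrix) and `meta`
#'   (tibble: `sample`, `accession`, `cluster`, `site`, `replicate`).
#' @export
simulate_expression_counts <- function(constitutive, plastic, config,
                                       baseline = 5) {
  stopifnot(inherits(config, "sim_config"),
            identical(dim(constitutive), dim(plastic)))
  if (config$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  n_acc <- nrow(constitutive)
  n_gene <- ncol(constitutive)
  acc <- rownames(constitutive) %||% sprintf("acc%03d", seq_len(n_acc))
  genes <- colnames(constitutive) %||% sprintf("gene%04d", seq_len(n_gene))
  cluster <- attr(constitutive, "cluster") %||% rep(NA_character_, n_acc)
  baseline <- rep_len(baseline, n_gene)
  sites <- c("inland", "coastal")
  meta <- tidyr::expand_grid(
    accession = acc, site = sites, replicate = seq_len(config$n_reps)
  )
  meta$cluster <- cluster[match(meta$accession, acc)]
  meta$sample <- sprintf("%s_%s_r%d", meta$accession,
                         substr(meta$site, 1, 4), meta$replicate)
  meta <- meta[, c("sample", "accession", "cluster", "site", "replicate")]
  counts <- with_seed_(derive_seed(config$seed, 3L), {
    site_eff <- rnorm(2, 0, config$site_effect_sd)
    out <- matrix(0L, n_gene, nrow(meta),
                  dimnames = list(genes, meta$sample))
    for (j in seq_len(nrow(meta))) {
      i <- match(meta$accession[j], acc)
      s <- match(meta$site[j], sites)
      sign <- if (sites[s] == "coastal") +0.5 else -0.5
      l2 <- baseline + constitutive[i, ] + sign * plastic[i, ] + site_eff[s]
      if (config$gxe_sd > 0) l2 <- l2 + rnorm(n_gene, 0, config$gxe_sd)
      mu <- 2^l2
      out[, j] <- if (config$nb_dispersion == 0) {
        rpois(n_gene, mu)
      } else {
        rnbinom(n_gene, size = 1 / config$nb_dispersion, mu = mu)
      }
    }
    out
  })
  list(counts = counts, meta = meta)
}

#' Simulate all-sites sequence windows with missingness
#'
#' Generates contiguous windows of invariant and variant sites for two or more
#' populations of selfing homozygotes. Each site is variant with probability
#' `theta`; variant sites get Balding-Nichols per-population frequencies. An
#' optional number of sites fixed for alternate alleles between the first two
#' populations can be planted (ground truth for divergence checks). Calls are
#' masked missing independently at `missing_rate`.
#'
#' @param config A [sim_config()] (cluster sizes and FST reused as population
#'   structure; the seed stream is independent of the genotype simulator's).
#' @param window_len Window length in bp; sites are placed at every bp.
#' @param n_windows Number of contiguous windows.
#' @param theta Per-site probability that a site is variant, in (0, 0.5).
#' @param missing_rate Per-call missing probability in `[0, 1)`.
#' @param n_fixed_diff Number of variant sites forced to fixed alternate
#'   differences between populations 1 and 2.
#' @return A [site_calls()] object; ground-truth site classes in
#'   `attr(, "truth")`.
#' @export
simulate_sites <- function(config, window_len = 1000L, n_windows = 5L,
                           theta = 0.01, missing_rate = 0.1,
                           n_fixed_diff = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (theta < 0 || theta >= 0.5) abort("`theta` must be in [0, 0.5).")
  assert_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  k <- length(config$n_per_cluster)
  n <- sum(config$n_per_cluster)
  S <- as.integer(window_len) * as.integer(n_windows)
  pop <- rep(paste0("pop", seq_len(k)), config$n_per_cluster)
  with_seed_(derive_seed(config$seed, 4L), {
    is_var <- runif(S) < theta
    fixed <- integer(0)
    if (n_fixed_diff > 0) {
      cand <- which(!is_var)
      fixed <- cand[seq_len(min(n_fixed_diff, length(cand)))]
      is_var[fixed] <- TRUE
    }
    alt <- matrix(0L, n, S)
    p_pop <- matrix(0, k, S)
    vi <- which(is_var)
    if (length(vi)) {
      p_anc <- runif(length(vi), 0.1, 0.9)
      for (cc in seq_len(k)) {
        f <- config$fst_per_cluster[cc]
        p_pop[cc, vi] <- rbeta(length(vi), p_anc * (1 - f) / f,
                               (1 - p_anc) * (1 - f) / f)
      }
    }
    if (length(fixed)) {
      p_pop[1, fixed] <- 0
      if (k >= 2) p_pop[2, fixed] <- 1
      if (k > 2) p_pop[3:k, fixed] <- 0
    }
    for (cc in seq_len(k)) {
      rows <- which(pop == paste0("pop", cc))
      idx <- vi
      if (length(idx)) {
        draws <- matrix(rbinom(length(rows) * length(idx), 1L,
                               rep(p_pop[cc, idx], each = length(rows))),
                        length(rows), length(idx))
        alt[rows, idx] <- 2L * draws
      }
    }
    called <- matrix(2L, n, S)
    if (missing_rate > 0) {
      miss <- matrix(runif(n * S) < missing_rate, n, S)
      called[miss] <- 0L
      alt[miss] <- 0L
    }
  })
  sites <- tibble::tibble(chrom = "Chr01", pos = seq_len(S))
  samples <- tibble::tibble(sample = sprintf("ind%03d", seq_len(n)), pop = pop)
  sc <- site_calls(sites, called, alt, samples)
  attr(sc, "truth") <- list(variant = which(is_var), fixed_diff = fixed,
                            p_pop = p_pop)
  sc
}

#' Simulate outgroup-polarized orthogroup alleles
#'
#' Each orthogroup carries a set of variant sites between the inland and
#' coastal clusters; the ancestral state equals the coastal allele with
#' probability `p_coastal_ancestral`, otherwise the inland allele.
#'
#' @param n_groups Number of orthogroups.
#' @param sites_per_group Integer range (length 2) of variant sites per group,
#'   drawn uniformly.
#' @param p_coastal_ancestral Probability that the coastal allele is the
#'   ancestral state at a site.
#' @param seed Integer seed.
#' @return Tibble: `orthogroup`, `site`, `inland`, `coastal`, `ancestral`.
#' @export
simulate_orthogroups <- function(n_groups, sites_per_group = c(3L, 8L),
                                 p_coastal_ancestral = 0.5, seed = 1L) {
  assert_fraction(p_coastal_ancestral, "p_coastal_ancestral")
  stopifnot(length(sites_per_group) == 2L,
            sites_per_group[1] <= sites_per_group[2])
  bases <- c("A", "C", "G", "T")
  with_seed_(seed, {
    ns <- sample(seq(sites_per_group[1], sites_per_group[2]),
                 n_groups, replace = TRUE)
    total <- sum(ns)
    inland <- sample(bases, total, replace = TRUE)
    shift <- sample(1:3, total, replace = TRUE)
    coastal <- bases[(match(inland, bases) - 1L + shift) %% 4L + 1L]
    coastal_anc <- runif(total) < p_coastal_ancestral
    tibble::tibble(
      orthogroup = rep(sprintf("OG%05d", seq_len(n_groups)), ns),
      site = unlist(lapply(ns, seq_len)),
      inland = inland,
      coastal = coastal,
      ancestral = ifelse(coastal_anc, coastal, inland)
    )
  })
}
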