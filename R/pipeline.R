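# End-to-end orchestration: simulate -> filter -> kinship -> traits -> Q_PC
# -> DAPC plasticity -> popgen -> ancestry -> enrichment, with plain-text
# artifacts (TSV + JSON) so reruns can be diffed byte-for-byte.

#' Pipeline run configuration
#'
#' All knobs of the demonstration pipeline with their standard defaults
#' (20-kb windows, FDR 0.1, test/neutral PC fractions 0.25/0.50,
#' low-expression mean-count cutoff 1, 2-kb promoters, >= 3 variant sites,
#' 10,000 bootstrap replicates). Unknown arguments are rejected.
#'
#' @param seed Run seed; every stage derives its own stream from it.
#' @param n_per_cluster,n_loci,fst_per_cluster,selfing_het_rate,n_reps,nb_dispersion,site_effect_sd,va
#'   Passed to [sim_config()].
#' @param n_genes Number of simulated genes.
#' @param n_shifted Genes given a PC1 mean shift on the constitutive trait.
#' @param shift_ncp Noncentrality `delta^2 / (va * lambda_1)` of the shift.
#' @param test_fraction,neutral_fraction PC partition fractions.
#' @param fdr q-value threshold for outlier calls.
#' @param window Popgen window size (bp).
#' @param min_mean Low-expression filter threshold.
#' @param promoter_length Promoter length (bp).
#' @param sites_window_len,sites_n_windows,theta,missing_rate All-sites
#'   simulation shape.
#' @param n_orthogroups,p_coastal_ancestral,min_variant_sites,n_boot
#'   Ancestry stage parameters.
#' @param ... Unknown keys; any use is an error.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_cluster = c(53L, 22L, 11L),
                       n_loci = 5000L,
                       fst_per_cluster = c(0.25, 0.25, 0.25),
                       selfing_het_rate = 0.01,
                       n_reps = 3L,
                       nb_dispersion = 0.05,
                       site_effect_sd = 0.5,
                       va = 0.25,
                       n_genes = 200L,
                       n_shifted = 20L,
                       shift_ncp = 16,
                       test_fraction = 0.25,
                       neutral_fraction = 0.50,
                       fdr = 0.1,
                       window = 20000L,
                       min_mean = 1.0,
                       promoter_length = 2000L,
                       sites_window_len = 2000L,
                       sites_n_windows = 5L,
                       theta = 0.01,
                       missing_rate = 0.1,
                       n_orthogroups = 500L,
                       p_coastal_ancestral = 0.5,
                       min_variant_sites = 3L,
                       n_boot = 10000L,
                       ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste("unknown config key(s):",
                paste(names(extra), collapse = ", ")))
  }
  cfg <- as.list(environment())
  cfg$extra <- NULL
  structure(cfg, class = "run_config")
}

#' Small, fast demonstration configuration
#'
#' @param seed Run seed.
#' @return A [run_config()] scaled down for quick demonstration runs.
#' @export
demo_run_config <- function(seed = 1L) {
  run_config(seed = seed,
             n_per_cluster = c(14L, 10L, 8L), n_loci = 600L,
             n_genes = 80L, n_shifted = 8L,
             sites_n_windows = 3L, sites_window_len = 1000L,
             n_orthogroups = 200L, n_boot = 1000L)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- tibble::as_tibble(as.data.frame(m), rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

write_json_ <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline into a directory
#'
#' Executes the stages in dependency order — simulate genotypes, filter the
#' neutral panel, build the conditional kinship, simulate traits and counts,
#' derive constitutive/plastic traits, Q_PC scans, DAPC plasticity, windowed
#' popgen statistics, ancestry bootstrap, and enrichment of the truly
#' shifted genes among the called outliers — writing every artifact as TSV or
#' JSON. Rerunning with the same config reproduces identical bytes.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created; must not require parents).
#' @return Invisibly, a list with the in-memory stage results and `outdir`.
#' @export
run_end_to_end <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_out <- config
  class(cfg_out) <- NULL
  write_json_(cfg_out, file.path(outdir, "config.json"))

  # stage 1: genotypes + kinship
  sc <- sim_config(n_per_cluster = config$n_per_cluster,
                   n_loci = config$n_loci,
                   fst_per_cluster = config$fst_per_cluster,
                   selfing_het_rate = config$selfing_het_rate,
                   n_reps = config$n_reps,
                   nb_dispersion = config$nb_dispersion,
                   site_effect_sd = config$site_effect_sd,
                   va = config$va,
                   seed = derive_seed(config$seed, 11L))
  geno <- simulate_genotypes(sc)
  write_vcf(geno, file.path(outdir, "genotypes.vcf"))
  panel <- filter_sites(geno, preset = "neutral-panel")
  K <- standardized_kinship(panel)
  write_matrix_tsv(K, file.path(outdir, "kinship.tsv"), "sample")
  eig <- pc_sets(conditional_eigen(K),
                 test_fraction = config$test_fraction,
                 neutral_fraction = config$neutral_fraction)
  write_json_(list(values = eig$values, test_pcs = eig$test_pcs,
                   neutral_pcs = eig$neutral_pcs,
                   provenance = eig$provenance),
              file.path(outdir, "eigen.json"))

  # stage 2: traits and counts with known truth
  lam1 <- eig$values[1]
  delta <- sqrt(config$shift_ncp * config$va * lam1)
  shifts <- if (config$n_shifted > 0) {
    tibble::tibble(trait = seq_len(config$n_shifted), pc = 1L, delta = delta)
  } else {
    tibble::tibble(trait = integer(), pc = integer(), delta = numeric())
  }
  truth <- trait_truth(va_true = config$va, shifts = shifts)
  g_const <- simulate_traits(eig, truth, config$n_genes,
                             seed = derive_seed(config$seed, 12L))
  g_plast <- simulate_traits(eig, trait_truth(va_true = config$va),
                             config$n_genes,
                             seed = derive_seed(config$seed, 13L))
  colnames(g_const) <- colnames(g_plast) <-
    sprintf("gene%04d", seq_len(config$n_genes))
  attr(g_const, "cluster") <- panel$samples$cluster
  expr <- simulate_expression_counts(g_const, g_plast, sc)
  readr::write_tsv(tibble::as_tibble(as.data.frame(expr$counts),
                                     rownames = "gene"),
                   file.path(outdir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(expr$meta, file.path(outdir, "sample_meta.tsv"),
                   progress = FALSE)
  write_json_(list(va_true = config$va, shift_delta = delta,
                   shifted_genes = colnames(g_const)[shifts$trait]),
              file.path(outdir, "truth.json"))

  counts <- filter_low_expression(expr$counts, min_mean = config$min_mean)
  norm <- vst_normalize(counts)
  traits <- constitutive_plastic(accession_site_means(norm, expr$meta))
  write_matrix_tsv(traits$constitutive,
                   file.path(outdir, "traits_constitutive.tsv"), "accession")
  write_matrix_tsv(traits$plastic,
                   file.path(outdir, "traits_plastic.tsv"), "accession")

  # stage 3: Q_PC scans
  scan_c <- qpc_scan(traits, eig, which = "constitutive", fdr = config$fdr)
  scan_p <- qpc_scan(traits, eig, which = "plastic", fdr = config$fdr)
  readr::write_tsv(tibble::as_tibble(scan_c),
                   file.path(outdir, "qpc_constitutive.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(scan_p),
                   file.path(outdir, "qpc_plastic.tsv"), progress = FALSE)
  out_c <- call_outliers(scan_c, config$fdr)
  out_p <- call_outliers(scan_p, config$fdr)
  write_json_(list(
    constitutive = list(n_outliers = length(out_c$union),
                        multi_pc = length(out_c$multi_pc)),
    plastic = list(n_outliers = length(out_p$union),
                   multi_pc = length(out_p$multi_pc))
  ), file.path(outdir, "qpc_summary.json"))

  # stage 4: DAPC plasticity on the transcriptome
  clusters <- sort(unique(expr$meta$cluster))
  native_map <- stats::setNames(
    c(rep("inland", length(clusters) - 1), "coastal"), clusters)
  native <- expr$meta$site == unname(native_map[expr$meta$cluster])
  X <- t(norm)
  fit <- dapc_fit(X[expr$meta$sample[native], , drop = FALSE],
                  expr$meta$cluster[native],
                  n_pcs = min(10L, sum(native) - length(clusters) - 1L))
  proj <- dapc_project(fit, X)
  plast <- plasticity(proj$scores[, 1], expr$meta, native_map)
  readr::write_tsv(plast, file.path(outdir, "plasticity.tsv"),
                   progress = FALSE)
  ptest <- plasticity_test(plast)
  write_json_(list(anova = as.list(ptest$anova),
                   tukey = ptest$tukey),
              file.path(outdir, "plasticity_test.json"))

  # stage 5: windowed popgen statistics
  sites <- simulate_sites(sc, window_len = config$sites_window_len,
                          n_windows = config$sites_n_windows,
                          theta = config$theta,
                          missing_rate = config$missing_rate)
  wins <- make_windows(sites, size = config$sites_window_len)
  pops <- split(sites$samples$sample, sites$samples$pop)
  pi_tabs <- purrr::imap_dfr(pops, function(ss, nm) {
    dplyr::mutate(pi_window(sites, ss, wins), pop = nm, stat = "pi",
                  value = .data$pi, pi = NULL)
  })
  pair <- utils::combn(names(pops), 2, simplify = FALSE)
  dxy_tabs <- purrr::map_dfr(pair, function(pr) {
    dplyr::mutate(dxy_window(sites, pops[[pr[1]]], pops[[pr[2]]], wins),
                  pop = paste(pr, collapse = ":"), stat = "dxy",
                  value = .data$dxy, dxy = NULL)
  })
  cl_pops <- split(panel$samples$sample, panel$samples$cluster)
  gwins <- make_windows(panel$loci, size = config$window)
  fst_tabs <- purrr::map_dfr(utils::combn(names(cl_pops), 2, simplify = FALSE),
    function(pr) {
      dplyr::mutate(
        fst_wc_window(panel, cl_pops[[pr[1]]], cl_pops[[pr[2]]], gwins),
        pop = paste(pr, collapse = ":"), stat = "fst",
        value = .data$fst, fst = NULL)
    })
  popgen <- dplyr::bind_rows(
    dplyr::select(pi_tabs, "chrom", "start", "end", "stat", "pop", "value"),
    dplyr::select(dxy_tabs, "chrom", "start", "end", "stat", "pop", "value"),
    dplyr::select(fst_tabs, "chrom", "start", "end", "stat", "pop", "value")
  )
  readr::write_tsv(popgen, file.path(outdir, "popgen_windows.tsv"),
                   progress = FALSE)

  # stage 6: ancestry polarization
  og <- simulate_orthogroups(config$n_orthogroups,
                             p_coastal_ancestral = config$p_coastal_ancestral,
                             seed = derive_seed(config$seed, 16L))
  af <- ancestral_fraction(og, min_variant_sites = config$min_variant_sites)
  ci <- bootstrap_ci(af, n_boot = config$n_boot,
                     seed = derive_seed(config$seed, 17L))
  write_json_(list(estimate = af$estimate, lower = ci$lower,
                   upper = ci$upper, n_orthogroups = ci$n_orthogroups,
                   n_boot = ci$n_boot),
              file.path(outdir, "ancestry.json"))

  # stage 7: enrichment of true shifts among called outliers
  enr <- fisher_enrichment(hits = out_c$union,
                           category = colnames(g_const)[shifts$trait],
                           universe = unique(scan_c$gene))
  write_json_(c(as.list(tidy(enr))),
              file.path(outdir, "enrichment.json"))

  invisible(list(outdir = outdir, config = config, genotypes = geno,
                 panel = panel, eigen = eig, traits = traits,
                 scan_constitutive = scan_c, scan_plastic = scan_p,
                 outliers_constitutive = out_c, outliers_plastic = out_p,
                 plasticity = plast, plasticity_test = ptest,
                 popgen = popgen, ancestry = list(fraction = af, ci = ci),
                 enrichment = enr, truth = truth))
}
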