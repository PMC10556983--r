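# Missing-data-aware diversity and differentiation statistics.
# pi and D_XY follow the all-sites convention: per-site pairwise difference
# and comparison counts are summed over a window and the statistic is the
# ratio of sums, so missing calls shrink the denominator rather than the
# site list.

#' Tile chromosomes into non-overlapping windows
#'
#' @param sites A [site_calls()] object (or tibble with `chrom`, `pos`)
#'   whose extent defines the tiling.
#' @param size Window size in bp (default 20 kb).
#' @return Tibble `chrom`, `start` (0-based), `end` (exclusive).
#' @export
make_windows <- function(sites, size = 20000L) {
  st <- if (inherits(sites, "site_calls")) sites$sites else tibble::as_tibble(sites)
  ext <- st |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(max_pos = max(.data$pos), .groups = "drop")
  purrr::map_dfr(seq_len(nrow(ext)), function(i) {
    starts <- seq(0L, ext$max_pos[i] - 1L, by = size)
    tibble::tibble(chrom = ext$chrom[i], start = starts, end = starts + size)
  })
}

# per-site allele tallies for a population: named list of vectors
site_tallies <- function(sites, pop_samples) {
  idx <- match(pop_samples, sites$samples$sample)
  if (any(is.na(idx))) abort("unknown sample in population definition.")
  called <- colSums(sites$called[idx, , drop = FALSE])
  alt <- colSums(sites$alt[idx, , drop = FALSE])
  list(called = called, alt = alt)
}

# map each site to its window row index (NA if outside all windows)
window_index <- function(site_tbl, windows) {
  out <- rep(NA_integer_, nrow(site_tbl))
  for (cc in unique(windows$chrom)) {
    w <- windows[windows$chrom == cc, ]
    sel <- which(site_tbl$chrom == cc)
    if (!length(sel)) next
    pos0 <- site_tbl$pos[sel] - 1L
    j <- findInterval(pos0, w$start)
    ok <- j >= 1 & pos0 < w$end[pmax(j, 1)]
    out[sel[ok]] <- which(windows$chrom == cc)[j[ok]]
  }
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, `diffs = n_alt * n_ref` among the population's called alleles
#' and `comps = choose(n_called, 2)`; the window estimate is
#' `sum(diffs) / sum(comps)`. Windows with zero comparisons are reported as
#' `NA` (missing), never 0. Requires all-sites input: on variant-only input
#' pi is upward-biased and a warning is raised.
#'
#' @param sites A [site_calls()] object.
#' @param pop Character vector of sample ids forming the population.
#' @param windows Window tibble from [make_windows()].
#' @return Tibble: window columns plus `diff_sum`, `comp_sum`, `n_sites_used`
#'   and `pi`.
#' @export
pi_window <- function(sites, pop, windows = make_windows(sites)) {
  stopifnot(inherits(sites, "site_calls"))
  check_allsites(sites)
  t1 <- site_tallies(sites, pop)
  diffs <- t1$alt * (t1$called - t1$alt)
  comps <- t1$called * (t1$called - 1) / 2
  aggregate_window(sites, windows, diffs, comps, "pi")
}

#' Windowed absolute divergence (D_XY)
#'
#' Per site, `diffs = n_ref1 * n_alt2 + n_alt1 * n_ref2` and
#' `comps = n_called1 * n_called2` over the two populations' called alleles;
#' the window estimate is the ratio of sums. Symmetric in population order.
#'
#' @param sites A [site_calls()] object.
#' @param pop1,pop2 Character vectors of sample ids.
#' @param windows Window tibble from [make_windows()].
#' @return Tibble with `diff_sum`, `comp_sum`, `n_sites_used`, `dxy`.
#' @export
dxy_window <- function(sites, pop1, pop2, windows = make_windows(sites)) {
  stopifnot(inherits(sites, "site_calls"))
  check_allsites(sites)
  t1 <- site_tallies(sites, pop1)
  t2 <- site_tallies(sites, pop2)
  diffs <- (t1$called - t1$alt) * t2$alt + t1$alt * (t2$called - t2$alt)
  comps <- t1$called * t2$called
  aggregate_window(sites, windows, diffs, comps, "dxy")
}

check_allsites <- function(sites) {
  called_tot <- colSums(sites$called)
  alt_tot <- colSums(sites$alt)
  invariant <- alt_tot == 0 | alt_tot == called_tot
  if (!any(invariant)) {
    warn("input looks variant-only; pi and D_XY will be upward-biased.")
  }
  invisible(NULL)
}

aggregate_window <- function(sites, windows, diffs, comps, name) {
  wi <- window_index(sites$sites, windows)
  ok <- !is.na(wi)
  out <- windows
  agg <- function(x) {
    v <- rep(0, nrow(windows))
    if (any(ok)) {
      s <- rowsum(x[ok], wi[ok])
      v[as.integer(rownames(s))] <- s[, 1]
    }
    v
  }
  out$diff_sum <- agg(diffs)
  out$comp_sum <- agg(comps)
  out$n_sites_used <- agg(as.numeric(comps > 0))
  out[[name]] <- ifelse(out$comp_sum > 0, out$diff_sum / out$comp_sum, NA_real_)
  out
}

# per-site Weir & Cockerham (1984) variance components for two populations,
# from diploid dosage matrices (rows = individuals). Returns a, b, c vectors.
wc_components <- function(dos1, dos2) {
  r <- 2
  n1 <- colSums(!is.na(dos1))
  n2 <- colSums(!is.na(dos2))
  p1 <- colMeans(dos1, na.rm = TRUE) / 2
  p2 <- colMeans(dos2, na.rm = TRUE) / 2
  h1 <- colMeans(dos1 == 1, na.rm = TRUE)
  h2 <- colMeans(dos2 == 1, na.rm = TRUE)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 1 | n2 < 1 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) of the 1984 diploid
#' estimator, computed from sample sizes, allele frequencies and observed
#' heterozygosity, are summed over each window and combined as
#' `theta = sum(a) / sum(a + b + c)` (ratio of sums). Sites with undefined
#' components are skipped; negative window values are reported as-is.
#'
#' @param g A [genotype_matrix()] of variant sites.
#' @param pop1,pop2 Character vectors of sample ids.
#' @param windows Window tibble from [make_windows()]; defaults to one 20-kb
#'   tiling of the loci.
#' @return Tibble with `a_sum`, `abc_sum`, `n_sites_used`, `fst`.
#' @export
fst_wc_window <- function(g, pop1, pop2,
                          windows = make_windows(g$loci, 20000L)) {
  stopifnot(inherits(g, "genotype_matrix"))
  i1 <- match(pop1, g$samples$sample)
  i2 <- match(pop2, g$samples$sample)
  if (any(is.na(i1)) || any(is.na(i2))) abort("unknown sample id in a population.")
  comp <- wc_components(g$dosage[i1, , drop = FALSE],
                        g$dosage[i2, , drop = FALSE])
  ok_site <- is.finite(comp$a)
  abc <- comp$a + comp$b + comp$c
  wi <- window_index(g$loci, windows)
  use <- ok_site & !is.na(wi)
  agg <- function(x) {
    v <- rep(0, nrow(windows))
    if (any(use)) {
      s <- rowsum(x[use], wi[use])
      v[as.integer(rownames(s))] <- s[, 1]
    }
    v
  }
  out <- windows
  out$a_sum <- agg(comp$a)
  out$abc_sum <- agg(abc)
  out$n_sites_used <- agg(rep(1, length(wi)))
  out$fst <- ifelse(out$n_sites_used > 0 & out$abc_sum != 0,
                    out$a_sum / out$abc_sum, NA_real_)
  out
}

#' Genome-wide Weir-Cockerham F_ST
#'
#' Ratio-of-sums theta over all usable sites (no windowing).
#'
#' @inheritParams fst_wc_window
#' @return Single numeric theta.
#' @export
fst_wc <- function(g, pop1, pop2) {
  win <- tibble::tibble(chrom = unique(g$loci$chrom), start = 0L,
                        end = max(g$loci$pos) + 1L)
  res <- fst_wc_window(g, pop1, pop2, windows = win)
  sum(res$a_sum) / sum(res$abc_sum)
}

#' Diversity and divergence per gene feature
#'
#' Aggregates the same per-site difference/comparison sums over each
#' feature's intervals (all of a gene's CDS exons are summed before the
#' ratio) instead of over windows.
#'
#' @param sites A [site_calls()] object.
#' @param features Tibble: `gene_id`, `feature`, `chrom`, `start` (0-based),
#'   `end` (exclusive). Promoters can be appended via [promoter_regions()].
#' @param pops Named list of character vectors of sample ids.
#' @param stats Which statistics to compute: any of `"pi"` (per population)
#'   and `"dxy"` (per population pair).
#' @return Tibble: `gene_id`, `feature`, `stat`, `pop`, `diff_sum`,
#'   `comp_sum`, `value` (`NA` where no comparisons).
#' @export
feature_stats <- function(sites, features, pops, stats = c("pi", "dxy")) {
  stopifnot(inherits(sites, "site_calls"))
  features <- tibble::as_tibble(features)
  if (!nrow(features)) {
    return(tibble::tibble(gene_id = character(), feature = character(),
                          stat = character(), pop = character(),
                          diff_sum = numeric(), comp_sum = numeric(),
                          value = numeric()))
  }
  tallies <- lapply(pops, function(p) site_tallies(sites, p))
  per_site <- list()
  if ("pi" %in% stats) {
    for (nm in names(pops)) {
      t1 <- tallies[[nm]]
      per_site[[paste0("pi.", nm)]] <- list(
        diffs = t1$alt * (t1$called - t1$alt),
        comps = t1$called * (t1$called - 1) / 2
      )
    }
  }
  if ("dxy" %in% stats && length(pops) >= 2) {
    prs <- utils::combn(names(pops), 2, simplify = FALSE)
    for (pr in prs) {
      t1 <- tallies[[pr[1]]]; t2 <- tallies[[pr[2]]]
      per_site[[paste0("dxy.", pr[1], ":", pr[2])]] <- list(
        diffs = (t1$called - t1$alt) * t2$alt + t1$alt * (t2$called - t2$alt),
        comps = t1$called * t2$called
      )
    }
  }
  purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    sel <- sites$sites$chrom == f$chrom &
      (sites$sites$pos - 1L) >= f$start & (sites$sites$pos - 1L) < f$end
    purrr::map_dfr(names(per_site), function(nm) {
      d <- sum(per_site[[nm]]$diffs[sel])
      co <- sum(per_site[[nm]]$comps[sel])
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      tibble::tibble(gene_id = f$gene_id, feature = f$feature,
                     stat = parts[1], pop = parts[2],
                     diff_sum = d, comp_sum = co,
                     value = if (co > 0) d / co else NA_real_)
    })
  }) |>
    dplyr::group_by(.data$gene_id, .data$feature, .data$stat, .data$pop) |>
    dplyr::summarise(diff_sum = sum(.data$diff_sum),
                     comp_sum = sum(.data$comp_sum), .groups = "drop") |>
    dplyr::mutate(value = ifelse(.data$comp_sum > 0,
                                 .data$diff_sum / .data$comp_sum, NA_real_))
}

#' Compare a statistic between gene sets
#'
#' Assigns genes to the supplied disjoint sets (e.g. constitutively divergent
#' vs non-divergent expression genes), then for every feature x statistic
#' combination reports group means with standard errors and one-way ANOVA
#' with Tukey HSD adjusted pairwise p-values.
#'
#' @param stats Tibble of per-gene values with columns `gene_id`, `feature`,
#'   `stat`, `pop`, `value` (from [feature_stats()]) or any tibble with
#'   `gene_id` and `value` (then `feature`/`stat` default to one level).
#' @param sets Named list of disjoint gene-id vectors; genes in none are
#'   dropped unless `background = TRUE` adds them as a "background" group.
#' @param background Include unassigned genes as a background group.
#' @return List of class `gene_set_comparison` with `summary` and `tests`
#'   tibbles.
#' @export
compare_gene_sets <- function(stats, sets, background = FALSE) {
  stats <- tibble::as_tibble(stats)
  if (!"feature" %in% names(stats)) stats$feature <- "all"
  if (!"stat" %in% names(stats)) stats$stat <- "value"
  if (!"pop" %in% names(stats)) stats$pop <- "all"
  if (anyDuplicated(unlist(sets))) abort("gene sets must be disjoint.")
  grp <- rep(NA_character_, nrow(stats))
  for (nm in names(sets)) grp[stats$gene_id %in% sets[[nm]]] <- nm
  if (background) grp[is.na(grp)] <- "background"
  stats$set <- grp
  df <- stats[!is.na(stats$set) & !is.na(stats$value), , drop = FALSE]
  # drop sets with < 2 genes within each stratum
  summ <- df |>
    dplyr::group_by(.data$feature, .data$stat, .data$pop, .data$set) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  tests <- df |>
    dplyr::group_by(.data$feature, .data$stat, .data$pop) |>
    dplyr::group_modify(function(d, key) {
      d <- d |> dplyr::group_by(.data$set) |>
        dplyr::filter(dplyr::n() >= 2) |> dplyr::ungroup()
      if (dplyr::n_distinct(d$set) < 2 || sd(d$value) == 0) {
        return(tibble::tibble(contrast = NA_character_, diff = NA_real_,
                              adj.p.value = NA_real_))
      }
      fit <- aov(value ~ set, data = dplyr::mutate(d, set = factor(.data$set)))
      th <- TukeyHSD(fit)$set
      tibble::tibble(contrast = rownames(th), diff = th[, "diff"],
                     adj.p.value = th[, "p adj"])
    }) |>
    dplyr::ungroup()
  structure(list(summary = summ, tests = tests),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat("<gene_set_comparison>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' @method tidy gene_set_comparison
#' @export
tidy.gene_set_comparison <- function(x, ...) x$tests

#' @method glance gene_set_comparison
#' @export
glance.gene_set_comparison <- function(x, ...) {
  x$summary |>
    dplyr::group_by(.data$feature, .data$stat, .data$pop) |>
    dplyr::summarise(n_sets = dplyr::n(), .groups = "drop")
}

#' Mean-and-SE bar plot of a gene-set comparison
#' @param object A [compare_gene_sets()] result.
#' @param ... Unused.
#' @return A ggplot faceted by feature and statistic.
#' @method autoplot gene_set_comparison
#' @export
autoplot.gene_set_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$set, .data$mean, fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::facet_grid(ggplot2::vars(.data$stat, .data$pop),
                        ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SE") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
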