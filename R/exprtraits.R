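#' Remove lowly expressed genes
#'
#' Drops genes whose mean raw count across *all* samples is below `min_mean`
#' (strictly; a gene with mean exactly `min_mean` is retained).
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_mean Minimum mean count.
#' @return Filtered count matrix; retained/removed totals in
#'   `attr(, "filter_report")`.
#' @export
filter_low_expression <- function(counts, min_mean = 1.0) {
  counts <- as.matrix(counts)
  if (!nrow(counts) || !ncol(counts)) abort("empty count matrix.")
  if (any(counts < 0)) abort("counts must be nonnegative.")
  keep <- rowMeans(counts) >= min_mean
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_report") <- tibble::tibble(
    retained = sum(keep), removed = sum(!keep)
  )
  out
}

#' Median-of-ratios library size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over genes
#' positive in every sample, of that sample's count divided by the gene's
#' geometric mean; factors are then rescaled to geometric mean 1. If no gene
#' is positive in all samples the total-count ratio is used instead (with a
#' warning).
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    warn("no gene is positive in all samples; falling back to total-count ratios.")
    f <- colSums(counts)
  } else {
    logc <- log(counts[pos, , drop = FALSE])
    loggeo <- rowMeans(logc)
    f <- apply(exp(sweep(logc, 1, loggeo, "-")), 2, median)
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Variance-flattening transform of normalized counts
#'
#' A started-log transform on size-normalized counts:
#' `log2(count / factor + 1)`. It is monotone in the count, equal for equal
#' normalized counts, and flattens the count-variance trend sufficiently for
#' the trait pipeline; it is deliberately isolated in one function so a
#' different variance-stabilizing transform can be swapped in.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample positive size factors (default
#'   [size_factors()]).
#' @return Matrix of transformed values, same shape as `counts`.
#' @export
vst_normalize <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (any(factors <= 0)) abort("size factors must be positive.")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Collapse replicates to accession x site means
#'
#' @param norm Genes x samples matrix of normalized expression.
#' @param meta Sample metadata tibble with `sample`, `accession`, `site`,
#'   `replicate` (see [simulate_expression_counts()]).
#' @return List of class `site_means`: one accessions x genes matrix per
#'   site (`NA` rows where an accession was not measured at that site), plus
#'   `accessions` and `genes`.
#' @export
accession_site_means <- function(norm, meta) {
  norm <- as.matrix(norm)
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("sample", "accession", "site") %in% names(meta)))
  if (!all(meta$sample %in% colnames(norm))) {
    abort("every metadata sample must appear in the expression matrix.")
  }
  accs <- unique(meta$accession)
  sites <- sort(unique(meta$site))
  genes <- rownames(norm) %||% sprintf("gene%04d", seq_len(nrow(norm)))
  out <- lapply(sites, function(s) {
    mat <- matrix(NA_real_, length(accs), nrow(norm),
                  dimnames = list(accs, genes))
    ms <- meta[meta$site == s, ]
    for (a in unique(ms$accession)) {
      cols <- ms$sample[ms$accession == a]
      mat[a, ] <- rowMeans(norm[, cols, drop = FALSE])
    }
    mat
  })
  names(out) <- sites
  structure(list(means = out, accessions = accs, genes = genes,
                 sites = sites), class = "site_means")
}

#' Constitutive and plastic expression traits
#'
#' The reaction-norm decomposition of two-site expression: the constitutive
#' trait of an accession is the unweighted mean of its two site means (the
#' main-effect, intercept-like component) and the plastic trait is the
#' coastal - inland difference (the interaction, slope-like component). Both
#' are then mean-centered per gene across accessions. Accessions measured at
#' only one site are excluded (with a message).
#'
#' @param means A [accession_site_means()] result with sites `"inland"` and
#'   `"coastal"`.
#' @param center Mean-center each gene across accessions (default `TRUE`).
#' @return List of class `trait_set` with matrices `constitutive` and
#'   `plastic` (accessions x genes), `accessions`, `genes`, `centered`.
#' @export
constitutive_plastic <- function(means, center = TRUE) {
  stopifnot(inherits(means, "site_means"))
  if (!all(c("inland", "coastal") %in% means$sites)) {
    abort("both an 'inland' and a 'coastal' site are required.")
  }
  inl <- means$means[["inland"]]
  coa <- means$means[["coastal"]]
  both <- stats::complete.cases(inl) & stats::complete.cases(coa)
  if (any(!both)) {
    inform(sprintf("%d accession(s) missing a site; excluded from traits.",
                   sum(!both)))
  }
  inl <- inl[both, , drop = FALSE]
  coa <- coa[both, , drop = FALSE]
  constitutive <- (inl + coa) / 2
  plastic <- coa - inl
  if (center) {
    constitutive <- scale(constitutive, center = TRUE, scale = FALSE)
    plastic <- scale(plastic, center = TRUE, scale = FALSE)
    attr(constitutive, "scaled:center") <- NULL
    attr(plastic, "scaled:center") <- NULL
  }
  structure(
    list(constitutive = constitutive, plastic = plastic,
         accessions = rownames(inl), genes = means$genes, centered = center),
    class = "trait_set"
  )
}

#' @export
print.trait_set <- function(x, ...) {
  cat(sprintf("<trait_set> %d accessions x %d genes (centered: %s)\n",
              length(x$accessions), length(x$genes), x$centered))
  invisible(x)
}

#' One-call trait pipeline from raw counts
#'
#' Convenience chain: [filter_low_expression()] -> [size_factors()] ->
#' [vst_normalize()] -> [accession_site_means()] -> [constitutive_plastic()].
#'
#' @param counts Genes x samples raw counts.
#' @param meta Sample metadata (see [accession_site_means()]).
#' @param min_mean Low-expression threshold.
#' @return A `trait_set`.
#' @export
counts_to_traits <- function(counts, meta, min_mean = 1.0) {
  counts <- filter_low_expression(counts, min_mean = min_mean)
  norm <- vst_normalize(counts)
  constitutive_plastic(accession_site_means(norm, meta))
}
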