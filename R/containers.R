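#' Genotype matrix container
#'
#' Bundles a biallelic dosage matrix (samples x loci, values 0/1/2 or `NA` for
#' missing) with locus coordinates and per-sample metadata. This is the object
#' consumed by [standardized_kinship()], [fst_wc_window()] and the site
#' filters.
#'
#' @param dosage Numeric matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param loci Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param samples Tibble with column `sample` and optionally `cluster`.
#' @param provenance Character tag recording how the panel was derived (for
#'   example `"region-purged"` after [subset_by_regions()]); carried through
#'   kinship construction so constrained-mode scans can check it.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, samples, provenance = "raw") {
  dosage <- as.matrix(dosage)
  loci <- tibble::as_tibble(loci)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(dosage) == nrow(samples), ncol(dosage) == nrow(loci))
  if (!all(c("chrom", "pos") %in% names(loci))) {
    abort("`loci` needs `chrom` and `pos` columns.")
  }
  if (!"sample" %in% names(samples)) abort("`samples` needs a `sample` column.")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("dosages must be 0, 1, 2 or NA.")
  }
  rownames(dosage) <- samples$sample
  structure(
    list(dosage = dosage, loci = loci, samples = samples,
         provenance = provenance),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci (provenance: %s)\n",
              nrow(x$dosage), ncol(x$dosage), x$provenance))
  if ("cluster" %in% names(x$samples)) {
    tab <- table(x$samples$cluster)
    cat("  clusters:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosage)

#' All-sites call matrix
#'
#' Per-site allele-call bookkeeping for pixy-style diversity statistics:
#' for every site (variant *and* invariant) and every sample, the number of
#' callable alleles (`0` when the genotype is missing, `2` for a called
#' diploid genotype) and the alternate-allele dosage among called alleles.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based).
#' @param called Integer matrix samples x sites of callable allele counts.
#' @param alt Integer matrix samples x sites of alt dosages (`alt <= called`).
#' @param samples Tibble with column `sample`, optionally `pop`.
#'
#' @return An object of class `site_calls`.
#' @export
site_calls <- function(sites, called, alt, samples) {
  sites <- tibble::as_tibble(sites)
  called <- as.matrix(called)
  alt <- as.matrix(alt)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(called) == nrow(samples), ncol(called) == nrow(sites),
            identical(dim(called), dim(alt)))
  if (any(alt > called)) abort("alt dosage cannot exceed called alleles.")
  rownames(called) <- rownames(alt) <- samples$sample
  structure(
    list(sites = sites, called = called, alt = alt, samples = samples),
    class = "site_calls"
  )
}

#' @export
print.site_calls <- function(x, ...) {
  n_var <- sum(apply(x$alt, 2, function(a) {
    s <- sum(a); s > 0 && s < sum(x$called[, 1])
  }))
  cat(sprintf("<site_calls> %d samples x %d sites\n",
              nrow(x$called), nrow(x$sites)))
  invisible(x)
}

#' Genomic region set
#'
#' A validated tibble of intervals in BED convention: 0-based, half-open
#' `[start, end)`. Overlapping or book-ended intervals with the same label are
#' merged.
#'
#' @param chrom,start,end Vectors defining the intervals, or a data frame with
#'   those columns passed as `chrom`.
#' @param label Optional label (recycled).
#' @return A tibble of class `region_set` with columns `chrom`, `start`,
#'   `end`, `label`, sorted by position.
#' @export
region_set <- function(chrom, start = NULL, end = NULL, label = "region") {
  if (is.data.frame(chrom)) {
    df <- chrom
    if (!"label" %in% names(df)) df$label <- label
  } else {
    df <- tibble::tibble(chrom = chrom, start = start, end = end, label = label)
  }
  df <- tibble::as_tibble(df)[, c("chrom", "start", "end", "label")]
  if (!nrow(df)) {
    class(df) <- c("region_set", class(df))
    return(df)
  }
  if (any(df$start >= df$end)) abort("regions need start < end.")
  if (any(df$start < 0)) abort("regions are 0-based; start must be >= 0.")
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$end)
  # merge overlapping/adjacent intervals within chrom+label
  df <- df |>
    dplyr::group_by(.data$chrom, .data$label) |>
    dplyr::mutate(.grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                         default = -1L))) |>
    dplyr::group_by(.data$chrom, .data$label, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "label") |>
    dplyr::arrange(.data$chrom, .data$start)
  class(df) <- c("region_set", class(df))
  df
}

# TRUE for each locus position (1-based) falling inside some interval
in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  pos0 <- pos - 1L
  for (cc in unique(regions$chrom)) {
    r <- regions[regions$chrom == cc, ]
    sel <- which(chrom == cc)
    if (!length(sel)) next
    for (k in seq_len(nrow(r))) {
      hit[sel] <- hit[sel] | (pos0[sel] >= r$start[k] & pos0[sel] < r$end[k])
    }
  }
  hit
}
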