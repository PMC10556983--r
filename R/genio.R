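#' Read a VCF into a genotype or all-sites call matrix
#'
#' Parsing is delegated to \pkg{vcfR}. Diploid GT fields are converted to
#' alternate-allele dosages; missing genotypes stay missing. Multiallelic
#' records are skipped and counted (reported via a message and
#' `attr(, "n_multiallelic_skipped")`).
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param include_invariant If `TRUE`, return a [site_calls()] object keeping
#'   invariant sites (records with missing/`.` ALT) for all-sites diversity
#'   statistics; otherwise return a [genotype_matrix()] of variant sites only.
#' @return A [genotype_matrix()] or [site_calls()].
#' @export
read_vcf <- function(path, include_invariant = FALSE) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- !is.na(fix$ALT) & grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    inform(sprintf("skipped %d multiallelic record(s).", n_multi))
  }
  invariant <- is.na(fix$ALT) | fix$ALT == "." | fix$ALT == ""
  keep <- !multi & (include_invariant | !invariant)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  invariant <- invariant[keep]
  # dosage: number of non-ref alleles; NA when any allele is missing
  dos <- apply(gt, 2, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == "." | is.na(x))) NA_real_
      else sum(x != "0")
    }, numeric(1))
  })
  dos <- matrix(dos, nrow = nrow(fix),
                dimnames = list(NULL, colnames(gt)))
  loci <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = ifelse(invariant, ".", fix$ALT)
  )
  samples <- tibble::tibble(sample = colnames(gt))
  if (include_invariant) {
    called <- t(ifelse(is.na(dos), 0L, 2L))
    alt <- t(ifelse(is.na(dos), 0L, dos))
    out <- site_calls(loci[, c("chrom", "pos")], called, alt, samples)
  } else {
    out <- genotype_matrix(t(dos), loci, samples, provenance = "vcf")
  }
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Write a genotype or all-sites matrix as VCF 4.2
#'
#' Dosages are written as unphased diploid GT calls (`0/0`, `0/1`, `1/1`,
#' missing `./.`). Invariant sites of a [site_calls()] object get ALT `.`.
#'
#' @param x A [genotype_matrix()] or [site_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "genotype_matrix")) {
    loci <- x$loci
    dos <- t(x$dosage)   # loci x samples
    samples <- x$samples$sample
  } else if (inherits(x, "site_calls")) {
    alt_mat <- t(x$alt)
    called <- t(x$called)
    dos <- ifelse(called == 0L, NA, alt_mat)
    variant <- vapply(seq_len(nrow(dos)), function(i) {
      d <- dos[i, ]; any(d > 0, na.rm = TRUE)
    }, logical(1))
    loci <- tibble::tibble(chrom = x$sites$chrom, pos = x$sites$pos,
                           ref = "A", alt = ifelse(variant, "T", "."))
    samples <- x$samples$sample
  } else {
    abort("`x` must be a genotype_matrix or site_calls object.")
  }
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=qpcscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chrom[i], loci$pos[i], ".",
            loci$ref[i] %||% "A", loci$alt[i] %||% "T",
            ".", "PASS", ".", "GT", gt_code(dos[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Site-level genotype filters
#'
#' Retains sites passing all thresholds, mirroring a two-stage filtering
#' scheme for selfing resequencing panels: a variant-calling stage
#' (per-site heterozygosity below the 85th-percentile cutoff of 3.6%, under
#' 20% missing data) and a neutral-panel stage (under 10% missing, minor
#' allele count at least 3). Heterozygosity is the percentage of heterozygous
#' calls among called genotypes; MAC is computed on called alleles. Rules are
#' applied in the order heterozygosity, missingness, MAC; the first failing
#' rule gets the attribution in the report.
#'
#' @param g A [genotype_matrix()].
#' @param max_het_pct Drop sites with >= this percent heterozygous calls.
#' @param max_missing Drop sites with >= this fraction of missing genotypes.
#' @param min_mac Drop sites with minor allele count below this.
#' @param biallelic_only Kept for interface completeness; the container is
#'   biallelic by construction.
#' @param preset Optional shorthand: `"variant-calling"`
#'   (het < 3.6%, missing < 20%) or `"neutral-panel"`
#'   (missing < 10%, MAC >= 3). Explicit arguments override the preset.
#' @return Filtered [genotype_matrix()]; the per-rule drop counts are in
#'   `attr(, "filter_report")`.
#' @export
filter_sites <- function(g, max_het_pct = 3.6, max_missing = 0.20,
                         min_mac = 3, biallelic_only = TRUE, preset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("variant-calling", "neutral-panel"))
    defs <- switch(preset,
      "variant-calling" = list(max_het_pct = 3.6, max_missing = 0.20,
                               min_mac = 0),
      "neutral-panel" = list(max_het_pct = 100, max_missing = 0.10,
                             min_mac = 3)
    )
    if (missing(max_het_pct)) max_het_pct <- defs$max_het_pct
    if (missing(max_missing)) max_missing <- defs$max_missing
    if (missing(min_mac)) min_mac <- defs$min_mac
  }
  if (max_het_pct < 0 || max_het_pct > 100) abort("`max_het_pct` must be in [0, 100].")
  assert_fraction(max_missing, "max_missing")
  dos <- g$dosage
  n <- nrow(dos)
  n_called <- colSums(!is.na(dos))
  het_pct <- 100 * colSums(dos == 1, na.rm = TRUE) / pmax(n_called, 1L)
  miss_frac <- 1 - n_called / n
  alt_count <- colSums(dos, na.rm = TRUE)
  mac <- pmin(alt_count, 2 * n_called - alt_count)
  fail_het <- het_pct >= max_het_pct
  fail_miss <- miss_frac >= max_missing
  fail_mac <- mac < min_mac
  drop_rule <- rep(NA_character_, ncol(dos))
  drop_rule[fail_mac] <- "mac"
  drop_rule[fail_miss] <- "missing"
  drop_rule[fail_het] <- "heterozygosity"   # first rule wins
  keep <- is.na(drop_rule)
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         g$loci[keep, , drop = FALSE],
                         g$samples, provenance = g$provenance)
  report <- tibble::tibble(
    rule = c("heterozygosity", "missing", "mac"),
    dropped = c(sum(drop_rule == "heterozygosity", na.rm = TRUE),
                sum(drop_rule == "missing", na.rm = TRUE),
                sum(drop_rule == "mac", na.rm = TRUE))
  )
  attr(out, "filter_report") <- report
  out
}

#' Keep or exclude sites by genomic regions
#'
#' A site at 1-based position `pos` is inside an interval iff
#' `pos - 1` falls in the 0-based half-open `[start, end)`.
#'
#' @param g A [genotype_matrix()].
#' @param regions A [region_set()].
#' @param mode `"keep"` retains sites inside the regions, `"exclude"` purges
#'   them (e.g. purging SNPs in nonrecombining regions before building the
#'   constrained-mode kinship).
#' @return Filtered [genotype_matrix()]; in exclude mode the provenance tag
#'   becomes `"region-purged"`.
#' @export
subset_by_regions <- function(g, regions, mode = c("keep", "exclude")) {
  stopifnot(inherits(g, "genotype_matrix"))
  mode <- match.arg(mode)
  unknown <- setdiff(unique(g$loci$chrom), unique(regions$chrom))
  if (length(unknown) && nrow(regions)) {
    warn(sprintf(
      "chromosome(s) %s absent from the region set; their sites are %s.",
      paste(unknown, collapse = ", "),
      if (mode == "exclude") "retained" else "dropped"))
  }
  inside <- in_regions(g$loci$chrom, g$loci$pos, regions)
  keep <- if (mode == "keep") inside else !inside
  prov <- if (mode == "exclude" && nrow(regions)) "region-purged" else g$provenance
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$loci[keep, , drop = FALSE],
                  g$samples, provenance = prov)
}

#' Proximal promoter regions from gene models
#'
#' The proximal promoter is the 2 kb immediately upstream of the
#' transcription start site. For a + strand gene with 1-based start `s` the
#' promoter is `[s - 1 - length, s - 1)` in 0-based half-open coordinates,
#' truncated at the chromosome start; for a - strand gene with 1-based end
#' `e` it is `[e, e + length)`.
#'
#' @param features Tibble of gene models with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `gene_id`.
#' @param length Promoter length in bp.
#' @return A [region_set()] labelled by `gene_id`.
#' @export
promoter_regions <- function(features, length = 2000) {
  features <- tibble::as_tibble(features)
  need <- c("chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(features))) {
    abort(paste("`features` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(!features$strand %in% c("+", "-"))) {
    abort("every gene needs a known strand ('+' or '-').")
  }
  plus <- features$strand == "+"
  tss0 <- ifelse(plus, features$start - 1L, features$end)
  start <- ifelse(plus, pmax(0, tss0 - length), tss0)
  end <- ifelse(plus, tss0, tss0 + length)
  keep <- start < end
  region_set(tibble::tibble(
    chrom = features$chrom[keep],
    start = start[keep], end = end[keep],
    label = features$gene_id[keep]
  ))
}

#' Read gene models from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import()` returning the tibble layout that
#' [promoter_regions()] and [feature_stats()] expect.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (GFF3 `type` column).
#' @return Tibble: `chrom`, `start`, `end` (1-based), `strand`, `type`,
#'   `gene_id`.
#' @export
read_gff3 <- function(path, types = c("gene", "CDS", "five_prime_UTR",
                                      "three_prime_UTR", "intron")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gff3() needs the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% types, , drop = FALSE]
  id <- df$ID
  if (!is.null(df$Parent)) {
    parent <- vapply(df$Parent, function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
    id <- ifelse(df$type == "gene", as.character(id), parent)
  }
  tibble::tibble(
    chrom = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    type = as.character(df$type),
    gene_id = sub("\\.\\d+$", "", as.character(id))
  )
}

#' Read a BED3(+label) file as a region set
#'
#' @param path Path to a BED file (0-based half-open intervals; optional
#'   fourth column used as the label).
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) abort("BED needs at least 3 columns.")
  names(df)[1:3] <- c("chrom", "start", "end")
  label <- if (ncol(df) >= 4) as.character(df[[4]]) else "region"
  region_set(tibble::tibble(chrom = as.character(df$chrom),
                            start = df$start, end = df$end, label = label))
}

#' Write a region set as BED
#' @param regions A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(as.data.frame(regions)[, c("chrom", "start", "end", "label")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
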