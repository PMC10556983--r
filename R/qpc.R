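# Core selection test: trait projections on conditional-kinship PCs.

# internal: project a trait matrix (accessions x traits) onto all PCs.
# returns list(C = scaled projections (PCs x traits), lam)
qpc_project <- function(Z, eigen) {
  # explicit pre-centering: T annihilates constants analytically, and doing
  # it here keeps constant traits at exactly zero projection in floating point
  Z <- sweep(Z, 2, colMeans(Z), "-")
  Zc <- eigen$Tmat %*% Z
  C <- crossprod(eigen$vectors, Zc)
  lam <- eigen$values
  scale <- ifelse(eigen$usable, 1 / sqrt(pmax(lam, .Machine$double.eps)), 0)
  C <- C * scale
  C[!eigen$usable, ] <- 0
  C
}

#' Q_PC test of a single trait
#'
#' Projects the mean-centered trait onto the eigenvectors of the conditional
#' kinship matrix (`c_m = u_m' T z / sqrt(lambda_m)`), estimates the additive
#' genetic variance as the mean of `c_m^2` over the neutral PC set, and tests
#' each test PC with `F = c_m^2 / V_A_hat` against an F(1, n_neutral)
#' distribution (upper tail: the alternative is excessive divergence along
#' major axes of structure).
#'
#' @param trait Numeric vector of per-accession values, ordered (or named)
#'   as the eigen object's samples.
#' @param eigen A [conditional_eigen()] result with [pc_sets()] applied.
#' @return Tibble with one row per test PC: `pc`, `lambda`, `projection`,
#'   `va_hat`, `statistic`, `p.value`.
#' @export
qpc_test <- function(trait, eigen) {
  stopifnot(inherits(eigen, "kinship_eigen"))
  if (is.null(eigen$test_pcs)) abort("run pc_sets() on the eigen object first.")
  if (!is.null(names(trait))) trait <- trait[eigen$samples]
  if (length(trait) != length(eigen$samples)) {
    abort("trait length must match the kinship sample set.")
  }
  C <- qpc_project(matrix(trait, ncol = 1), eigen)[, 1]
  neutral <- eigen$neutral_pcs
  va_hat <- mean(C[neutral]^2)
  k <- length(neutral)
  purrr::map_dfr(eigen$test_pcs, function(m) {
    cm <- C[m]
    if (va_hat == 0) {
      stat <- if (cm == 0) 0 else Inf
      p <- if (cm == 0) 1 else 0
    } else {
      stat <- cm^2 / va_hat
      p <- pf(stat, 1, k, lower.tail = FALSE)
    }
    tibble::tibble(pc = m, lambda = eigen$values[m], projection = cm,
                   va_hat = va_hat, statistic = stat, p.value = p)
  })
}

#' Q_PC scan over a trait set
#'
#' Runs the Q_PC test for every gene of a [constitutive_plastic()] trait set
#' (or a plain accession x gene matrix) and computes Storey q-values per
#' tested PC across genes. In constrained mode the scan is restricted to
#' genes inside the supplied highly-recombined region set, and the kinship
#' provenance is checked: a constrained scan expects an eigen object built
#' from a region-purged SNP panel.
#'
#' @param traits A `trait_set` or accession x gene matrix.
#' @param eigen A [conditional_eigen()] result with [pc_sets()] applied.
#' @param which `"constitutive"` or `"plastic"` (ignored for plain matrices).
#' @param mode `"relaxed"` (all genes) or `"constrained"` (genes in regions).
#' @param regions [region_set()] of highly recombined regions (constrained
#'   mode).
#' @param gene_coords Tibble `gene_id`, `chrom`, `pos` (1-based
#'   representative position; constrained mode).
#' @param fdr FDR threshold recorded for outlier flags.
#' @param pool_pcs If `TRUE` q-values are computed pooling all tested PCs
#'   instead of within each PC.
#' @return An object of class `qpc_scan`: tibble `gene`, `pc`, `lambda`,
#'   `projection`, `va_hat`, `statistic`, `p.value`, `q.value`, `outlier`,
#'   with the mode, trait kind and thresholds as attributes.
#' @export
qpc_scan <- function(traits, eigen, which = c("constitutive", "plastic"),
                     mode = c("relaxed", "constrained"),
                     regions = NULL, gene_coords = NULL, fdr = 0.1,
                     pool_pcs = FALSE) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  stopifnot(inherits(eigen, "kinship_eigen"))
  if (is.null(eigen$test_pcs)) abort("run pc_sets() on the eigen object first.")
  Z <- if (inherits(traits, "trait_set")) traits[[which]] else as.matrix(traits)
  if (!is.null(rownames(Z))) {
    if (!all(eigen$samples %in% rownames(Z))) {
      abort("trait accessions do not cover the kinship sample set.")
    }
    Z <- Z[eigen$samples, , drop = FALSE]
  }
  genes <- colnames(Z) %||% sprintf("gene%04d", seq_len(ncol(Z)))
  if (mode == "constrained") {
    if (is.null(regions) || is.null(gene_coords)) {
      abort("constrained mode needs `regions` and `gene_coords`.")
    }
    if (!identical(eigen$provenance, "region-purged")) {
      warn("constrained scan with a kinship not built from region-purged SNPs.")
    }
    gc <- tibble::as_tibble(gene_coords)
    inside <- gc$gene_id[in_regions(gc$chrom, gc$pos, regions)]
    keep <- genes %in% inside
    Z <- Z[, keep, drop = FALSE]
    genes <- genes[keep]
  }
  C <- qpc_project(Z, eigen)
  neutral <- eigen$neutral_pcs
  k <- length(neutral)
  va_hat <- colMeans(C[neutral, , drop = FALSE]^2)
  res <- purrr::map_dfr(eigen$test_pcs, function(m) {
    cm <- C[m, ]
    stat <- ifelse(va_hat > 0, cm^2 / va_hat,
                   ifelse(cm == 0, 0, Inf))
    p <- ifelse(is.finite(stat), pf(stat, 1, k, lower.tail = FALSE), 0)
    p[va_hat == 0 & cm == 0] <- 1
    tibble::tibble(gene = genes, pc = m, lambda = eigen$values[m],
                   projection = cm, va_hat = va_hat,
                   statistic = stat, p.value = p)
  })
  if (nrow(res)) {
    if (pool_pcs) {
      res$q.value <- qvalues(res$p.value)
    } else {
      res <- res |>
        dplyr::group_by(.data$pc) |>
        dplyr::mutate(q.value = qvalues(.data$p.value)) |>
        dplyr::ungroup()
    }
    res$outlier <- res$q.value < fdr
  } else {
    res$q.value <- numeric(0)
    res$outlier <- logical(0)
  }
  structure(res,
            class = c("qpc_scan", class(res)),
            mode = mode, which = which, fdr = fdr,
            n_neutral = k, test_pcs = eigen$test_pcs)
}

#' Storey q-values
#'
#' The proportion of true nulls `pi0` is estimated on the lambda grid
#' 0.05-0.95 (step 0.05) by cubic-spline smoothing of
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` evaluated at the largest
#' lambda; when the spline estimate is above 1 or unstable the procedure
#' falls back to `pi0 = 1`, i.e. plain Benjamini-Hochberg. Then
#' `q_i = pi0 * min_{p_j >= p_i} (N p_j / rank_j)`, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param pi0 Optional override of the estimated null proportion.
#' @return Vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(p < 0 | p > 1 | is.na(p))) abort("p-values must lie in [0, 1].")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  pmin(pi0 * p.adjust(p, method = "BH"), 1)
}

# Storey pi0: spline-smoothed lambda grid, evaluated at max lambda
estimate_pi0 <- function(p, lambdas = seq(0.05, 0.95, by = 0.05)) {
  n <- length(p)
  if (n < 20) return(1)
  pi0_l <- vapply(lambdas, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(smooth.spline(lambdas, pi0_l, df = 3),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  pi0 <- predict(fit, x = max(lambdas))$y
  if (!is.finite(pi0) || pi0 > 1 || pi0 <= 0) return(1)
  pi0
}

#' Neutral-envelope slope for a PC
#'
#' The 95% (by default) neutral envelope for a trait against the unit-norm
#' coordinate of eigenvector `pc` is the pair of lines through the origin
#' with slopes `+/- b`, `b = sqrt(F^{-1}_{1-alpha}(1, n_neutral) * va_hat *
#' lambda_pc)`. A gene falls outside the envelope exactly when its Q_PC
#' F-test at that PC is significant at `alpha` (same quantile by
#' construction).
#'
#' @param eigen A [conditional_eigen()] result with [pc_sets()] applied.
#' @param va_hat Additive variance estimate of the trait.
#' @param pc PC index.
#' @param alpha Tail probability.
#' @return Tibble `pc`, `alpha`, `slope`.
#' @export
neutral_envelope <- function(eigen, va_hat, pc, alpha = 0.05) {
  stopifnot(inherits(eigen, "kinship_eigen"))
  if (is.null(eigen$neutral_pcs)) abort("run pc_sets() first.")
  if (any(va_hat < 0)) abort("`va_hat` must be >= 0.")
  k <- length(eigen$neutral_pcs)
  b <- sqrt(qf(1 - alpha, 1, k) * va_hat * eigen$values[pc])
  tibble::tibble(pc = pc, alpha = alpha, slope = b)
}

#' Outlier gene sets from a scan
#'
#' @param scan A [qpc_scan()] result.
#' @param q_threshold q-value cutoff.
#' @return List of class `qpc_outliers`: `per_pc` (named list of gene
#'   vectors), `union`, and `multi_pc` (genes significant on >= 2 PCs).
#' @export
call_outliers <- function(scan, q_threshold = 0.1) {
  stopifnot(inherits(scan, "qpc_scan"))
  sig <- scan[scan$q.value < q_threshold, , drop = FALSE]
  per_pc <- split(sig$gene, sig$pc)
  counts <- table(sig$gene)
  structure(
    list(per_pc = per_pc,
         union = sort(unique(sig$gene)),
         multi_pc = sort(names(counts)[counts >= 2]),
         q_threshold = q_threshold),
    class = "qpc_outliers"
  )
}

#' @export
print.qpc_outliers <- function(x, ...) {
  cat(sprintf("<qpc_outliers> q < %g: %d genes (%d on multiple PCs)\n",
              x$q_threshold, length(x$union), length(x$multi_pc)))
  for (pc in names(x$per_pc)) {
    cat(sprintf("  PC%s: %d genes\n", pc, length(x$per_pc[[pc]])))
  }
  invisible(x)
}

#' @method tidy qpc_scan
#' @export
tidy.qpc_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance qpc_scan
#' @export
glance.qpc_scan <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    which = attr(x, "which"),
    n_genes = dplyr::n_distinct(x$gene),
    n_test_pcs = length(attr(x, "test_pcs")),
    n_neutral = attr(x, "n_neutral"),
    fdr = attr(x, "fdr"),
    n_outliers = length(unique(x$gene[x$outlier]))
  )
}

#' Envelope plot of a Q_PC scan at one PC
#'
#' Plots each gene's PC projection (on the `sqrt(lambda)` scale used by the
#' neutral model) against its estimated additive SD, with the neutral
#' envelope shown as dotted lines: genes outside diverge more along this axis
#' of population structure than drift predicts.
#'
#' @param object A [qpc_scan()] result.
#' @param pc PC to display (default: first tested PC).
#' @param alpha Envelope tail probability.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qpc_scan
#' @export
autoplot.qpc_scan <- function(object, pc = NULL, alpha = 0.05, ...) {
  pc <- pc %||% attr(object, "test_pcs")[1]
  df <- object[object$pc == pc, , drop = FALSE]
  k <- attr(object, "n_neutral")
  b <- sqrt(qf(1 - alpha, 1, k))
  df$sd_hat <- sqrt(df$va_hat * df$lambda)
  df$coord <- df$projection * sqrt(df$lambda)
  ggplot2::ggplot(df, ggplot2::aes(.data$sd_hat, .data$coord,
                                   color = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = c(b, -b), intercept = 0, linetype = 3) +
    ggplot2::labs(
      x = expression(sqrt(hat(V)[A] ~ lambda[m])),
      y = sprintf("trait projection on PC%d", pc),
      color = sprintf("q < %g", attr(object, "fdr"))
    ) +
    ggplot2::theme_minimal()
}
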