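#' Standardized kinship matrix from a neutral SNP panel
#'
#' Per locus, dosages are centered and scaled by the binomial SD:
#' `s_il = (g_il - 2 p_l) / sqrt(2 p_l (1 - p_l))` with `p_l` the alternate
#' allele frequency estimated as mean dosage / 2 over called samples. Missing
#' dosages contribute 0 after centering (mean imputation). The kinship matrix
#' is `K = S S' / L`.
#'
#' In a highly selfing population the diagonal of `K` is inflated relative to
#' an outbred population ((1 + F)-style inflation); downstream tests work in
#' the mean-centered space and tolerate this.
#'
#' @param g A [genotype_matrix()] with monomorphic sites already removed
#'   (see [filter_sites()]).
#' @return Symmetric n x n matrix with sample ids as dimnames and the panel
#'   provenance stored in `attr(, "provenance")`.
#' @export
standardized_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosage
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (any(!is.finite(p))) abort("some loci have no called genotypes.")
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic loci present; filter them out first (filter_sites()).")
  }
  S <- sweep(dos, 2, 2 * p, "-")
  S <- sweep(S, 2, sqrt(2 * p * (1 - p)), "/")
  S[is.na(S)] <- 0
  K <- tcrossprod(S) / ncol(S)
  dimnames(K) <- list(g$samples$sample, g$samples$sample)
  attr(K, "provenance") <- g$provenance
  K
}

#' Conditional (mean-centered) kinship eigendecomposition
#'
#' Conditions the kinship matrix on the trait mean by applying the centering
#' operator `T` (the first n-1 rows of `I - 11'/n`), giving the rank n-1
#' conditional kinship `K_cond = T K T'`, and eigendecomposes it. Eigenvalues
#' below `1e-8 * lambda_max` are clipped to zero and flagged unusable;
#' eigenvector signs are fixed so each vector's largest-magnitude entry is
#' positive.
#'
#' @param K Symmetric kinship matrix (from [standardized_kinship()]).
#' @param tol Relative symmetry tolerance.
#' @return An object of class `kinship_eigen` with elements `K`, `K_cond`,
#'   `Tmat`, `values`, `vectors`, `usable` (logical), `samples`,
#'   `provenance`; PC sets are added by [pc_sets()].
#' @export
conditional_eigen <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > tol * max(1, max(abs(K)))) {
    abort("`K` is not symmetric within tolerance.")
  }
  n <- nrow(K)
  Tmat <- (diag(n) - matrix(1 / n, n, n))[seq_len(n - 1L), , drop = FALSE]
  Kc <- Tmat %*% K %*% t(Tmat)
  Kc <- (Kc + t(Kc)) / 2
  ee <- eigen(Kc, symmetric = TRUE)
  lam <- ee$values
  U <- ee$vectors
  lam_max <- max(lam, 0)
  usable <- lam > 1e-8 * lam_max
  lam[!usable] <- 0
  if (!any(usable)) {
    warn("conditional kinship is degenerate (all samples identical); no usable PCs.")
  }
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(
    list(K = K, K_cond = Kc, Tmat = Tmat, values = lam, vectors = U,
         usable = usable,
         samples = rownames(K) %||% sprintf("s%03d", seq_len(n)),
         provenance = attr(K, "provenance") %||% "unknown",
         test_pcs = NULL, neutral_pcs = NULL),
    class = "kinship_eigen"
  )
}

#' @export
print.kinship_eigen <- function(x, ...) {
  cat(sprintf("<kinship_eigen> %d samples, %d usable PCs (provenance: %s)\n",
              length(x$samples), sum(x$usable), x$provenance))
  if (!is.null(x$test_pcs)) {
    cat("  test PCs:", paste(x$test_pcs, collapse = ", "),
        "| neutral PCs:", length(x$neutral_pcs), "PCs\n")
  }
  invisible(x)
}

#' Partition PCs into test and neutral sets
#'
#' The test set is the smallest leading block of PCs whose cumulative
#' eigenvalue share reaches `test_fraction` of the conditional kinship's
#' variance (the major axes of population structure, where selection is
#' tested). The neutral set represents neutral evolution and is chosen by one
#' of two rules:
#' \describe{
#'   \item{`"tail-share"`}{the smallest trailing block of PCs whose summed
#'     eigenvalue share reaches `neutral_fraction` (default).}
#'   \item{`"after-cum"`}{all PCs after the smallest leading block whose
#'     cumulative share reaches `1 - neutral_fraction`, i.e. the PCs beyond
#'     the cumulative cut point.}
#' }
#' The sets are guaranteed disjoint: if they would overlap the neutral block
#' is started after the test block, with a warning. Clipped (zero) eigenvalues
#' never enter either set.
#'
#' @param eigen A [conditional_eigen()] result.
#' @param test_fraction,neutral_fraction Fractions in (0, 1).
#' @param max_test_pcs Optional cap on the number of test PCs.
#' @param rule Neutral-set rule, see above.
#' @return The `kinship_eigen` object with `test_pcs` and `neutral_pcs`
#'   filled in.
#' @export
pc_sets <- function(eigen, test_fraction = 0.25, neutral_fraction = 0.50,
                    max_test_pcs = NULL, rule = c("tail-share", "after-cum")) {
  stopifnot(inherits(eigen, "kinship_eigen"))
  rule <- match.arg(rule)
  assert_fraction(test_fraction, "test_fraction", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(neutral_fraction, "neutral_fraction",
                  lo_open = TRUE, hi_open = TRUE)
  idx <- which(eigen$usable)
  lam <- eigen$values[idx]
  share <- lam / sum(lam)
  cum <- cumsum(share)
  m_test <- which(cum >= test_fraction)[1]
  if (!is.null(max_test_pcs)) m_test <- min(m_test, max_test_pcs)
  test <- idx[seq_len(m_test)]
  M <- length(idx)
  if (rule == "tail-share") {
    tail_share <- rev(cumsum(rev(share)))
    start <- which(tail_share >= neutral_fraction)
    start <- start[length(start)]  # largest start index still reaching the share
    neutral <- idx[start:M]
  } else {
    cut <- which(cum >= 1 - neutral_fraction)[1]
    neutral <- if (cut < M) idx[(cut + 1L):M] else integer(0)
  }
  if (length(intersect(test, neutral))) {
    warn("test and neutral PC sets overlapped; starting the neutral block after the test block.")
    neutral <- setdiff(neutral, test)
    neutral <- neutral[neutral > max(test)]
  }
  if (length(neutral) < 3) {
    abort("fewer than 3 neutral PCs; V_A estimation would be unstable.")
  }
  eigen$test_pcs <- test
  eigen$neutral_pcs <- neutral
  eigen$pc_rule <- rule
  eigen
}

#' Scree plot of the conditional kinship spectrum
#'
#' @param object A [conditional_eigen()] result (after [pc_sets()] the test
#'   and neutral blocks are colored).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinship_eigen
#' @export
autoplot.kinship_eigen <- function(object, ...) {
  idx <- which(object$usable)
  df <- tibble::tibble(
    pc = idx,
    eigenvalue = object$values[idx],
    set = dplyr::case_when(
      idx %in% (object$test_pcs %||% integer()) ~ "test",
      idx %in% (object$neutral_pcs %||% integer()) ~ "neutral",
      TRUE ~ "unused"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc, .data$eigenvalue,
                                   fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "conditional kinship PC", y = "eigenvalue",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method tidy kinship_eigen
#' @export
tidy.kinship_eigen <- function(x, ...) {
  idx <- seq_along(x$values)
  tibble::tibble(
    pc = idx,
    eigenvalue = x$values,
    share = x$values / sum(x$values),
    usable = x$usable,
    set = dplyr::case_when(
      idx %in% (x$test_pcs %||% integer()) ~ "test",
      idx %in% (x$neutral_pcs %||% integer()) ~ "neutral",
      TRUE ~ "unused"
    )
  )
}
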