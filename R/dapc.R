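# Discriminant analysis of principal components, used both for genotype
# cluster inference and for the transcriptome plasticity statistic.

#' K-means grouping on leading PCs
#'
#' PCA (centered, unscaled) followed by k-means on the top `n_pcs` scores,
#' best of `n_init` restarts; a BIC in the style used for selecting the
#' number of clusters from successive k-means fits is reported.
#'
#' @param X Samples x features numeric matrix.
#' @param k Number of groups.
#' @param n_pcs PCs retained (default 10).
#' @param n_init k-means restarts.
#' @param seed Integer seed.
#' @return List of class `kmeans_groups`: `groups` (factor), `bic`,
#'   `n_pcs`, `wss`.
#' @export
kmeans_groups <- function(X, k, n_pcs = 10, n_init = 10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) abort("`k` cannot exceed the number of samples.")
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  km <- with_seed_(seed, kmeans(scores, centers = k, nstart = n_init))
  wss <- km$tot.withinss
  bic <- n * log(wss / n) + k * log(n)
  structure(
    list(groups = factor(km$cluster), bic = bic, n_pcs = n_pcs, wss = wss,
         centers = km$centers),
    class = "kmeans_groups"
  )
}

#' Fit a discriminant analysis of principal components
#'
#' Centered (unscaled by default) PCA retaining `n_pcs` components, followed
#' by Fisher linear discriminant analysis in PC space maximizing
#' between-group over within-group variance; `k` groups give `k - 1`
#' discriminant axes, unit-norm in the within-group (whitened) metric. If the
#' pooled within-group covariance is singular a small ridge (1e-8 of its
#' mean diagonal) is added and noted. The leading axis sign is fixed so the
#' first group level has a negative mean score.
#'
#' @param X Samples x features matrix (e.g. variance-stabilized expression or
#'   genotype dosages).
#' @param groups Factor (or coercible) of group labels, length `nrow(X)`.
#' @param n_pcs PCs to retain; must be `< nrow(X) - nlevels(groups)`.
#' @param scale. Scale features to unit variance before PCA.
#' @return An object of class `dapc_fit`.
#' @export
dapc_fit <- function(X, groups, n_pcs = 10, scale. = FALSE) {
  X <- as.matrix(X)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 groups.")
  if (any(table(groups) < 2)) abort("each group needs >= 2 members.")
  if (n_pcs >= nrow(X) - k) abort("`n_pcs` must be < n samples - n groups.")
  pca <- prcomp(X, center = TRUE, scale. = scale.)
  n_pcs <- min(n_pcs, ncol(pca$x))
  S <- pca$x[, seq_len(n_pcs), drop = FALSE]
  gm <- rowsum(S, groups) / as.vector(table(groups))
  # pooled within-group covariance in PC space
  W <- matrix(0, n_pcs, n_pcs)
  for (g in levels(groups)) {
    D <- sweep(S[groups == g, , drop = FALSE], 2, gm[g, ], "-")
    W <- W + crossprod(D)
  }
  W <- W / (nrow(S) - k)
  ridge_used <- FALSE
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < 1e-10 * max(ew$values)) {
    ridge_used <- TRUE
    W <- W + diag(1e-8 * mean(diag(W)) + 1e-12, n_pcs)
    ew <- eigen(W, symmetric = TRUE)
    inform("singular within-group covariance; ridge added.")
  }
  Wi_half <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  # between-group scatter (weighted by group size)
  mu <- colMeans(S)
  B <- matrix(0, n_pcs, n_pcs)
  for (g in levels(groups)) {
    d <- gm[g, ] - mu
    B <- B + sum(groups == g) * tcrossprod(d)
  }
  B <- B / nrow(S)
  M <- Wi_half %*% B %*% Wi_half
  M <- (M + t(M)) / 2
  eb <- eigen(M, symmetric = TRUE)
  n_axes <- min(k - 1L, n_pcs)
  axes <- Wi_half %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  # orientation: first group level scores negative on each axis
  scores <- S %*% axes
  for (j in seq_len(n_axes)) {
    if (mean(scores[groups == levels(groups)[1], j]) > 0) {
      axes[, j] <- -axes[, j]
    }
  }
  scores <- S %*% axes
  colnames(scores) <- colnames(axes) <- paste0("LD", seq_len(n_axes))
  group_means <- rowsum(scores, groups) / as.vector(table(groups))
  structure(
    list(center = pca$center, scale = if (isFALSE(scale.)) NULL else pca$scale,
         rotation = pca$rotation[, seq_len(n_pcs), drop = FALSE],
         explained = pca$sdev[seq_len(n_pcs)]^2 / sum(pca$sdev^2),
         axes = axes, levels = levels(groups), group_means = group_means,
         scores = scores, groups = groups, n_pcs = n_pcs,
         ridge_used = ridge_used, features = colnames(X)),
    class = "dapc_fit"
  )
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("<dapc_fit> %d groups, %d retained PCs, %d discriminant axes\n",
              length(x$levels), x$n_pcs, ncol(x$axes)))
  invisible(x)
}

#' Project samples onto a fitted DAPC
#'
#' Centers new data with the training means, projects onto the retained PCs
#' and then onto the discriminant axes. Posterior group probabilities come
#' from a Gaussian class model in discriminant space with shared (identity,
#' because the axes are whitened) covariance and equal priors.
#'
#' @param model A [dapc_fit()].
#' @param X Samples x features matrix with the model's feature set.
#' @return List: `scores` (samples x axes), `posterior` (samples x groups),
#'   `assigned` (factor of argmax groups).
#' @export
dapc_project <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X))) {
    missing_feats <- setdiff(model$features, colnames(X))
    if (length(missing_feats)) {
      abort(paste("missing features:",
                  paste(utils::head(missing_feats, 5), collapse = ", ")))
    }
    X <- X[, model$features, drop = FALSE]
  }
  if (ncol(X) != length(model$center)) abort("feature dimension mismatch.")
  Xc <- sweep(X, 2, model$center, "-")
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  scores <- Xc %*% model$rotation %*% model$axes
  d2 <- sapply(seq_along(model$levels), function(g) {
    rowSums(sweep(scores, 2, model$group_means[g, ], "-")^2)
  })
  d2 <- matrix(d2, nrow = nrow(scores))
  logp <- -0.5 * d2
  logp <- sweep(logp, 1, apply(logp, 1, max), "-")
  post <- exp(logp) / rowSums(exp(logp))
  colnames(post) <- model$levels
  rownames(post) <- rownames(scores) <- rownames(X)
  list(scores = scores, posterior = post,
       assigned = factor(model$levels[max.col(post)], levels = model$levels))
}

#' Transcriptomic plasticity of accessions
#'
#' Discriminant scores are z-transformed within each genetic cluster (mean
#' and SD over all that cluster's samples at both sites, SD with `n - 1`),
#' replicate scores averaged per accession x site, and an accession's
#' plasticity is the absolute difference between its mean z-score at the
#' transplant site and at its native site.
#'
#' @param scores Numeric vector (or 1-column matrix) of discriminant scores,
#'   one per sample.
#' @param meta Tibble with `sample`, `accession`, `cluster`, `site` matching
#'   `scores` order (or `scores` names).
#' @param native_site_map Named character vector mapping cluster -> native
#'   site, e.g. `c(Northern = "inland", Central = "inland", Coastal =
#'   "coastal")`.
#' @return Tibble: `accession`, `cluster`, `native_site`, `z_native`,
#'   `z_transplant`, `plasticity`.
#' @export
plasticity <- function(scores, meta, native_site_map) {
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("sample", "accession", "cluster", "site") %in% names(meta)))
  scores <- drop(as.matrix(scores))
  if (!is.null(names(scores))) scores <- scores[meta$sample]
  if (length(scores) != nrow(meta)) abort("one score per metadata row required.")
  if (!all(meta$cluster %in% names(native_site_map))) {
    abort("`native_site_map` must name every cluster.")
  }
  df <- meta
  df$score <- scores
  df <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(z = (.data$score - mean(.data$score)) / sd(.data$score)) |>
    dplyr::ungroup()
  acc <- df |>
    dplyr::group_by(.data$accession, .data$cluster, .data$site) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  wide <- tidyr::pivot_wider(acc, names_from = "site", values_from = "z")
  sites <- setdiff(names(wide), c("accession", "cluster"))
  if (length(sites) != 2) abort("exactly two sites are required.")
  incomplete <- !stats::complete.cases(wide[, sites])
  if (any(incomplete)) {
    inform(sprintf("%d accession(s) measured at one site only; excluded.",
                   sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  native <- unname(native_site_map[wide$cluster])
  transplant <- ifelse(native == sites[1], sites[2], sites[1])
  z_nat <- ifelse(native == sites[1], wide[[sites[1]]], wide[[sites[2]]])
  z_tra <- ifelse(native == sites[1], wide[[sites[2]]], wide[[sites[1]]])
  tibble::tibble(
    accession = wide$accession, cluster = wide$cluster,
    native_site = native, z_native = z_nat, z_transplant = z_tra,
    plasticity = abs(z_tra - z_nat)
  )
}

#' Test for cluster differences in plasticity
#'
#' One-way ANOVA of per-accession plasticity on genetic cluster, followed by
#' Tukey HSD pairwise comparisons. (With replicates already collapsed to one
#' plasticity value per accession, the genotype random effect of a mixed
#' model is absorbed into the residual, so accession-level ANOVA is the
#' appropriate fixed-effect test.)
#'
#' @param plast Tibble from [plasticity()] (needs `plasticity`, `cluster`),
#'   or a numeric vector with `clusters` given separately.
#' @param clusters Optional cluster labels when `plast` is a vector.
#' @return List of class `plasticity_test`: `summary` (cluster means and
#'   SE), `anova` (F and p), `tukey` (pairwise adjusted p).
#' @export
plasticity_test <- function(plast, clusters = NULL) {
  if (is.data.frame(plast)) {
    values <- plast$plasticity
    clusters <- plast$cluster
  } else {
    values <- as.numeric(plast)
  }
  df <- tibble::tibble(plasticity = values, cluster = factor(clusters))
  small <- names(which(table(df$cluster) < 2))
  if (length(small)) {
    warn(sprintf("cluster(s) with a single accession dropped: %s",
                 paste(small, collapse = ", ")))
    df <- df[!df$cluster %in% small, , drop = FALSE]
    df$cluster <- droplevels(df$cluster)
  }
  if (nlevels(df$cluster) < 2) abort("need >= 2 clusters with >= 2 accessions.")
  summ <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean = mean(.data$plasticity),
                     se = sd(.data$plasticity) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  if (isTRUE(all(values == values[1]))) {
    an <- tibble::tibble(statistic = 0, p.value = 1)
    tk <- tidyr::expand_grid(a = levels(df$cluster), b = levels(df$cluster)) |>
      dplyr::filter(.data$a < .data$b) |>
      dplyr::transmute(contrast = paste(.data$b, .data$a, sep = "-"),
                       diff = 0, adj.p.value = 1)
  } else {
    fit <- aov(plasticity ~ cluster, data = df)
    anova_tab <- summary(fit)[[1]]
    an <- tibble::tibble(statistic = anova_tab[["F value"]][1],
                         p.value = anova_tab[["Pr(>F)"]][1])
    th <- TukeyHSD(fit)$cluster
    tk <- tibble::tibble(contrast = rownames(th),
                         diff = th[, "diff"],
                         adj.p.value = th[, "p adj"])
  }
  structure(list(summary = summ, anova = an, tukey = tk),
            class = "plasticity_test")
}

#' @export
print.plasticity_test <- function(x, ...) {
  cat("<plasticity_test>\n")
  print(x$summary)
  cat(sprintf("ANOVA F = %.3f, p = %.3g\n", x$anova$statistic, x$anova$p.value))
  print(x$tukey)
  invisible(x)
}

#' @method tidy plasticity_test
#' @export
tidy.plasticity_test <- function(x, ...) x$tukey

#' @method glance plasticity_test
#' @export
glance.plasticity_test <- function(x, ...) x$anova

#' @method tidy dapc_fit
#' @export
tidy.dapc_fit <- function(x, ...) {
  tibble::tibble(
    sample = rownames(x$scores) %||% seq_len(nrow(x$scores)),
    group = x$groups,
    score = x$scores[, 1]
  )
}

#' Density plot of DAPC scores by group
#'
#' @param object A [dapc_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dapc_fit
#' @export
autoplot.dapc_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "discriminant score (LD1)", fill = NULL) +
    ggplot2::theme_minimal()
}
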