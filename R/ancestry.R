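# Outgroup polarization: is the coastal or the inland cluster ancestral?

#' Per-orthogroup coastal-ancestral fraction
#'
#' Orthogroups with fewer than `min_variant_sites` variant sites (inland
#' allele differing from coastal allele) are excluded. Within an orthogroup,
#' only polarizable sites count: those where exactly one of the two ingroup
#' alleles matches the ancestral state. The orthogroup fraction is the share
#' of polarizable sites at which the coastal allele is ancestral; the overall
#' statistic is the mean of orthogroup fractions. With `method = "majority"`
#' each orthogroup instead contributes a binary majority call (fraction >
#' 0.5 counts 1, < 0.5 counts 0, ties 0.5).
#'
#' @param table Tibble with columns `orthogroup`, `inland`, `coastal`,
#'   `ancestral` (see [simulate_orthogroups()]).
#' @param min_variant_sites Minimum variant sites per orthogroup.
#' @param method `"fraction"` (default) or `"majority"`.
#' @return List of class `ancestral_fraction`: `per_group` tibble
#'   (`orthogroup`, `n_variant`, `n_informative`, `fraction`) and `estimate`.
#' @export
ancestral_fraction <- function(table, min_variant_sites = 3,
                               method = c("fraction", "majority")) {
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  need <- c("orthogroup", "inland", "coastal", "ancestral")
  if (!all(need %in% names(table))) {
    abort(paste("`table` needs columns:", paste(need, collapse = ", ")))
  }
  tab <- table |>
    dplyr::mutate(
      variant = .data$inland != .data$coastal,
      coastal_anc = .data$coastal == .data$ancestral,
      inland_anc = .data$inland == .data$ancestral,
      informative = .data$variant & (xor(.data$coastal_anc, .data$inland_anc)) &
        !is.na(.data$ancestral)
    )
  per_group <- tab |>
    dplyr::group_by(.data$orthogroup) |>
    dplyr::summarise(
      n_variant = sum(.data$variant),
      n_informative = sum(.data$informative),
      fraction = ifelse(sum(.data$informative) > 0,
                        sum(.data$coastal_anc & .data$informative) /
                          sum(.data$informative), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_variant >= min_variant_sites,
                  !is.na(.data$fraction))
  if (!nrow(per_group)) {
    abort("no orthogroup passes the variant-site filter.")
  }
  vals <- if (method == "majority") {
    ifelse(per_group$fraction > 0.5, 1,
           ifelse(per_group$fraction < 0.5, 0, 0.5))
  } else {
    per_group$fraction
  }
  structure(
    list(per_group = per_group, values = vals, estimate = mean(vals),
         method = method, min_variant_sites = min_variant_sites),
    class = "ancestral_fraction"
  )
}

#' @export
print.ancestral_fraction <- function(x, ...) {
  cat(sprintf(
    "<ancestral_fraction> %d orthogroups; P(coastal ancestral) = %.3f (%s)\n",
    nrow(x$per_group), x$estimate, x$method))
  invisible(x)
}

#' Bootstrap CI for the mean coastal-ancestral fraction
#'
#' Resamples orthogroups with replacement and returns the percentile
#' interval of the mean fraction.
#'
#' @param fractions Numeric vector of per-orthogroup fractions, or an
#'   [ancestral_fraction()] result.
#' @param n_boot Bootstrap replicates (default 10,000).
#' @param alpha Two-sided tail probability (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return Tibble: `point`, `lower`, `upper`, `n_boot`, `n_orthogroups`.
#' @export
bootstrap_ci <- function(fractions, n_boot = 10000L, alpha = 0.05, seed = 1L) {
  if (inherits(fractions, "ancestral_fraction")) fractions <- fractions$values
  fractions <- as.numeric(fractions)
  n <- length(fractions)
  if (n < 2) abort("need >= 2 orthogroups to bootstrap.")
  means <- with_seed_(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(fractions[idx], nrow = n_boot))
  })
  qs <- quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  tibble::tibble(point = mean(fractions), lower = qs[1], upper = qs[2],
                 n_boot = as.integer(n_boot), n_orthogroups = n)
}
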