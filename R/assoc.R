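# Small bespoke statistics: Fisher enrichment, relative water content,
# partial Spearman correlation.

#' Fisher enrichment of a gene category within a hit set
#'
#' Builds the 2x2 table `[[a, b], [c, d]]` with `a` the hits in the
#' category, `b` the hits outside it, `c` the non-hit category genes and `d`
#' the rest of the universe. The odds ratio is the sample estimate
#' `ad / bc`, with a Haldane 0.5 correction applied (and flagged) iff any
#' cell is zero. The p-value is the two-sided exact test summing all tables
#' with the fixed margins whose probability does not exceed the observed
#' table's.
#'
#' @param hits,category Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return List of class `enrichment_result`: `table`, `odds_ratio`,
#'   `p.value`, `haldane`, `labels`.
#' @export
fisher_enrichment <- function(hits, category, universe) {
  if (!length(universe)) abort("`universe` is empty.")
  universe <- unique(universe)
  hits <- intersect(unique(hits), universe)
  category <- intersect(unique(category), universe)
  a <- length(intersect(hits, category))
  b <- length(hits) - a
  cc <- length(category) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("hit", "non-hit"),
                                c("in category", "out")))
  haldane <- any(tab == 0)
  tc <- if (haldane) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- fisher.test(tab)$p.value
  structure(
    list(table = tab, odds_ratio = or, p.value = p, haldane = haldane,
         labels = c(hits = "hits", category = "category")),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat(sprintf("odds ratio = %.3g%s, p = %.3g\n", x$odds_ratio,
              if (x$haldane) " (Haldane-corrected)" else "", x$p.value))
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(a = x$table[1, 1], b = x$table[1, 2],
                 c = x$table[2, 1], d = x$table[2, 2],
                 odds_ratio = x$odds_ratio, p.value = x$p.value,
                 haldane = x$haldane)
}

#' Relative water content
#'
#' `RWC = (fresh - dry) / (turgid - dry) * 100`. Values above 100 are
#' physically impossible but occur through measurement noise; they are
#' returned as-is with a warning.
#'
#' @param fresh,turgid,dry Weights (same units), vectorized.
#' @return Percent RWC.
#' @export
rwc <- function(fresh, turgid, dry) {
  if (any(turgid <= dry)) abort("turgid weight must exceed dry weight.")
  if (any(fresh < dry)) abort("fresh weight cannot be below dry weight.")
  out <- (fresh - dry) / (turgid - dry) * 100
  if (any(out > 100)) {
    warn(sprintf("%d RWC value(s) above 100%% (measurement noise).",
                 sum(out > 100)))
  }
  out
}

#' Partial Spearman correlation
#'
#' All three vectors are rank-transformed; the linear effect of the control
#' ranks is removed from the x and y ranks, and the correlation of the
#' residuals is tested with a t approximation on n - 3 degrees of freedom.
#'
#' @param x,y,control Numeric vectors of equal length >= 4.
#' @return Tibble: `estimate`, `statistic`, `p.value`, `n`.
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  if (n < 4 || length(y) != n || length(control) != n) {
    abort("x, y and control must have equal length >= 4.")
  }
  if (sd(x) == 0 || sd(y) == 0 || sd(control) == 0) {
    abort("constant vectors have no defined correlation.")
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(control)
  ex <- resid(lm(rx ~ rz))
  ey <- resid(lm(ry ~ rz))
  if (sd(ex) < 1e-12 || sd(ey) < 1e-12) {
    # a variable fully explained by the control has no partial association
    return(tibble::tibble(estimate = 0, statistic = 0, p.value = 1, n = n))
  }
  rho <- cor(ex, ey)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 3)
  tibble::tibble(estimate = rho, statistic = tstat, p.value = p, n = n)
}
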