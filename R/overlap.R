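#' Fisher overlap test between two hit lists
#'
#' Tests whether two gene lists share more members than expected by chance in
#' a universe of `n_universe` genes, with the two-sided Fisher exact test:
#' all 2x2 tables with the observed margins whose point hypergeometric
#' probability does not exceed that of the observed table contribute to the
#' p-value. Probabilities are accumulated in log space, so extreme overlaps
#' (p ~ 1e-35) are computed without underflow.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param n_universe Size of the gene universe; must be at least
#'   `length(union(set_a, set_b))`.
#' @return An `overlap_result`: list with `table` (2x2 matrix), `p_value`,
#'   and `venn` (tibble: `both`, `a_only`, `b_only`, `neither`). Supports
#'   [tidy()] and [glance()].
#' @export
#' @examples
#' a <- paste0("g", 1:10); b <- paste0("g", 6:20)
#' fisher_overlap(a, b, n_universe = 100)$p_value
fisher_overlap <- function(set_a, set_b, n_universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_a <- length(set_a)
  n_b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  n_union <- n_a + n_b - k
  if (n_universe < n_union) {
    abort("`n_universe` is smaller than the union of the two sets.")
  }
  p <- fisher_two_sided(k, n_a, n_b, n_universe)
  tab <- matrix(c(k, n_a - k, n_b - k, n_universe - n_union), nrow = 2,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  structure(
    list(table = tab, p_value = p,
         venn = tibble(both = k, a_only = n_a - k, b_only = n_b - k,
                       neither = n_universe - n_union)),
    class = "overlap_result"
  )
}

# Two-sided Fisher exact p by the point-probability criterion, in log space.
fisher_two_sided <- function(k, n_a, n_b, n) {
  support <- max(0, n_a + n_b - n):min(n_a, n_b)
  lp <- dhyper(support, n_a, n - n_a, n_b, log = TRUE)
  obs <- dhyper(k, n_a, n - n_a, n_b, log = TRUE)
  keep <- lp <= obs + 1e-7 # tolerate rounding at the point probability
  m <- max(lp[keep])
  min(1, exp(m + log(sum(exp(lp[keep] - m)))))
}

#' Venn partition counts for two gene lists
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return A tibble with columns `both`, `a_only`, `b_only`.
#' @export
#' @examples
#' venn_counts(paste0("g", 1:10), paste0("g", 6:20))
venn_counts <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  tibble(both = k, a_only = length(set_a) - k, b_only = length(set_b) - k)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result>\n")
  print(x$table)
  cat(sprintf("two-sided Fisher p = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) x$venn

#' @export
glance.overlap_result <- function(x, ...) {
  bind_cols(tibble(p_value = x$p_value), x$venn)
}
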