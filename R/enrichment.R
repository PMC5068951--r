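#' Fold enrichment of a term in a hit list
#'
#' `(k/n) / (K/N)`: the list frequency of a term divided by its background
#' frequency, the over-representation ratio printed in enrichment tables
#' (which round it to the nearest integer).
#'
#' @param k Hits annotated to the term.
#' @param n Hit-list size.
#' @param K Term size in the background.
#' @param N Background (universe) size.
#' @return The raw fold enrichment (use `round()` for the printed integer).
#' @export
#' @examples
#' fold_enrichment(10, 36, 93, 5135) # ~15.3
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(N <= 0)) abort("`n` and `N` must be > 0.")
  if (any(K <= 0)) abort("`K` must be > 0: term absent from the background.")
  if (any(k < 0) || any(k > pmin(n, K))) abort("`k` must lie in [0, min(n, K)].")
  (k / n) / (K / N)
}

#' Upper-tail hypergeometric p-value for over-representation
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` term members in a hit list of size `n` from a universe of `N`
#' genes of which `K` carry the term. Computed on the log scale internally so
#' extreme enrichments do not underflow.
#'
#' @inheritParams fold_enrichment
#' @return The p-value in [0, 1] (`k = 0` gives exactly 1).
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) abort("`n`, `K`, `N` must be > 0.")
  if (any(k < 0) || any(k > pmin(n, K))) abort("`k` must lie in [0, min(n, K)].")
  if (any(K > N) || any(n > N)) abort("`K` and `n` cannot exceed `N`.")
  ifelse(k == 0, 1, pmin(1, exp(phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE, log.p = TRUE))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across a vector of p-values; order-preserving and
#' bounded by 1.
#'
#' @param pvalues Numeric vector of p-values in [0, 1]; an empty vector
#'   returns an empty vector.
#' @return Adjusted q-values.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation table for a hit list
#'
#' One row per term with at least one hit: fold enrichment, list and
#' background frequencies, upper-tail hypergeometric p and BH q, ranked by p.
#' The background universe materially changes every statistic; it is taken
#' from the collection (e.g. all protein-coding genes vs only the assayed
#' mutants) and recorded in the output.
#'
#' @param hit_list Character vector of hit gene ids.
#' @param collection A `gene_set_collection`.
#' @param alpha Significance level for the `significant` flag on q (default
#'   0.01).
#' @return An `enrichment_result` tibble with columns `term`, `k`, `n`, `K`,
#'   `N`, `fold`, `fold_rounded`, `list_freq`, `background_freq`, `p_value`,
#'   `q_value`, `significant`, `genes`.
#' @export
enrich_table <- function(hit_list, collection, alpha = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  hit_list <- unique(hit_list)
  hits_in_universe <- intersect(hit_list, collection$universe)
  if (length(hits_in_universe) == 0) {
    abort("hit list is disjoint from the collection's universe.")
  }
  n <- length(hits_in_universe)
  N <- length(collection$universe)
  rows <- imap(collection$sets, function(members, term) {
    K <- length(members)
    k <- length(intersect(members, hits_in_universe))
    if (k == 0 || K == 0) return(NULL)
    tibble(
      term = term, k = k, n = n, K = K, N = N,
      fold = fold_enrichment(k, n, K, N),
      list_freq = k / n,
      background_freq = K / N,
      p_value = hypergeom_pvalue(k, n, K, N),
      genes = paste(sort(intersect(members, hits_in_universe)), collapse = ",")
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(term = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), fold = numeric(),
                  list_freq = numeric(), background_freq = numeric(),
                  p_value = numeric(), genes = character())
  }
  out <- out |>
    mutate(fold_rounded = round(.data$fold), .after = "fold") |>
    arrange(.data$p_value) |>
    mutate(q_value = adjust_fdr(.data$p_value),
           significant = .data$q_value <= alpha, .after = "p_value")
  structure(out, alpha = alpha,
            class = c("enrichment_result", class(out)))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         background_size = if (nrow(x) > 0) x$N[[1]] else NA_integer_)
}
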