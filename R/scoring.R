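#' Library-size normalize a count table (counts per million)
#'
#' Adds a pseudocount to every entry and scales each sample column to a total
#' of 10^6, putting samples of different sequencing depth on a common scale
#' before log-ratio computation.
#'
#' @param counts Tibble with `mutant_id` plus integer sample columns.
#' @param pseudocount Positive pseudocount (default 1) guarding the log
#'   against zero counts.
#' @return A tibble of the same shape whose sample columns each sum to 10^6.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  samples <- assert_count_table(counts)
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  out <- counts
  for (s in samples) {
    x <- counts[[s]] + pseudocount
    tot <- sum(x)
    if (sum(counts[[s]]) == 0) {
      abort(sprintf("sample '%s' has no reads; cannot normalize.", s))
    }
    out[[s]] <- 1e6 * x / tot
  }
  out
}

#' Growth-inhibition (GI) score from normalized endpoint abundances
#'
#' `GI_i = log2(control_i / treatment_i) / d`: the per-doubling log2 depletion
#' of a mutant under treatment relative to control. A mutant unaffected by the
#' treatment scores 0; a mutant that completely fails to grow while the pool
#' completes `d` doublings is depleted 2^d-fold and scores approximately 1.
#' Comparing the treatment endpoint against the control endpoint (rather than
#' the inoculum) cancels intrinsic slow growth, which affects both arms.
#'
#' @param norm_control,norm_treatment Named numeric vectors of normalized
#'   abundances for the same mutant universe (names = mutant ids). Mutants
#'   missing from either vector get `NA` (recorded, never imputed).
#' @param d Number of pool doublings (> 0), default 5.
#' @return A tibble with columns `mutant_id` and `gi`.
#' @export
#' @examples
#' gi_score(c(a = 320, b = 10), c(a = 10, b = 10), d = 5)
gi_score <- function(norm_control, norm_treatment, d = 5) {
  if (d <= 0) abort("`d` must be > 0.")
  if (is.null(names(norm_control)) || is.null(names(norm_treatment))) {
    abort("normalized abundance vectors must be named by mutant id.")
  }
  ids <- union(names(norm_control), names(norm_treatment))
  ctrl <- norm_control[ids]
  trt <- norm_treatment[ids]
  gi <- log2(ctrl / trt) / d
  gi[is.na(ctrl) | is.na(trt)] <- NA_real_
  tibble(mutant_id = ids, gi = unname(gi))
}

#' Robust Z-scores from a GI vector (median / NIQR)
#'
#' Each mutant's deviation from the screen median GI, expressed in units of
#' the normalized interquartile range NIQR = IQR / 1.349. The NIQR is a
#' robust, outlier-insensitive estimate of the spread of the null bulk
#' (1.349 = 2 * qnorm(0.75), making NIQR a consistent estimator of the
#' standard deviation under normality), so genuinely sensitive mutants do not
#' inflate the scale they are judged against.
#'
#' @param gi Numeric vector of GI scores (NA allowed; propagated).
#' @return A list with `z` (numeric, same length/names as `gi`) and `stats`
#'   (one-row tibble: `median`, `iqr`, `niqr`, `n`).
#' @export
robust_z <- function(gi) {
  ok <- !is.na(gi)
  if (sum(ok) < 10) abort("need at least 10 non-missing GI values.")
  med <- median(gi[ok])
  iqr <- IQR(gi[ok])
  niqr <- iqr / 1.349
  if (niqr == 0) abort("degenerate screen: NIQR is 0.")
  z <- (gi - med) / niqr
  list(z = z, stats = tibble(median = med, iqr = iqr, niqr = niqr, n = sum(ok)))
}

#' Tail-area false discovery rates from robust Z-scores
#'
#' Two-component empirical-null model on absolute Z-scores: the central bulk
#' of |Z| is treated as null and fitted with a half-normal of scale `sigma0`
#' by truncated maximum likelihood below a cutoff quantile; the implied null
#' proportion `pi0` follows from the fraction of scores below the cutoff. The
#' tail-area FDR of a score `z` is then
#' `Fdr(z) = min(1, pi0 * P0(|Z| >= |z|) / Fhat(|Z| >= |z|))`,
#' with `Fhat` the empirical exceedance, and the result is forced
#' non-increasing in |z| (a larger score never gets a larger FDR).
#'
#' @param z Numeric vector of robust Z-scores (NA allowed; propagated).
#' @param cutoff_quantile Quantile of |z| below which scores are used for the
#'   null fit (default 0.75).
#' @return A list with `fdr` (numeric, same length as `z`) and `null` (one-row
#'   tibble: `pi0`, `sigma0`, `cutoff`, `n`).
#' @export
tail_area_fdr <- function(z, cutoff_quantile = 0.75) {
  ok <- which(!is.na(z) & is.finite(z))
  if (length(ok) < 100) abort("need at least 100 finite Z-scores.")
  a <- abs(z[ok])
  n <- length(a)
  z0 <- quantile(a, cutoff_quantile, names = FALSE)
  if (z0 <= 0) abort("null fit failure: cutoff quantile of |z| is 0.")
  central <- a[a <= z0]
  if (length(central) < n / 2) {
    abort("null fit failure: more than half of the scores lie in the tail.")
  }
  # truncated half-normal MLE for sigma0 on |z| <= z0
  nll <- function(s) {
    -sum(dnorm(central, 0, s, log = TRUE) -
           log(2 * pnorm(z0 / s) - 1))
  }
  fit <- optimize(nll, interval = c(1e-3, max(10, 10 * z0)))
  sigma0 <- fit$minimum
  p_central <- 2 * pnorm(z0 / sigma0) - 1 # null mass below the cutoff
  pi0 <- min(1, (length(central) / n) / p_central)

  surv0 <- 2 * pnorm(-a / sigma0)                  # null P(|Z| >= a)
  emp <- (n + 1 - rank(a, ties.method = "min")) / n # empirical exceedance
  raw <- pmin(1, pi0 * surv0 / emp)
  # enforce monotone non-increasing FDR in |z|: each score's FDR is the
  # largest raw value at or beyond it, so a weaker score is never reported
  # as more significant than a stronger one
  ord <- order(a)
  mono <- rev(cummax(rev(raw[ord])))
  fdr_ok <- numeric(n)
  fdr_ok[ord] <- mono
  fdr <- rep(NA_real_, length(z))
  fdr[ok] <- fdr_ok
  list(fdr = fdr,
       null = tibble(pi0 = pi0, sigma0 = sigma0, cutoff = z0, n = n))
}

#' Score one screen: counts in, GI / Z / FDR out
#'
#' Convenience wrapper running [normalize_counts()], [gi_score()],
#' [robust_z()] and [tail_area_fdr()] for one control/treatment pair.
#'
#' @param counts Count table (tibble with `mutant_id` + sample columns).
#' @param control,treatment Column names of the control and treatment samples.
#' @param d Pool doublings for this screen (default 5).
#' @param pseudocount Pseudocount for normalization.
#' @param screen_id,compound Optional metadata attached to the result.
#' @return A `gi_screen` tibble with columns `mutant_id`, `gi`, `z`, `fdr`;
#'   robust statistics, the null model and metadata are carried as attributes
#'   and surfaced by [glance()].
#' @export
score_screen <- function(counts, control, treatment, d = 5, pseudocount = 1,
                         screen_id = NULL, compound = NULL) {
  samples <- assert_count_table(counts)
  if (!all(c(control, treatment) %in% samples)) {
    abort("`control` and `treatment` must name sample columns of `counts`.")
  }
  norm <- normalize_counts(counts[c("mutant_id", control, treatment)], pseudocount)
  gi <- gi_score(setNames(norm[[control]], norm$mutant_id),
                 setNames(norm[[treatment]], norm$mutant_id), d = d)
  rz <- robust_z(gi$gi)
  fd <- tail_area_fdr(rz$z)
  out <- tibble(mutant_id = gi$mutant_id, gi = gi$gi, z = rz$z, fdr = fd$fdr)
  structure(out,
            robust_stats = rz$stats,
            null_model = fd$null,
            screen_id = screen_id %||% paste(control, "vs", treatment),
            compound = compound,
            d = d,
            class = c("gi_screen", class(out)))
}

#' @export
tidy.gi_screen <- function(x, ...) as_tibble(x)

#' @export
glance.gi_screen <- function(x, ...) {
  bind_cols(
    tibble(screen_id = attr(x, "screen_id"),
           compound = attr(x, "compound") %||% NA_character_,
           d = attr(x, "d")),
    attr(x, "robust_stats"),
    rename(attr(x, "null_model"), n_finite_z = "n")
  )
}
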