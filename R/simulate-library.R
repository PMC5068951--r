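#' Generate a barcoded deletion-library design
#'
#' Creates a synthetic pooled-library catalog: one uptag and one dntag barcode
#' per mutant, all drawn from \{A,C,G,T\}, with every pair of barcodes within a
#' tag class at Hamming distance >= 3 so that single-mismatch matching is
#' provably unambiguous. The read layout (sample index + constant spacer +
#' barcode) is attached to the design and shared with the counting stage.
#'
#' @param n_mutants Number of deletion mutants in the pool.
#' @param barcode_length Barcode length in nucleotides (default 20).
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @param spacer Constant spacer sequence placed between the sample index and
#'   the barcode in every read.
#' @param max_attempts Bound on rejection-sampling rounds used to repair
#'   distance violations before giving up.
#'
#' @return An object of class `barseq_design`: a list with `catalog` (a tibble
#'   with columns `mutant_id`, `uptag`, `dntag`) and `layout` (spacer sequence
#'   and barcode length).
#' @export
#' @examples
#' design <- generate_library(20, seed = 1)
#' design$catalog
generate_library <- function(n_mutants, barcode_length = 20, seed = 1,
                             spacer = "CGCTA", max_attempts = 50) {
  if (n_mutants < 1) abort("`n_mutants` must be >= 1.")
  if (barcode_length < 1) abort("`barcode_length` must be >= 1.")
  if (!grepl("^[ACGT]*$", spacer)) abort("`spacer` must be an ACGT string.")
  catalog <- with_seed(seed, {
    up <- sample_distant_barcodes(n_mutants, barcode_length, max_attempts)
    dn <- sample_distant_barcodes(n_mutants, barcode_length, max_attempts)
    tibble(
      mutant_id = sprintf("mut%04d", seq_len(n_mutants)),
      uptag = up,
      dntag = dn
    )
  })
  structure(
    list(
      catalog = catalog,
      layout = list(spacer = spacer, barcode_length = as.integer(barcode_length))
    ),
    class = "barseq_design"
  )
}

# Rejection sampling of a barcode set with pairwise Hamming distance >= 3.
# Random draws almost always satisfy the constraint at L = 20; offending
# sequences are resampled and rechecked for a bounded number of rounds.
sample_distant_barcodes <- function(n, length, max_attempts) {
  mat <- random_dna(n, length)
  for (attempt in seq_len(max_attempts)) {
    bad <- distance_violations(mat)
    if (length(bad) == 0L) return(collapse_dna(mat))
    mat[bad, ] <- random_dna(length(bad), length)
  }
  abort(sprintf(
    "could not find %d barcodes of length %d with pairwise Hamming distance >= 3 in %d attempts",
    n, length, max_attempts
  ))
}

# Indices of rows involved in a pair at Hamming distance < 3. Distances are
# computed via per-letter indicator cross-products, avoiding an explicit
# character-level double loop.
distance_violations <- function(mat) {
  n <- nrow(mat)
  if (n < 2L) return(integer())
  L <- ncol(mat)
  matches <- matrix(0, n, n)
  for (b in DNA_ALPHABET) {
    ind <- (mat == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- L - matches
  diag(d) <- Inf
  which(apply(d, 1L, min) < 3)
}

#' @export
print.barseq_design <- function(x, ...) {
  cat(sprintf(
    "<barseq_design> %d mutants, %d-nt barcodes, spacer '%s'\n",
    nrow(x$catalog), x$layout$barcode_length, x$layout$spacer
  ))
  print(x$catalog, n = 5)
  invisible(x)
}

#' Define per-mutant fitness under control and treatment
#'
#' Builds the latent fitness model whose parameter the GI score estimates.
#' Each mutant carries a baseline relative doubling rate (1 = wild type) and a
#' treatment fitness `f` in [0, 1]: the fraction of wild-type doublings it
#' achieves under treatment. Mutants are planted into sensitivity classes
#' `none` (f = 1), `low`, `medium` and `high`; with baseline rate 1 the
#' expected GI score of a mutant is `1 - f`, so the defaults f = 0.9 / 0.6 / 0
#' give expected GI 0.1 / 0.4 / 1.0 — spanning low to complete growth failure.
#'
#' @param design A `barseq_design` from [generate_library()].
#' @param n_low,n_medium,n_high Numbers of mutants planted in each sensitivity
#'   class; the remainder are unaffected (`none`).
#' @param f_low,f_medium,f_high Treatment fitness values for the classes.
#' @param baseline_rate Per-mutant relative doubling rate under control;
#'   recycled to the number of mutants.
#' @param seed Seed controlling which mutants receive the planted classes.
#'
#' @return A `barseq_fitness` tibble with columns `mutant_id`, `baseline_rate`,
#'   `f` (treatment fitness), `class`, and `expected_gi` (`1 - f` scaled by the
#'   baseline rate). This is the simulation truth table used by
#'   parameter-recovery tests.
#' @export
fitness_model <- function(design, n_low = 0, n_medium = 0, n_high = 0,
                          f_low = 0.9, f_medium = 0.6, f_high = 0,
                          baseline_rate = 1, seed = 1) {
  stopifnot(inherits(design, "barseq_design"))
  fs <- c(low = f_low, medium = f_medium, high = f_high)
  if (any(fs < 0 | fs > 1)) abort("treatment fitness values must lie in [0, 1].")
  n <- nrow(design$catalog)
  n_planted <- n_low + n_medium + n_high
  if (n_planted > n) abort("more planted mutants than mutants in the design.")
  cls <- with_seed(seed, {
    lab <- rep("none", n)
    idx <- sample.int(n, n_planted)
    lab[idx] <- rep(c("low", "medium", "high"), times = c(n_low, n_medium, n_high))
    lab
  })
  f <- ifelse(cls == "none", 1, fs[cls])
  out <- tibble(
    mutant_id = design$catalog$mutant_id,
    baseline_rate = rep_len(baseline_rate, n),
    f = unname(f),
    class = cls,
    # doublings lost per pool doubling; equals 1 - f when baseline_rate = 1
    expected_gi = rep_len(baseline_rate, n) * (1 - unname(f))
  )
  class(out) <- c("barseq_fitness", class(out))
  out
}

#' Expected relative abundances after pooled competitive growth
#'
#' Deterministic expectation of the simulator: after `d` pool doublings the
#' relative abundance of mutant i is proportional to
#' `a0_i * 2^(g_i * d)`, where `g_i` is the mutant's realised relative growth
#' rate (`baseline_rate` under control, `baseline_rate * f` under treatment).
#' Useful for closed-form checks of the GI estimator at infinite sequencing
#' depth.
#'
#' @param fitness A `barseq_fitness` tibble (see [fitness_model()]).
#' @param d Number of pool doublings during the screen.
#' @param condition `"control"` or `"treatment"`.
#' @param initial_abundance Optional initial relative abundances (default
#'   equal); recycled and renormalised.
#'
#' @return A named numeric vector of expected proportions (sums to 1).
#' @export
expected_proportions <- function(fitness, d, condition = c("control", "treatment"),
                                 initial_abundance = NULL) {
  condition <- match.arg(condition)
  if (d <= 0) abort("`d` must be > 0.")
  n <- nrow(fitness)
  a0 <- initial_abundance %||% rep(1, n)
  a0 <- rep_len(a0, n)
  if (any(a0 < 0) || sum(a0) <= 0) abort("initial abundances must be non-negative with positive total.")
  g <- fitness$baseline_rate
  if (condition == "treatment") g <- g * fitness$f
  w <- a0 * 2^(g * d)
  if (sum(w) <= 0) abort("zero total abundance after growth.")
  setNames(w / sum(w), fitness$mutant_id)
}

#' Simulate a Bar-seq count table for one growth condition
#'
#' Grows the pool deterministically in expectation ([expected_proportions()])
#' and draws observed per-mutant read counts as a single multinomial sample of
#' `reads_per_sample` reads over the endpoint proportions — the counting noise
#' model of a pooled sequencing experiment.
#'
#' @inheritParams expected_proportions
#' @param design A `barseq_design`.
#' @param reads_per_sample Total sequencing depth for the sample.
#' @param d Pool doublings (default 5, the usual length of a competitive
#'   growth screen).
#' @param seed Integer seed; fixed seed gives identical counts.
#' @param sample_id Column name for the counts in the returned table.
#' @param initial_abundance Optional initial relative abundances.
#'
#' @return A tibble with columns `mutant_id` and `<sample_id>` (integer
#'   counts).
#' @export
simulate_counts <- function(design, fitness, condition, reads_per_sample,
                            d = 5, seed = 1, sample_id = condition,
                            initial_abundance = NULL) {
  stopifnot(inherits(design, "barseq_design"))
  if (reads_per_sample < 0) abort("`reads_per_sample` must be >= 0.")
  prob <- expected_proportions(fitness, d, condition, initial_abundance)
  counts <- if (reads_per_sample == 0) {
    rep(0L, length(prob))
  } else {
    with_seed(seed, as.integer(rmultinom(1, reads_per_sample, prob)))
  }
  out <- tibble(mutant_id = names(prob), count = counts)
  names(out)[2] <- sample_id
  out
}
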