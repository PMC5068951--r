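#' Stack scored screens into one long table
#'
#' @param screens A list of `gi_screen` objects (see [score_screen()]).
#' @return A long tibble with columns `screen_id`, `compound`, `mutant_id`,
#'   `gi`, `z`, `fdr`.
#' @export
bind_screens <- function(screens) {
  if (inherits(screens, "gi_screen")) screens <- list(screens)
  bind_rows(lapply(screens, function(s) {
    mutate(as_tibble(s),
           screen_id = attr(s, "screen_id"),
           compound = attr(s, "compound") %||% NA_character_,
           .before = 1)
  }))
}

#' Call treatment-sensitive mutants across replicate screens
#'
#' A mutant is a hit for a compound when it is significantly depleted —
#' FDR at or below `fdr_cutoff` **and** GI > 0 — in *every* screen of that
#' compound in which it was assayed (mutants missing from some screens are
#' judged on the screens where they are present, never imputed). Mutants
#' significant in at least one but not all screens are emitted as
#' rescreen candidates: too inconsistent for an automatic call, the set a
#' follow-up spot assay would re-test. Hits are graded into expressivity
#' classes from their mean GI via [classify_expressivity()].
#'
#' @param screens A list of `gi_screen` objects or a long tibble from
#'   [bind_screens()].
#' @param fdr_cutoff FDR threshold applied per screen (default 0.1).
#' @param expressivity_cutoffs Passed to [classify_expressivity()].
#' @return A `barseq_hits` tibble, one row per (compound, mutant):
#'   `compound`, `mutant_id`, `n_assayed`, `n_significant`, `mean_gi`,
#'   `status` (`"hit"`, `"rescreen"`, `"none"`), `expressivity` (hits only,
#'   else `"none"`).
#' @export
call_hits <- function(screens, fdr_cutoff = 0.1,
                      expressivity_cutoffs = c(low = 0.25, high = 0.6)) {
  long <- if (is.data.frame(screens)) screens else bind_screens(screens)
  if (nrow(long) == 0) abort("no screens supplied.")
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1) abort("`fdr_cutoff` must be in (0, 1).")
  out <- long |>
    filter(!is.na(.data$gi)) |>
    mutate(significant = .data$fdr <= fdr_cutoff & .data$gi > 0) |>
    group_by(.data$compound, .data$mutant_id) |>
    summarise(
      n_assayed = n(),
      n_significant = sum(.data$significant),
      mean_gi = mean(.data$gi),
      .groups = "drop"
    ) |>
    mutate(
      status = dplyr::case_when(
        .data$n_significant == .data$n_assayed & .data$n_significant > 0 ~ "hit",
        .data$n_significant > 0 ~ "rescreen",
        TRUE ~ "none"
      ),
      expressivity = ifelse(
        .data$status == "hit",
        as.character(classify_expressivity(.data$mean_gi, expressivity_cutoffs)),
        "none"
      )
    )
  structure(out, fdr_cutoff = fdr_cutoff,
            class = c("barseq_hits", class(out)))
}

#' Grade hit expressivity from mean GI score
#'
#' Sensitive mutants span a range from mild growth impairment to complete
#' growth failure. Expressivity is graded from the mean GI with two cutoffs:
#' `high` for mean GI >= `c_high`, `medium` for `c_low` <= GI < `c_high`,
#' `low` below. The defaults (0.25 / 0.6) split the range between unaffected
#' (GI ~ 0) and complete failure (GI ~ 1); they are configuration, not
#' biology.
#'
#' @param mean_gi Numeric vector of mean GI scores.
#' @param cutoffs Named numeric `c(low = ..., high = ...)` with
#'   `0 < low < high`.
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
classify_expressivity <- function(mean_gi, cutoffs = c(low = 0.25, high = 0.6)) {
  if (!all(c("low", "high") %in% names(cutoffs)) ||
      cutoffs[["low"]] <= 0 || cutoffs[["low"]] >= cutoffs[["high"]]) {
    abort("`cutoffs` must satisfy 0 < low < high.")
  }
  cls <- ifelse(mean_gi >= cutoffs[["high"]], "high",
                ifelse(mean_gi >= cutoffs[["low"]], "medium", "low"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Extract the hit gene list for one compound
#' @param hits A `barseq_hits` tibble.
#' @param compound Compound to extract (default: all compounds pooled).
#' @return Character vector of mutant ids with `status == "hit"`.
#' @export
hit_list <- function(hits, compound = NULL) {
  h <- hits[hits$status == "hit", ]
  if (!is.null(compound)) h <- h[h$compound == compound, ]
  unique(h$mutant_id)
}

#' @export
tidy.barseq_hits <- function(x, ...) as_tibble(x)

#' @export
glance.barseq_hits <- function(x, ...) {
  x |>
    group_by(.data$compound) |>
    summarise(n_hits = sum(.data$status == "hit"),
              n_rescreen = sum(.data$status == "rescreen"),
              n_assayed = n(),
              .groups = "drop") |>
    mutate(fdr_cutoff = attr(x, "fdr_cutoff"))
}
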