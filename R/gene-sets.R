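#' Construct a gene-set collection with an explicit background universe
#'
#' Enrichment statistics depend critically on the background ("universe") of
#' genes against which over-representation is judged. This constructor pairs a
#' named list of gene sets with a universe and drops set members that fall
#' outside it (with a message reporting how many were dropped).
#'
#' @param sets Named list of character vectors (term id -> gene ids).
#' @param universe Character vector of background gene ids.
#'
#' @return A `gene_set_collection`: list with `sets` (filtered, deduplicated)
#'   and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets) > 0 && is.null(names(sets))) abort("`sets` must be named.")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  dropped <- 0L
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s %in% universe
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0) {
    inform(sprintf("dropped %d set member(s) outside the universe.", dropped))
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Generate gene-set annotations with planted overlaps
#'
#' Builds a synthetic annotation collection for testing over-representation
#' arithmetic: each planted term has an exact, requested size `K` and overlap
#' `k` with a designated hit list; the remaining `K - k` members are drawn
#' uniformly from the universe outside the hit list.
#'
#' @param universe Character vector of background gene ids.
#' @param hit_list Character vector of "hit" gene ids (subset of universe).
#' @param planted Data frame with columns `term`, `K` (term size) and `k`
#'   (overlap with `hit_list`).
#' @param seed Integer seed.
#'
#' @return A `gene_set_collection` whose terms have exactly the requested
#'   (k, K) against `hit_list`.
#' @export
generate_annotations <- function(universe, hit_list, planted, seed = 1) {
  stopifnot(all(c("term", "K", "k") %in% names(planted)))
  if (!all(hit_list %in% universe)) abort("`hit_list` must be a subset of `universe`.")
  if (any(planted$k > planted$K)) abort("planted overlap k cannot exceed term size K.")
  if (any(planted$K > length(universe))) abort("term size K cannot exceed the universe.")
  if (any(planted$k > length(hit_list))) abort("planted overlap k cannot exceed the hit list.")
  non_hits <- setdiff(universe, hit_list)
  if (any(planted$K - planted$k > length(non_hits))) {
    abort("not enough non-hit genes in the universe to fill a planted term.")
  }
  sets <- with_seed(seed, {
    out <- pmap(planted, function(term, K, k, ...) {
      inside <- if (k > 0) sample(hit_list, k) else character()
      outside <- if (K - k > 0) sample(non_hits, K - k) else character()
      c(inside, outside)
    })
    setNames(out, planted$term)
  })
  gene_set_collection(sets, universe)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (term, description, members per line).
#' @param universe Background gene ids; defaults to the union of all set
#'   members.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write gene sets to a GMT file
#'
#' @param collection A `gene_set_collection` (or named list of gene sets).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
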