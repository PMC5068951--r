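# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package route through this so that
# a fixed seed gives byte-identical outputs.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific seed from a base seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483587L
}

random_dna <- function(n, length) {
  matrix(sample(DNA_ALPHABET, n * length, replace = TRUE), nrow = n)
}

collapse_dna <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Column-wise Hamming distances between one sequence and a character matrix
# (rows = sequences, columns = positions).
hamming_to_matrix <- function(seq_chars, mat) {
  rowSums(mat != matrix(seq_chars, nrow = nrow(mat), ncol = length(seq_chars),
                        byrow = TRUE))
}

seq_to_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), nrow = 0))
  t(vapply(strsplit(seqs, ""), identity, character(nchar(seqs[[1]]))))
}

assert_count_table <- function(counts) {
  if (!is.data.frame(counts) || !"mutant_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `mutant_id` column.")
  }
  num <- setdiff(names(counts), "mutant_id")
  if (length(num) == 0L) abort("`counts` has no sample columns.")
  invisible(num)
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
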