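#' Write simulated Bar-seq reads to FASTQ
#'
#' Emits one read per counted barcode occurrence. Each read is laid out as
#' sample index + constant spacer + barcode, padded with `A` to `read_length`
#' (42 nt by default, one single-end sequencing run). Substitution errors are
#' applied i.i.d. per base at `error_rate`. Reads for all samples assigned to
#' the same FASTQ file are interleaved by sample in deterministic order, so a
#' fixed seed reproduces the files byte for byte.
#'
#' @param counts Count table: tibble with `mutant_id` plus one integer column
#'   per `sample_id` present in `sample_sheet`.
#' @param design A `barseq_design` (provides barcodes and layout).
#' @param sample_sheet Tibble with columns `sample_id`, `file`, `index_seq`,
#'   `tag_class` (`"up"` or `"dn"`), and optionally `condition`, `batch`.
#' @param out_dir Output directory (created if needed).
#' @param error_rate Per-base substitution probability in [0, 0.1].
#' @param read_length Total read length after padding.
#' @param seed Integer seed for the error process.
#' @param gzip Write `.gz`-compressed FASTQ.
#'
#' @return Invisibly, the manifest: a list with the files written, the layout,
#'   the seed and the error rate. The manifest is also written as
#'   `manifest.json` in `out_dir`.
#' @export
write_reads <- function(counts, design, sample_sheet, out_dir,
                        error_rate = 0, read_length = 42, seed = 1,
                        gzip = FALSE) {
  stopifnot(inherits(design, "barseq_design"))
  assert_count_table(counts)
  validate_sample_sheet(sample_sheet)
  if (error_rate < 0 || error_rate > 0.1) abort("`error_rate` must be in [0, 0.1].")
  missing_cols <- setdiff(sample_sheet$sample_id, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("counts lack columns for samples: ", paste(missing_cols, collapse = ", ")))
  }
  layout <- design$layout
  min_len <- max(nchar(sample_sheet$index_seq)) + nchar(layout$spacer) +
    layout$barcode_length
  if (read_length < min_len) {
    abort(sprintf("`read_length` (%d) shorter than index+spacer+barcode (%d).",
                  read_length, min_len))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- unique(sample_sheet$file)
  written <- character()
  for (fi in seq_along(files)) {
    f <- files[[fi]]
    sheet_f <- sample_sheet[sample_sheet$file == f, ]
    reads <- unlist(lapply(seq_len(nrow(sheet_f)), function(i) {
      row <- sheet_f[i, ]
      bc <- if (row$tag_class == "up") design$catalog$uptag else design$catalog$dntag
      reps <- counts[[row$sample_id]][match(design$catalog$mutant_id, counts$mutant_id)]
      reps[is.na(reps)] <- 0L
      if (sum(reps) == 0) return(character())
      body <- paste0(row$index_seq, layout$spacer, rep(bc, times = reps))
      paste0(body, strrep("A", read_length - nchar(body)))
    }))
    if (error_rate > 0 && length(reads) > 0) {
      reads <- with_seed(derive_seed(seed, fi), apply_substitutions(reads, error_rate))
    }
    path <- file.path(out_dir, if (gzip) paste0(f, ".gz") else f)
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    if (length(reads) > 0) {
      fastq <- as.vector(rbind(
        paste0("@read", seq_along(reads)),
        reads,
        "+",
        strrep("I", read_length)
      ))
    } else {
      fastq <- character()
    }
    writeLines(fastq, con)
    close(con)
    written <- c(written, path)
  }

  manifest <- list(
    files = written,
    n_samples = nrow(sample_sheet),
    layout = list(spacer = layout$spacer,
                  barcode_length = layout$barcode_length,
                  read_length = as.integer(read_length)),
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# i.i.d. per-base substitutions: each erroneous base is replaced by one of the
# three other letters uniformly.
apply_substitutions <- function(reads, error_rate) {
  mat <- seq_to_char_matrix(reads)
  hit <- which(runif(length(mat)) < error_rate)
  if (length(hit) > 0) {
    # shift by 1..3 letters within the alphabet so the base always changes
    cur <- match(mat[hit], DNA_ALPHABET)
    mat[hit] <- DNA_ALPHABET[((cur - 1L + sample.int(3, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  collapse_dna(mat)
}

validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "file", "index_seq", "tag_class")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample_id in sample sheet.")
  if (!all(sheet$tag_class %in% c("up", "dn"))) {
    abort("`tag_class` must be 'up' or 'dn'.")
  }
  # Within one FASTQ file indices must be unique and prefix-free, otherwise
  # demultiplexing would be ambiguous.
  for (f in unique(sheet$file)) {
    idx <- toupper(sheet$index_seq[sheet$file == f])
    if (anyDuplicated(idx)) {
      abort(sprintf("samples in file '%s' share an index sequence.", f))
    }
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (i != j && startsWith(idx[j], idx[i])) {
          abort(sprintf("index '%s' is a prefix of '%s' in file '%s'.",
                        idx[i], idx[j], f))
        }
      }
    }
  }
  invisible(sheet)
}
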