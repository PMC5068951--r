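#' Assign a read to a sample by its index prefix
#'
#' Sample indices (3–4 nt) are matched exactly and case-insensitively against
#' the read prefix; no mismatch is tolerated because indices are too short to
#' distinguish a sequencing error from a different sample. Index sets within a
#' file must be prefix-free (validated when the sheet is loaded).
#'
#' @param read Read sequence (character scalar).
#' @param sample_sheet Sample sheet tibble (see [write_reads()]), restricted
#'   to the file the read came from.
#' @return The matching `sample_id`, or `NA_character_` if unassigned.
#' @export
demultiplex_read <- function(read, sample_sheet) {
  read <- toupper(read)
  idx <- toupper(sample_sheet$index_seq)
  hit <- which(startsWith(read, idx))
  if (length(hit) == 1L) sample_sheet$sample_id[hit] else NA_character_
}

#' Match a barcode sequence against a catalog
#'
#' Finds the unique catalog barcode within Hamming distance `max_mismatch`.
#' Two or more catalog entries at the minimal distance make the read
#' `"ambiguous"` — it is never assigned arbitrarily. A length mismatch makes
#' the read `"unassigned"` (a QC condition, not an error).
#'
#' @param barcode_seq Barcode sequence extracted from the read.
#' @param design A `barseq_design` (or its catalog tibble).
#' @param tag_class `"up"` or `"dn"`.
#' @param max_mismatch 0 or 1 tolerated substitutions.
#' @return A list with `status` (`"assigned"`, `"unassigned"`, `"ambiguous"`)
#'   and `mutant_id` (`NA` unless assigned).
#' @export
match_barcode <- function(barcode_seq, design, tag_class = c("up", "dn"),
                          max_mismatch = 1) {
  tag_class <- match.arg(tag_class)
  if (!max_mismatch %in% c(0, 1)) abort("`max_mismatch` must be 0 or 1.")
  catalog <- if (inherits(design, "barseq_design")) design$catalog else design
  bcs <- if (tag_class == "up") catalog$uptag else catalog$dntag
  barcode_seq <- toupper(barcode_seq)
  if (nchar(barcode_seq) != nchar(bcs[[1]])) {
    return(list(status = "unassigned", mutant_id = NA_character_))
  }
  d <- hamming_to_matrix(strsplit(barcode_seq, "")[[1]], seq_to_char_matrix(bcs))
  dmin <- min(d)
  if (dmin > max_mismatch) {
    return(list(status = "unassigned", mutant_id = NA_character_))
  }
  at_min <- which(d == dmin)
  if (length(at_min) > 1L) {
    return(list(status = "ambiguous", mutant_id = NA_character_))
  }
  list(status = "assigned", mutant_id = catalog$mutant_id[at_min])
}

#' Count barcodes from indexed FASTQ files
#'
#' Streams each FASTQ file in chunks, demultiplexes reads by exact index
#' prefix, extracts the barcode at the layout's fixed offset and matches it
#' against the catalog with `max_mismatch` tolerance (ambiguous matches are
#' rejected, see [match_barcode()]). Row order follows the catalog, column
#' order the sample sheet. Reads too short to contain a full barcode are
#' counted as unassigned-barcode.
#'
#' @param fastq_files Character vector of FASTQ(.gz) paths. Basenames (with
#'   any `.gz` suffix removed) are matched against the sheet's `file` column.
#' @param design A `barseq_design` providing the catalog and read layout.
#' @param sample_sheet Sample sheet tibble.
#' @param max_mismatch Barcode mismatch tolerance, 0 or 1 (default 1).
#' @param chunk_size Reads processed per chunk (memory bound).
#'
#' @return A `barseq_counts` object: tibble with `mutant_id` and one integer
#'   column per sample, with a per-file QC table in `attr(, "qc")`
#'   (`total = assigned + unassigned_index + unassigned_barcode + ambiguous`).
#' @export
count_barcodes <- function(fastq_files, design, sample_sheet,
                           max_mismatch = 1, chunk_size = 100000L) {
  stopifnot(inherits(design, "barseq_design"))
  validate_sample_sheet(sample_sheet)
  if (nrow(design$catalog) == 0) abort("empty barcode catalog.")
  if (!max_mismatch %in% c(0, 1)) abort("`max_mismatch` must be 0 or 1.")

  layout <- design$layout
  lut <- build_barcode_lookup(design, max_mismatch)
  counts <- matrix(0L, nrow = nrow(design$catalog), ncol = nrow(sample_sheet),
                   dimnames = list(design$catalog$mutant_id, sample_sheet$sample_id))
  qc <- list()

  for (path in fastq_files) {
    fname <- sub("\\.gz$", "", basename(path))
    sheet_f <- sample_sheet[sample_sheet$file == fname, ]
    if (nrow(sheet_f) == 0) {
      abort(sprintf("no samples in the sheet for FASTQ file '%s'.", fname))
    }
    qc_f <- c(total = 0L, assigned = 0L, unassigned_index = 0L,
              unassigned_barcode = 0L, ambiguous = 0L)
    skip <- 0L
    repeat {
      reads <- tryCatch(
        as.character(Biostrings::readDNAStringSet(path, format = "fastq",
                                                  nrec = chunk_size, skip = skip)),
        error = function(e) {
          abort(sprintf("failed reading FASTQ '%s' at record %d: %s",
                        path, skip + 1L, conditionMessage(e)))
        }
      )
      if (length(reads) == 0L) break
      res <- count_chunk(reads, sheet_f, lut, layout, max_mismatch)
      qc_f <- qc_f + res$qc
      if (nrow(res$tallies) > 0) {
        ij <- cbind(res$tallies$row,
                    match(res$tallies$sample_id, colnames(counts)))
        counts[ij] <- counts[ij] + res$tallies$n
      }
      skip <- skip + length(reads)
      if (length(reads) < chunk_size) break
    }
    inform(sprintf("%s: %d reads, %d assigned, %d unassigned-index, %d unassigned-barcode, %d ambiguous",
                   fname, qc_f["total"], qc_f["assigned"], qc_f["unassigned_index"],
                   qc_f["unassigned_barcode"], qc_f["ambiguous"]))
    qc[[fname]] <- tibble(file = fname, !!!as.list(qc_f))
  }

  out <- bind_cols(tibble(mutant_id = design$catalog$mutant_id),
                   as_tibble(counts))
  structure(out, qc = bind_rows(qc), class = c("barseq_counts", class(out)))
}

# Hash-based matcher: maps every catalog barcode (and, at max_mismatch = 1,
# each of its 3L single-substitution neighbours) to a catalog row. Neighbour
# collisions between different mutants are marked ambiguous up front, which
# reproduces the minimum-distance tie rule for distance-3-separated catalogs;
# exact hits always take precedence over 1-mismatch hits.
build_barcode_lookup <- function(design, max_mismatch) {
  catalog <- design$catalog
  mk <- function(bcs) {
    bcs <- toupper(bcs)
    exact <- setNames(seq_along(bcs), bcs)
    if (anyDuplicated(names(exact))) abort("duplicate barcodes in catalog.")
    neigh <- integer()
    if (max_mismatch >= 1) {
      L <- nchar(bcs[[1]])
      mat <- seq_to_char_matrix(bcs)
      keys <- character(0); vals <- integer(0)
      for (pos in seq_len(L)) {
        for (b in DNA_ALPHABET) {
          m2 <- mat
          changed <- m2[, pos] != b
          m2[, pos] <- b
          s <- collapse_dna(m2)
          keys <- c(keys, s[changed])
          vals <- c(vals, which(changed))
        }
      }
      # a neighbour key shared by two mutants is an ambiguous 1-mismatch hit
      dup <- keys %in% keys[duplicated(keys)]
      amb_keys <- unique(keys[dup])
      keep <- !dup & !(keys %in% names(exact))
      neigh <- setNames(vals[keep], keys[keep])
      attr(neigh, "ambiguous") <- setdiff(amb_keys, names(exact))
    }
    list(exact = exact, neigh = neigh)
  }
  list(up = mk(catalog$uptag), dn = mk(catalog$dntag),
       barcode_length = design$layout$barcode_length)
}

count_chunk <- function(reads, sheet_f, lut, layout, max_mismatch) {
  reads <- toupper(reads)
  n <- length(reads)
  qc <- c(total = n, assigned = 0L, unassigned_index = 0L,
          unassigned_barcode = 0L, ambiguous = 0L)

  # vectorised demultiplexing over the (few) samples in this file
  sample_of <- rep(NA_integer_, n)
  for (i in seq_len(nrow(sheet_f))) {
    hit <- startsWith(reads, toupper(sheet_f$index_seq[i]))
    sample_of[hit] <- i
  }
  qc["unassigned_index"] <- sum(is.na(sample_of))

  tallies <- list()
  for (i in seq_len(nrow(sheet_f))) {
    sel <- which(sample_of == i)
    if (length(sel) == 0) next
    off <- nchar(sheet_f$index_seq[i]) + nchar(layout$spacer)
    bc <- substr(reads[sel], off + 1L, off + lut$barcode_length)
    tab <- if (sheet_f$tag_class[i] == "up") lut$up else lut$dn
    too_short <- nchar(bc) < lut$barcode_length
    row <- unname(tab$exact[bc])
    if (max_mismatch >= 1) {
      miss <- is.na(row) & !too_short
      row[miss] <- unname(tab$neigh[bc[miss]])
      amb <- is.na(row) & !too_short & bc %in% attr(tab$neigh, "ambiguous")
    } else {
      amb <- rep(FALSE, length(bc))
    }
    assigned <- !is.na(row)
    qc["assigned"] <- qc["assigned"] + sum(assigned)
    qc["ambiguous"] <- qc["ambiguous"] + sum(amb)
    qc["unassigned_barcode"] <- qc["unassigned_barcode"] +
      sum(!assigned & !amb)
    if (any(assigned)) {
      tt <- table(row[assigned])
      tallies[[length(tallies) + 1L]] <- tibble(
        row = as.integer(names(tt)),
        sample_id = sheet_f$sample_id[i],
        n = as.integer(tt)
      )
    }
  }
  if (length(tallies) > 0) {
    tal <- bind_rows(tallies)
  } else {
    tal <- tibble(row = integer(), sample_id = character(), n = integer())
  }
  list(qc = qc, tallies = tal)
}

#' Sum uptag and dntag counts per pooled sample
#'
#' Each biological pool is sequenced twice (uptag and dntag). By default the
#' two tag counts are summed into one column per pool, maximising depth;
#' alternatively keep only one tag class, or leave them separate.
#'
#' @param counts A count table from [count_barcodes()].
#' @param sample_sheet Sample sheet with a `pool_id` column grouping the tag
#'   samples of one biological pool.
#' @param how `"sum"` (default), `"uptag"`, `"dntag"`, or `"separate"`.
#' @return A tibble with `mutant_id` and one column per `pool_id` (or the
#'   input unchanged for `"separate"`).
#' @export
combine_tags <- function(counts, sample_sheet,
                         how = c("sum", "uptag", "dntag", "separate")) {
  how <- match.arg(how)
  if (how == "separate") return(counts)
  if (!"pool_id" %in% names(sample_sheet)) {
    abort("`sample_sheet` needs a `pool_id` column to combine tags.")
  }
  keep <- switch(how,
    sum = sample_sheet,
    uptag = sample_sheet[sample_sheet$tag_class == "up", ],
    dntag = sample_sheet[sample_sheet$tag_class == "dn", ]
  )
  out <- tibble(mutant_id = counts$mutant_id)
  for (pool in unique(keep$pool_id)) {
    cols <- keep$sample_id[keep$pool_id == pool]
    cols <- intersect(cols, names(counts))
    if (length(cols) == 0) next
    out[[pool]] <- as.integer(rowSums(as.matrix(counts[cols])))
  }
  out
}

#' Read a barcode catalog TSV
#'
#' @param path TSV with columns `mutant_id`, `uptag`, `dntag`.
#' @param spacer,barcode_length Read-layout parameters to attach.
#' @return A `barseq_design`.
#' @export
read_catalog <- function(path, spacer = "CGCTA", barcode_length = NULL) {
  catalog <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("mutant_id", "uptag", "dntag")
  if (!all(req %in% names(catalog))) {
    abort("catalog must have columns mutant_id, uptag, dntag.")
  }
  structure(
    list(catalog = as_tibble(catalog[req]),
         layout = list(
           spacer = spacer,
           barcode_length = as.integer(barcode_length %||% nchar(catalog$uptag[[1]]))
         )),
    class = "barseq_design"
  )
}

#' Write a barcode catalog TSV
#' @param design A `barseq_design`.
#' @param path Output path.
#' @export
write_catalog <- function(design, path) {
  write_tsv_file(design$catalog, path)
}

#' Read a sample sheet TSV
#' @param path TSV with columns `sample_id`, `file`, `index_seq`, `tag_class`
#'   and optionally `pool_id`, `condition`, `batch`.
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' @export
tidy.barseq_counts <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"mutant_id",
                      names_to = "sample_id", values_to = "count")
}

#' @export
glance.barseq_counts <- function(x, ...) {
  qc <- attr(x, "qc")
  tibble(
    n_mutants = nrow(x),
    n_samples = ncol(x) - 1L,
    total_reads = sum(qc$total),
    assigned = sum(qc$assigned),
    assigned_frac = sum(qc$assigned) / max(1, sum(qc$total))
  )
}
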