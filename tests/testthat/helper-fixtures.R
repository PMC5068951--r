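# Shared fixture builders. Everything is generated in code at test time.

# Four prefix-free 4-nt indices used throughout.
test_indices <- c("CGAT", "TATA", "GCCA", "ATTG")

# A one-file sample sheet with control/treatment pools, both tags each.
make_sheet <- function(file = "s1.fastq") {
  tibble::tibble(
    sample_id = c("c_up", "c_dn", "t_up", "t_dn"),
    file = file,
    index_seq = test_indices,
    tag_class = c("up", "dn", "up", "dn"),
    pool_id = c("ctrl", "ctrl", "trt", "trt"),
    condition = c("control", "control", "treatment", "treatment")
  )
}

# Simulate a 4-sample count table (ctrl/trt x up/dn) for a design + fitness.
make_counts <- function(design, fitness, depth, d = 5, seed = 1) {
  sheet <- make_sheet()
  cts <- tibble::tibble(mutant_id = design$catalog$mutant_id)
  for (i in seq_len(nrow(sheet))) {
    cond <- sheet$condition[i]
    sim <- simulate_counts(design, fitness, cond, depth, d = d,
                           seed = seed * 10 + i, sample_id = sheet$sample_id[i])
    cts[[sheet$sample_id[i]]] <- sim[[2]]
  }
  cts
}

# Quadratic brute-force counting oracle: scans every (read, catalog barcode)
# pair with an explicit Hamming loop. Independent of the package's hash-based
# matcher; used only on small inputs.
oracle_count <- function(reads, design, sheet, max_mismatch = 1) {
  catalog <- design$catalog
  spacer_len <- nchar(design$layout$spacer)
  bl <- design$layout$barcode_length
  counts <- matrix(0L, nrow(catalog), nrow(sheet),
                   dimnames = list(catalog$mutant_id, sheet$sample_id))
  qc <- c(total = length(reads), assigned = 0L, unassigned_index = 0L,
          unassigned_barcode = 0L, ambiguous = 0L)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (r in reads) {
    r <- toupper(r)
    samp <- which(vapply(sheet$index_seq,
                         function(ix) startsWith(r, toupper(ix)), logical(1)))
    if (length(samp) != 1L) {
      qc["unassigned_index"] <- qc["unassigned_index"] + 1L
      next
    }
    off <- nchar(sheet$index_seq[samp]) + spacer_len
    bc <- substr(r, off + 1L, off + bl)
    if (nchar(bc) < bl) {
      qc["unassigned_barcode"] <- qc["unassigned_barcode"] + 1L
      next
    }
    bcs <- if (sheet$tag_class[samp] == "up") catalog$uptag else catalog$dntag
    dd <- vapply(bcs, function(b) ham(bc, b), numeric(1))
    dmin <- min(dd)
    if (dmin > max_mismatch) {
      qc["unassigned_barcode"] <- qc["unassigned_barcode"] + 1L
    } else if (sum(dd == dmin) > 1L) {
      qc["ambiguous"] <- qc["ambiguous"] + 1L
    } else {
      counts[which.min(dd), samp] <- counts[which.min(dd), samp] + 1L
      qc["assigned"] <- qc["assigned"] + 1L
    }
  }
  list(counts = counts, qc = qc)
}

# Write raw read sequences as a plain FASTQ file; returns the path.
write_raw_fastq <- function(reads, dir, file = "s1.fastq") {
  path <- file.path(dir, file)
  if (length(reads) > 0) {
    writeLines(as.vector(rbind(
      paste0("@r", seq_along(reads)), reads, "+",
      vapply(reads, function(r) strrep("I", nchar(r)), character(1))
    )), path)
  } else {
    writeLines(character(), path)
  }
  path
}

count_values <- function(counts) {
  unname(as.matrix(counts[setdiff(names(counts), "mutant_id")]))
}
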