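# Demultiplexing, barcode matching and FASTQ counting.

test_that("index demultiplexing is exact, case-insensitive and zero-tolerance", {
  sheet <- tibble::tibble(sample_id = "S1", file = "f", index_seq = "CGAT",
                          tag_class = "up")
  expect_identical(demultiplex_read("CGATTTACGGA", sheet), "S1")
  expect_identical(demultiplex_read("cgatTTACGGA", sheet), "S1")
  expect_identical(demultiplex_read("NNNNTTACGGA", sheet), NA_character_)
  # one mismatch in the index is enough to discard the read
  expect_identical(demultiplex_read("CGAATTACGGA", sheet), NA_character_)
})

test_that("barcode matching resolves exact, 1-mismatch and ambiguous cases", {
  d <- generate_library(30, seed = 4)
  bc <- d$catalog$uptag[7]
  expect_identical(match_barcode(bc, d, "up")$mutant_id, d$catalog$mutant_id[7])

  mutated <- bc
  substr(mutated, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(bc, 3, 3))[1]
  # brute-force scan confirms the mutated sequence is uniquely closest to entry 7
  dists <- vapply(d$catalog$uptag, function(b)
    sum(strsplit(mutated, "")[[1]] != strsplit(b, "")[[1]]), numeric(1))
  expect_identical(sum(dists <= 1), 1L)
  expect_identical(match_barcode(mutated, d, "up", max_mismatch = 1)$mutant_id,
                   d$catalog$mutant_id[7])
  expect_identical(match_barcode(mutated, d, "up", max_mismatch = 0)$status,
                   "unassigned")

  # a sequence equidistant from two catalog entries is ambiguous, never assigned
  cat2 <- tibble::tibble(mutant_id = c("m1", "m2"),
                         uptag = c("AAAA", "AATT"), dntag = c("CCCC", "GGGG"))
  res <- match_barcode("AAAT", cat2, "up", max_mismatch = 1)
  expect_identical(res$status, "ambiguous")
  expect_true(is.na(res$mutant_id))

  # length mismatch is a QC condition, not an exception
  expect_identical(match_barcode(substr(bc, 1, 10), d, "up")$status, "unassigned")
})

test_that("count_barcodes matches the quadratic brute-force oracle", {
  d <- generate_library(25, seed = 8)
  sheet <- make_sheet()
  spacer <- d$layout$spacer
  mutate1 <- function(s, pos) {
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), substr(s, pos, pos))[1]
    s
  }
  reads <- c(
    paste0("CGAT", spacer, d$catalog$uptag[1]),             # exact, c_up
    paste0("CGAT", spacer, mutate1(d$catalog$uptag[2], 5)), # 1-mismatch, c_up
    paste0("TATA", spacer, d$catalog$dntag[3]),             # exact dntag, c_dn
    paste0("GGGG", spacer, d$catalog$uptag[1]),             # unknown index
    paste0("ATTG", spacer, strrep("N", 20)),                # unmatchable barcode
    paste0("GCCA", spacer, substr(d$catalog$uptag[4], 1, 8)) # too short
  )
  dir <- withr::local_tempdir()
  path <- write_raw_fastq(reads, dir)
  got <- suppressMessages(count_barcodes(path, d, sheet))
  oracle <- oracle_count(reads, d, sheet)
  expect_identical(count_values(got), unname(oracle$counts))
  qc <- attr(got, "qc")
  expect_identical(
    as.integer(qc[1, c("total", "assigned", "unassigned_index",
                       "unassigned_barcode", "ambiguous")]),
    as.integer(oracle$qc)
  )
})

test_that("count_barcodes equals the oracle on 1000 random reads", {
  d <- generate_library(50, seed = 15)
  sheet <- make_sheet()
  spacer <- d$layout$spacer
  reads <- withr::with_seed(99, {
    n <- 1000
    idx <- sample(c(test_indices, "GGGG"), n, replace = TRUE,
                  prob = c(rep(0.23, 4), 0.08))
    tag <- ifelse(idx %in% test_indices[c(1, 3)], "uptag", "dntag")
    bc <- vapply(seq_len(n), function(i) {
      b <- sample(d$catalog[[tag[i]]], 1)
      nerr <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
      for (p in sample(20, nerr)) {
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      b
    }, character(1))
    paste0(idx, spacer, bc)
  })
  dir <- withr::local_tempdir()
  path <- write_raw_fastq(reads, dir)
  for (mm in c(0, 1)) {
    got <- suppressMessages(count_barcodes(path, d, sheet, max_mismatch = mm))
    oracle <- oracle_count(reads, d, sheet, max_mismatch = mm)
    expect_identical(count_values(got), unname(oracle$counts))
    expect_identical(
      as.integer(attr(got, "qc")[1, c("total", "assigned", "unassigned_index",
                                      "unassigned_barcode", "ambiguous")]),
      as.integer(oracle$qc)
    )
  }
})

test_that("QC categories always sum to the total and respect monotonicity", {
  d <- generate_library(40, seed = 21)
  fit <- fitness_model(d, n_high = 4, seed = 21)
  cts <- make_counts(d, fit, 3000, seed = 21)
  dir <- withr::local_tempdir()
  write_reads(cts, d, make_sheet(), dir, error_rate = 0.02, seed = 3)
  path <- file.path(dir, "s1.fastq")
  qc <- list()
  for (mm in c(0, 1)) {
    got <- suppressMessages(count_barcodes(path, d, make_sheet(), max_mismatch = mm))
    q <- attr(got, "qc")
    expect_identical(q$total,
                     q$assigned + q$unassigned_index + q$unassigned_barcode + q$ambiguous)
    qc[[as.character(mm)]] <- q
  }
  # raising the mismatch tolerance never loses assigned reads
  expect_gte(qc[["1"]]$assigned, qc[["0"]]$assigned)
})

test_that("read order does not affect the count table", {
  d <- generate_library(20, seed = 31)
  fit <- fitness_model(d, n_high = 2, seed = 31)
  cts <- make_counts(d, fit, 500, seed = 31)
  dir <- withr::local_tempdir()
  write_reads(cts, d, make_sheet(), dir, error_rate = 0.01, seed = 8)
  lines <- readLines(file.path(dir, "s1.fastq"))
  recs <- matrix(lines, nrow = 4)
  shuffled <- recs[, withr::with_seed(1, sample(ncol(recs)))]
  writeLines(as.vector(shuffled), file.path(dir, "s2.fastq"))
  sheet1 <- make_sheet("s1.fastq")
  sheet2 <- make_sheet("s2.fastq")
  a <- suppressMessages(count_barcodes(file.path(dir, "s1.fastq"), d, sheet1))
  b <- suppressMessages(count_barcodes(file.path(dir, "s2.fastq"), d, sheet2))
  expect_identical(count_values(a), count_values(b))
})

test_that("empty FASTQ gives an all-zero table with zero QC totals", {
  d <- generate_library(10, seed = 2)
  dir <- withr::local_tempdir()
  path <- write_raw_fastq(character(), dir)
  got <- suppressMessages(count_barcodes(path, d, make_sheet()))
  expect_true(all(count_values(got) == 0))
  expect_identical(sum(attr(got, "qc")$total), 0L)
})

test_that("error-free reads round-trip exactly; noisy reads nearly", {
  d <- generate_library(60, seed = 41)
  fit <- fitness_model(d, n_high = 6, seed = 41)
  sheet <- make_sheet()
  for (s in c(1, 23)) { # exact round trip holds for any seed
    cts <- make_counts(d, fit, 5000, seed = s)
    dir <- withr::local_tempdir()
    write_reads(cts, d, sheet, dir, error_rate = 0, seed = s, gzip = TRUE)
    got <- suppressMessages(count_barcodes(file.path(dir, "s1.fastq.gz"), d, sheet))
    expect_identical(count_values(got), count_values(cts))
  }
  # at error rate 0.005 only reads with >= 2 barcode errors are lost:
  # P(>=2 errors in 20 nt) ~ 0.45%, so >= 99% of demultiplexed reads assign
  # and per-mutant relative abundances agree within 2%
  neutral <- fitness_model(d, seed = 41) # uniform pool: every mutant well covered
  cts <- make_counts(d, neutral, 100000, seed = 7)
  dir <- withr::local_tempdir()
  write_reads(cts, d, sheet, dir, error_rate = 0.005, seed = 7)
  got <- suppressMessages(count_barcodes(file.path(dir, "s1.fastq"), d, sheet))
  qc <- attr(got, "qc")
  expect_gte(qc$assigned / (qc$total - qc$unassigned_index), 0.99)
  for (col in c("c_up", "t_dn")) {
    p_in <- cts[[col]] / sum(cts[[col]])
    p_out <- got[[col]] / sum(got[[col]])
    big <- p_in > 20 / sum(cts[[col]]) # compare mutants with real coverage
    expect_lt(max(abs(p_out[big] / p_in[big] - 1)), 0.02)
  }
})

test_that("tag combination modes behave as documented", {
  counts <- tibble::tibble(mutant_id = c("m1", "m2"),
                           c_up = c(3L, 0L), c_dn = c(2L, 5L),
                           t_up = c(1L, 1L), t_dn = c(0L, 2L))
  sheet <- make_sheet()
  summed <- combine_tags(counts, sheet, "sum")
  expect_identical(summed$ctrl, c(5L, 5L))
  expect_identical(summed$trt, c(1L, 3L))
  expect_identical(combine_tags(counts, sheet, "uptag")$ctrl, counts$c_up)
  expect_identical(combine_tags(counts, sheet, "dntag")$trt, counts$t_dn)
  expect_identical(combine_tags(counts, sheet, "separate"), counts)
})

test_that("counting fails fast on an empty catalog", {
  d <- generate_library(5, seed = 1)
  d$catalog <- d$catalog[0, ]
  expect_error(count_barcodes("whatever.fastq", d, make_sheet()), "empty")
})
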