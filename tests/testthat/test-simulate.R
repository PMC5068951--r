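# Synthetic-data generator: library design, pooled growth, reads, annotations.

test_that("generated libraries satisfy the barcode invariants and are deterministic", {
  d <- generate_library(2, barcode_length = 20, seed = 1)
  bcs <- c(d$catalog$uptag, d$catalog$dntag)
  expect_length(unique(bcs), 4)
  expect_true(all(grepl("^[ACGT]{20}$", bcs)))
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_gte(ham(d$catalog$uptag[1], d$catalog$uptag[2]), 3)
  expect_gte(ham(d$catalog$dntag[1], d$catalog$dntag[2]), 3)

  d1 <- generate_library(200, seed = 7)
  d2 <- generate_library(200, seed = 7)
  expect_identical(d1$catalog, d2$catalog)
  expect_false(identical(d1$catalog, generate_library(200, seed = 8)$catalog))
})

test_that("pairwise same-class Hamming distance >= 3 holds at scale", {
  d <- generate_library(150, barcode_length = 20, seed = 11)
  for (tag in c("uptag", "dntag")) {
    mat <- t(vapply(strsplit(d$catalog[[tag]], ""), identity, character(20)))
    m <- matrix(0, 150, 150)
    for (b in c("A", "C", "G", "T")) m <- m + tcrossprod((mat == b) * 1)
    dist <- 20 - m
    diag(dist) <- Inf
    expect_gte(min(dist), 3)
  }
})

test_that("an impossible distance-3 code errors out", {
  # at length 2 the maximum possible Hamming distance is 2
  expect_error(generate_library(2, barcode_length = 2, seed = 1),
               "Hamming distance")
})

test_that("neutral fitness gives uniform expected counts (chi-square not rejected)", {
  d <- generate_library(40, seed = 2)
  fit <- fitness_model(d, seed = 2) # all f = 1
  pvals <- vapply(1:20, function(s) {
    cts <- simulate_counts(d, fit, "control", 20000, seed = s)
    stats::chisq.test(cts[[2]])$p.value
  }, numeric(1))
  # under the null each seed is uniform; alpha 0.01 per draw
  expect_gte(min(pvals), 1e-4)
  expect_gt(sum(pvals > 0.01), 17)
})

test_that("a fully sensitive mutant is depleted 2^d-fold in expectation", {
  d <- generate_library(500, seed = 3)
  fit <- fitness_model(d, seed = 3)
  dead <- fit$mutant_id[42]
  fit$f[42] <- 0
  pc <- expected_proportions(fit, d = 5, "control")
  pt <- expected_proportions(fit, d = 5, "treatment")
  # normalized share ratio = 2^-5 up to the pool renormalisation (~0.2% here)
  expect_equal(unname(pt[dead] / pc[dead]), 2^-5, tolerance = 0.005)
  # and the sampled counts agree within sampling error at high depth
  cc <- simulate_counts(d, fit, "control", 1e6, seed = 4)
  ct <- simulate_counts(d, fit, "treatment", 1e6, seed = 5)
  ratio <- (ct[[2]][42] / sum(ct[[2]])) / (cc[[2]][42] / sum(cc[[2]]))
  expect_equal(ratio, unname(pt[dead] / pc[dead]), tolerance = 0.15)
})

test_that("zero sequencing depth yields an all-zero table", {
  d <- generate_library(10, seed = 1)
  fit <- fitness_model(d)
  cts <- simulate_counts(d, fit, "control", 0, seed = 1)
  expect_true(all(cts[[2]] == 0))
})

test_that("count noise across seeds is multinomial", {
  d <- generate_library(20, seed = 6)
  fit <- fitness_model(d, n_high = 3, seed = 6)
  depth <- 2000
  draws <- vapply(1:200, function(s) {
    simulate_counts(d, fit, "treatment", depth, seed = s)[[2]]
  }, numeric(20))
  p <- expected_proportions(fit, 5, "treatment")
  expected_var <- depth * p * (1 - p)
  obs_var <- apply(draws, 1, stats::var)
  # sampling SE of a variance estimate over 200 draws
  se <- expected_var * sqrt(2 / 199)
  within3 <- abs(obs_var - expected_var) <= 3 * se
  expect_gte(sum(within3), 18) # allow the occasional 3-SE excursion
  expect_equal(mean(obs_var / expected_var), 1, tolerance = 0.1)
})

test_that("fixed seed reproduces FASTQ output byte for byte", {
  d <- generate_library(30, seed = 9)
  fit <- fitness_model(d, n_high = 3, seed = 9)
  cts <- make_counts(d, fit, 2000, seed = 9)
  sheet <- make_sheet()
  root <- withr::local_tempdir()
  md5 <- vapply(c("a", "b"), function(sub) {
    out <- file.path(root, sub)
    write_reads(cts, d, sheet, out, error_rate = 0.01, seed = 77)
    unname(tools::md5sum(file.path(out, "s1.fastq")))
  }, character(1))
  expect_identical(md5[["a"]], md5[["b"]])
})

test_that("write_reads produces 4-line FASTQ records with the declared layout", {
  d <- generate_library(3, seed = 5)
  fit <- fitness_model(d)
  sheet <- make_sheet()
  cts <- tibble::tibble(mutant_id = d$catalog$mutant_id,
                        c_up = c(2L, 1L, 0L), c_dn = 0L, t_up = 0L,
                        t_dn = c(1L, 1L, 1L))
  out <- withr::local_tempdir()
  write_reads(cts, d, sheet, out, error_rate = 0, seed = 1)
  lines <- readLines(file.path(out, "s1.fastq"))
  expect_length(lines, 4 * 6) # 6 reads, 4 lines each
  seqs <- lines[seq(2, length(lines), by = 4)]
  expect_true(all(nchar(seqs) == 42))
  expect_true(all(startsWith(lines[seq(1, length(lines), by = 4)], "@")))
  # the first read carries sample c_up's index, the spacer, mutant 1's uptag
  expect_identical(substr(seqs[1], 1, 4), "CGAT")
  expect_identical(substr(seqs[1], 5, 9), d$layout$spacer)
  expect_identical(substr(seqs[1], 10, 29), d$catalog$uptag[1])
})

test_that("index collisions within one file are rejected", {
  sheet <- make_sheet()
  sheet$index_seq[2] <- sheet$index_seq[1]
  d <- generate_library(5, seed = 1)
  cts <- tibble::tibble(mutant_id = d$catalog$mutant_id,
                        c_up = 1L, c_dn = 1L, t_up = 1L, t_dn = 1L)
  expect_error(write_reads(cts, d, sheet, withr::local_tempdir()),
               "share an index")
  sheet2 <- make_sheet()
  sheet2$index_seq[2] <- substr(sheet2$index_seq[1], 1, 3)
  expect_error(write_reads(cts, d, sheet2, withr::local_tempdir()), "prefix")
})

test_that("growth-curve simulation honours inhibition and noise contracts", {
  curves <- simulate_growth_curves(c(`0` = 0, `5` = 1), noise_sd = 0)
  ctrl <- curves[curves$dose == "0", ]
  flat <- curves[curves$dose == "5", ]
  expect_identical(flat$od, rep(0.1, nrow(flat)))
  expect_gt(max(ctrl$od), 1) # grows towards carrying capacity
  expect_equal(ctrl$time_hr, seq(0, 16, by = 0.5))
  expect_error(simulate_growth_curves(c(`0` = 0), noise_sd = -1), "noise_sd")
  expect_error(simulate_growth_curves(c(`0` = 1.5)), "\\[0, 1\\]")
})

test_that("planted annotation terms have exactly the requested overlap", {
  universe <- paste0("g", 1:500)
  hits <- paste0("g", 1:36)
  coll <- generate_annotations(
    universe, hits,
    planted = tibble::tibble(term = c("t1", "t2", "t3"),
                             K = c(4, 5, 6), k = c(3, 0, 6)),
    seed = 2
  )
  expect_length(coll$sets$t1, 4)
  expect_length(intersect(coll$sets$t1, hits), 3)
  expect_length(intersect(coll$sets$t2, hits), 0)
  expect_length(intersect(coll$sets$t3, hits), 6)
  expect_error(
    generate_annotations(universe, hits,
                         planted = tibble::tibble(term = "bad", K = 3, k = 5)),
    "k cannot exceed"
  )
})

test_that("GMT files round-trip through write_gmt / read_gmt", {
  universe <- paste0("g", 1:100)
  coll <- generate_annotations(universe, paste0("g", 1:10),
                               planted = tibble::tibble(term = c("a", "b"),
                                                        K = c(5, 8), k = c(2, 0)),
                               seed = 1)
  path <- file.path(withr::local_tempdir(), "x.gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = universe)
  expect_identical(lapply(back$sets, sort), lapply(coll$sets, sort))
})
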