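#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file; every tunable of the pipeline
#' lives here (CLI flags mirror the keys 1:1). Paths are resolved relative to
#' the config file's directory. Validation checks that every referenced input
#' exists and that parameters are inside their documented ranges, before any
#' compute starts.
#'
#' @param path Path to a YAML config, or a named list with the same
#'   structure.
#' @return A validated config list with absolute paths and defaults filled
#'   in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    base <- dirname(normalizePath(path))
    raw <- yaml::read_yaml(path)
    raw$._base <- base
    raw
  } else {
    path$._base <- path$._base %||% getwd()
    path
  }
  defaults <- list(
    counting = list(max_mismatch = 1, tag_combination = "sum"),
    scoring = list(d = 5, pseudocount = 1, fdr_cutoff = 0.1,
                   expressivity_low = 0.25, expressivity_high = 0.6),
    enrichment = list(alpha = 0.01),
    seed = 1
  )
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      for (key in names(defaults[[sec]])) {
        cfg[[sec]][[key]] <- cfg[[sec]][[key]] %||% defaults[[sec]][[key]]
      }
    } else {
      cfg[[sec]] <- cfg[[sec]] %||% defaults[[sec]]
    }
  }
  req_paths <- c("catalog", "sample_sheet", "fastq_dir", "screens")
  for (p in req_paths) {
    if (is.null(cfg$paths[[p]])) abort(sprintf("config is missing paths$%s.", p))
    full <- cfg$paths[[p]]
    if (!grepl("^/", full)) full <- file.path(cfg$._base, full)
    if (!file.exists(full)) abort(sprintf("config path %s does not exist: %s", p, full))
    cfg$paths[[p]] <- normalizePath(full)
  }
  for (p in c("gmt", "universe")) {
    if (!is.null(cfg$paths[[p]])) {
      full <- cfg$paths[[p]]
      if (!grepl("^/", full)) full <- file.path(cfg$._base, full)
      if (!file.exists(full)) abort(sprintf("config path %s does not exist: %s", p, full))
      cfg$paths[[p]] <- normalizePath(full)
    }
  }
  if (is.null(cfg$paths$out_dir)) abort("config is missing paths$out_dir.")
  if (!cfg$counting$max_mismatch %in% c(0, 1)) abort("counting$max_mismatch must be 0 or 1.")
  if (cfg$scoring$fdr_cutoff <= 0 || cfg$scoring$fdr_cutoff >= 1) {
    abort("scoring$fdr_cutoff must be in (0, 1).")
  }
  if (cfg$enrichment$alpha <= 0 || cfg$enrichment$alpha > 1) {
    abort("enrichment$alpha must be in (0, 1].")
  }
  cfg
}

#' Run the full Bar-seq pipeline from a config
#'
#' Executes count -> score -> call -> overlap/cluster -> enrich. Every stage
#' writes its TSV outputs under `out_dir`; a JSON run manifest records the
#' config snapshot, input checksums, the seed and timestamps, so each output
#' is traceable to the run that produced it. Re-running with identical inputs
#' and config reproduces identical tables. On a stage failure the partial
#' outputs are retained next to a `FAILED` marker naming the stage.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @return Invisibly, a list with the main in-memory results (`counts`,
#'   `screens`, `hits`, `overlap`, `dendrogram`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
  }
  tryCatch({
    design <- read_catalog(cfg$paths$catalog,
                           spacer = cfg$layout$spacer %||% "CGCTA")
    sheet <- read_sample_sheet(cfg$paths$sample_sheet)
    screens_tbl <- readr::read_tsv(cfg$paths$screens, show_col_types = FALSE,
                                   progress = FALSE)
    inputs <- c(cfg$paths$catalog, cfg$paths$sample_sheet, cfg$paths$screens)
    manifest <- list(
      config = cfg[setdiff(names(cfg), "._base")],
      input_checksums = as.list(tools::md5sum(inputs)),
      seed = cfg$seed,
      started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    stage <- "count"
    fastqs <- list.files(cfg$paths$fastq_dir,
                         pattern = "\\.fastq(\\.gz)?$", full.names = TRUE)
    if (length(fastqs) == 0) abort("no FASTQ files found in fastq_dir.")
    counts <- count_barcodes(fastqs, design, sheet,
                             max_mismatch = cfg$counting$max_mismatch)
    pooled <- combine_tags(counts, sheet, how = cfg$counting$tag_combination)
    write_tsv_file(pooled, file.path(out_dir, "counts.tsv"))
    write_tsv_file(attr(counts, "qc"), file.path(out_dir, "counts_qc.tsv"))

    stage <- "score"
    screens <- lapply(seq_len(nrow(screens_tbl)), function(i) {
      row <- screens_tbl[i, ]
      score_screen(pooled, control = row$control, treatment = row$treatment,
                   d = if ("d" %in% names(row)) row$d else cfg$scoring$d,
                   pseudocount = cfg$scoring$pseudocount,
                   screen_id = row$screen_id, compound = row$compound)
    })
    long <- bind_screens(screens)
    write_tsv_file(long, file.path(out_dir, "scores.tsv"))
    write_tsv_file(bind_rows(lapply(screens, glance)),
                   file.path(out_dir, "screen_summary.tsv"))

    stage <- "call"
    cuts <- c(low = cfg$scoring$expressivity_low,
              high = cfg$scoring$expressivity_high)
    hits <- call_hits(long, fdr_cutoff = cfg$scoring$fdr_cutoff,
                      expressivity_cutoffs = cuts)
    write_tsv_file(as_tibble(hits), file.path(out_dir, "hits.tsv"))
    write_tsv_file(filter(as_tibble(hits), .data$status == "rescreen"),
                   file.path(out_dir, "rescreen_candidates.tsv"))

    stage <- "overlap"
    compounds <- unique(long$compound)
    overlap <- NULL
    if (length(compounds) >= 2) {
      universe <- if (!is.null(cfg$paths$universe)) {
        readLines(cfg$paths$universe)
      } else {
        design$catalog$mutant_id
      }
      a <- hit_list(hits, compounds[[1]])
      b <- hit_list(hits, compounds[[2]])
      if (length(a) > 0 && length(b) > 0) {
        overlap <- fisher_overlap(a, b, length(universe))
        write_tsv_file(glance(overlap), file.path(out_dir, "overlap.tsv"))
      }
    }

    stage <- "cluster"
    dendro <- NULL
    union_hits <- hit_list(hits)
    if (length(union_hits) >= 3) {
      gi_mat <- long |>
        filter(.data$mutant_id %in% union_hits) |>
        select("mutant_id", "screen_id", "gi") |>
        tidyr::pivot_wider(names_from = "screen_id", values_from = "gi")
      keep <- rowSums(!is.na(as.matrix(gi_mat[-1]))) >= 2
      gi_mat <- gi_mat[keep, ]
      if (nrow(gi_mat) >= 3) {
        dendro <- average_linkage(gi_distance(gi_mat))
        as_newick(dendro, file.path(out_dir, "dendrogram.newick"))
        write_tsv_file(ordered_gi_matrix(gi_mat, dendro),
                       file.path(out_dir, "gi_matrix_ordered.tsv"))
      }
    }

    stage <- "enrich"
    enrichment <- NULL
    if (!is.null(cfg$paths$gmt)) {
      universe <- if (!is.null(cfg$paths$universe)) {
        readLines(cfg$paths$universe)
      } else {
        design$catalog$mutant_id
      }
      collection <- read_gmt(cfg$paths$gmt, universe = universe)
      enrichment <- lapply(setNames(compounds, compounds), function(cp) {
        hl <- hit_list(hits, cp)
        if (length(intersect(hl, collection$universe)) == 0) return(NULL)
        et <- enrich_table(hl, collection, alpha = cfg$enrichment$alpha)
        write_tsv_file(as_tibble(et),
                       file.path(out_dir, sprintf("enrichment_%s.tsv", cp)))
        et
      })
    }

    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (file.exists(file.path(out_dir, "FAILED"))) {
      file.remove(file.path(out_dir, "FAILED"))
    }
    invisible(list(counts = counts, screens = screens, hits = hits,
                   overlap = overlap, dendrogram = dendro,
                   enrichment = enrichment))
  }, error = on_fail)
}

#' Simulate a complete screen-set input directory
#'
#' Generates everything [run_pipeline()] consumes for a two-compound study:
#' barcode catalog, sample sheet (uptag + dntag per pool, four indexed
#' samples per screen FASTQ), screen manifest, FASTQ reads, a GMT of planted
#' annotation terms, and the ground-truth fitness tables. Sensitivity effects
#' are planted per compound at the default class strengths (f = 0.9 / 0.6 / 0
#' for low / medium / high).
#'
#' @param dir Output directory.
#' @param n_mutants Pool size (default 3000).
#' @param compounds Character vector of compound names (two by default).
#' @param n_replicates Screens per compound.
#' @param planted Named list per compound: numeric `c(low, medium, high)`
#'   counts of planted sensitive mutants.
#' @param shared_high Number of high-sensitivity mutants planted in *all*
#'   compounds (overlap between the compound hit sets).
#' @param reads_per_sample Depth per tag sample.
#' @param d Pool doublings per screen.
#' @param error_rate Per-base substitution rate in the reads.
#' @param seed Integer seed.
#' @return Invisibly, a list with the design, the per-compound truth tables
#'   and the paths written (including a ready-to-run `config.yaml`).
#' @export
simulate_screen_set <- function(dir, n_mutants = 3000,
                                compounds = c("cadmium", "arsenite"),
                                n_replicates = 3,
                                planted = NULL, shared_high = 30,
                                reads_per_sample = 200000, d = 5,
                                error_rate = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastq_dir <- file.path(dir, "fastq")
  dir.create(fastq_dir, showWarnings = FALSE)
  design <- generate_library(n_mutants, seed = seed)
  write_catalog(design, file.path(dir, "catalog.tsv"))

  planted <- planted %||% setNames(
    rep(list(c(low = 20, medium = 20, high = 60)), length(compounds)),
    compounds
  )
  # shared high-sensitivity mutants: same ids planted for every compound
  shared_ids <- with_seed(derive_seed(seed, 999),
                          sample(design$catalog$mutant_id, shared_high))
  truths <- list()
  indices <- c("CGAT", "TATA", "GCCA", "ATTG")
  sheet <- list(); screens_tbl <- list()
  for (ci in seq_along(compounds)) {
    cp <- compounds[[ci]]
    pl <- planted[[cp]]
    fit <- fitness_model(design,
                         n_low = pl[["low"]], n_medium = pl[["medium"]],
                         n_high = pl[["high"]],
                         seed = derive_seed(seed, ci))
    # overwrite part of the planted set with the shared ids
    fit$f[fit$mutant_id %in% shared_ids] <- 0
    fit$class[fit$mutant_id %in% shared_ids] <- "high"
    fit$expected_gi <- fit$baseline_rate * (1 - fit$f)
    truths[[cp]] <- fit
    write_tsv_file(fit, file.path(dir, sprintf("truth_%s.tsv", cp)))

    for (r in seq_len(n_replicates)) {
      scr <- sprintf("%s_r%d", cp, r)
      pools <- c(ctrl = sprintf("%s_ctrl", scr), trt = sprintf("%s_trt", scr))
      counts <- tibble(mutant_id = design$catalog$mutant_id)
      srow <- 0L
      for (cond in c("control", "treatment")) {
        for (tag in c("up", "dn")) {
          srow <- srow + 1L
          sid <- sprintf("%s_%s_%s", scr,
                         if (cond == "control") "ctrl" else "trt", tag)
          sim <- simulate_counts(design, fit, cond, reads_per_sample, d = d,
                                 seed = derive_seed(seed, 1000 * ci + 10 * r + srow),
                                 sample_id = sid)
          counts[[sid]] <- sim[[sid]]
          sheet[[length(sheet) + 1L]] <- tibble(
            sample_id = sid, file = sprintf("%s.fastq", scr),
            index_seq = indices[[srow]], tag_class = tag,
            pool_id = unname(pools[[if (cond == "control") "ctrl" else "trt"]]),
            condition = cond, batch = r
          )
        }
      }
      write_reads(counts, design, bind_rows(tail(sheet, 4)), fastq_dir,
                  error_rate = error_rate,
                  seed = derive_seed(seed, 5000 + 100 * ci + r))
      screens_tbl[[length(screens_tbl) + 1L]] <- tibble(
        screen_id = scr, compound = cp, d = d,
        control = unname(pools[["ctrl"]]), treatment = unname(pools[["trt"]])
      )
    }
  }
  sheet <- bind_rows(sheet)
  screens_tbl <- bind_rows(screens_tbl)
  write_tsv_file(sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv_file(screens_tbl, file.path(dir, "screens.tsv"))

  # planted annotation terms against the first compound's high-sensitivity set
  hi <- truths[[1]]$mutant_id[truths[[1]]$class == "high"]
  ann <- generate_annotations(
    design$catalog$mutant_id, hi,
    planted = tibble(term = c("planted_strong", "planted_partial", "unrelated"),
                     K = c(min(10, length(hi)), 20, 15),
                     k = c(min(10, length(hi)), min(5, length(hi)), 0)),
    seed = derive_seed(seed, 42)
  )
  write_gmt(ann, file.path(dir, "terms.gmt"))

  cfg <- list(
    paths = list(catalog = "catalog.tsv", sample_sheet = "sample_sheet.tsv",
                 fastq_dir = "fastq", screens = "screens.tsv",
                 gmt = "terms.gmt", out_dir = file.path(dir, "results")),
    scoring = list(d = d),
    seed = seed
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(design = design, truths = truths,
                 config = file.path(dir, "config.yaml")))
}
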