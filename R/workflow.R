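#' Pipeline orchestration
#'
#' A run configuration (R list or JSON file) drives an end-to-end screen
#' analysis: simulate (or load) reads, count guides, estimate clones, split
#' internal replicates, run the gene test and score screen quality. All
#' outputs are TSV files with a commented provenance header (package version,
#' config hash, seed) so that identical configs reproduce identical tables.
#'
#' @name workflow
NULL

#' Validate a run configuration
#'
#' @param config list or path to a JSON config file. Recognised top-level
#'   fields: `stages` (character vector), `seed` (required when any
#'   stochastic stage is listed), `outdir`, plus one parameter block per
#'   stage.
#' @return the normalized config list (invisibly errors on problems)
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("simulate", "count", "clones", "split_replicates", "test", "ssmd")
  if (is.null(config$stages) || !all(config$stages %in% known)) {
    stop("config$stages must be a subset of: ", paste(known, collapse = ", "))
  }
  stochastic <- c("simulate", "test")
  if (any(config$stages %in% stochastic) && is.null(config$seed)) {
    stop("config$seed is mandatory when stochastic stages are run")
  }
  config$outdir <- config$outdir %||% "."
  for (f in c(config$count$library_file, config$count$r1, config$count$r2)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config references a missing file: ", f)
    }
  }
  config
}

provenance <- function(config) {
  ver <- as.character(utils::packageVersion("cropscreen"))
  hash <- substr(digest_config(config), 1L, 12L)
  c(sprintf("cropscreen %s", ver),
    sprintf("config_hash %s", hash),
    sprintf("seed %s", config$seed %||% "NA"))
}

digest_config <- function(config) {
  # order-stable serialization hashed with a small FNV-1a; avoids a digest
  # dependency for a provenance fingerprint
  config$outdir <- NULL  # where results land must not change their fingerprint
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x%04x", as.integer(h), nchar(s) %% 65536)
}

#' Run the configured pipeline
#'
#' Stages run in fixed dependency order
#' (simulate, count, clones, split_replicates, test, ssmd); each stage's
#' outputs feed the next. On stage failure the run halts naming the stage;
#' partial outputs keep a `.partial` suffix.
#'
#' @param config see [validate_config()]
#' @return run report list: per-stage status, QC, and result paths
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance(config)
  state <- list(report = list(config_hash = hdr[2]))

  order_known <- c("simulate", "count", "clones", "split_replicates",
                   "test", "ssmd")
  for (stage in order_known[order_known %in% config$stages]) {
    state <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, state, hdr),
             count = stage_count(config, state, hdr),
             clones = stage_clones(config, state, hdr),
             split_replicates = stage_split(config, state, hdr),
             test = stage_test(config, state, hdr),
             ssmd = stage_ssmd(config, state, hdr)),
      error = function(e) {
        stop("pipeline halted at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
      })
    state$report$stages <- c(state$report$stages, stage)
  }
  state$report
}

stage_simulate <- function(config, state, hdr) {
  p <- config$simulate %||% list()
  lib <- make_library(p$n_target_genes %||% 39L, p$guides_per_gene %||% 8L,
                      p$n_essential %||% 2L, p$n_nonessential %||% 2L,
                      p$n_safe_harbour %||% 3L, seed = config$seed)
  design <- screen_design(
    n_clones_founding = p$n_clones_founding %||% 5000L,
    bottleneck_fraction = p$bottleneck_fraction %||% 0.1,
    n_generations = p$n_generations %||% 10L,
    fitness_by_gene = default_fitness(lib, overrides = unlist(p$fitness)),
    depth = p$depth %||% 2e5,
    error_rate = p$error_rate %||% 0.003,
    seed = config$seed
  )
  sim <- simulate_invivo_screen(lib, design)
  reads <- emit_reads(sim$truth[[1L]], lib, design)
  state$library <- lib
  state$design <- design
  state$sim <- sim
  state$reads <- reads
  write_library(lib, file.path(config$outdir, "library.tsv"))
  state$report$n_reads <- length(reads$read1)
  state
}

stage_count <- function(config, state, hdr) {
  p <- config$count %||% list()
  if (is.null(state$reads)) {
    lib <- read_library(p$library_file)
    r1 <- read_fastq(p$r1)
    r2 <- if (!is.null(p$r2)) read_fastq(p$r2) else NULL
    state$library <- lib
    state$reads <- list(read1 = unname(r1), read2 = unname(r2))
  }
  layout <- read_layout(
    stagger_lengths = p$stagger_lengths %||% state$design$stagger_lengths %||% 0:7,
    anchor = p$anchor %||% state$design$anchor %||% DEFAULT_ANCHOR
  )
  res <- count_guides(state$reads$read1, state$reads$read2, state$library,
                      layout, with_umi = TRUE)
  state$counts <- res$counts
  state$umi_counts <- res$umi_counts
  state$qc <- res$qc
  write_tsv(res$counts, file.path(config$outdir, "counts.tsv"), hdr)
  write_tsv(res$umi_counts, file.path(config$outdir, "umi_counts.tsv"), hdr)
  write_tsv(as.data.frame(res$qc), file.path(config$outdir, "count_qc.tsv"),
            hdr)
  state$report$alignment_rate <- res$qc$alignment_rate
  state
}

stage_clones <- function(config, state, hdr) {
  p <- config$clones %||% list()
  est <- estimate_clones(state$umi_counts,
                         exclude_top = p$exclude_top %||% 50L,
                         min_reads = p$min_reads %||% 10L)
  state$clones <- est
  rep <- data.frame(x0 = est$x0, clone_count = est$clone_count,
                    n_umis_total = est$n_umis_total,
                    n_umis_fit = est$n_umis_fit)
  write_tsv(rep, file.path(config$outdir, "clones.tsv"), hdr)
  state$report$clone_count <- est$clone_count
  state
}

stage_split <- function(config, state, hdr) {
  p <- config$split_replicates %||% list()
  k <- p$prefix_length %||% 1L
  rs <- split_internal_replicates(state$umi_counts, k)
  state$replicates <- rs
  idx <- data.frame(prefix = names(rs$tables),
                    n_guides = vapply(rs$tables, nrow, integer(1L)))
  write_tsv(idx, file.path(config$outdir, "replicates_index.tsv"), hdr)
  state
}

stage_test <- function(config, state, hdr) {
  p <- config$test %||% list()
  # test = final clone abundance vs founding representation
  truth <- state$sim$truth[[1L]]
  lib <- state$library
  agg <- function(v) {
    out <- rowsum(v, factor(truth$guide_id, levels = lib$guide_id))
    as.vector(out)
  }
  counts <- data.frame(sgRNA = lib$guide_id, gene = lib$gene,
                       ref = agg(truth$founding_count),
                       test = agg(truth$final_count),
                       stringsAsFactors = FALSE)
  res <- screen_test(counts, "test", "ref",
                     n_perm = p$n_perm %||% 1000L, seed = config$seed)
  state$gene_results <- res
  write_tsv(res, file.path(config$outdir, "gene_results.tsv"), hdr)
  state$report$n_hits <- sum(res$hit)
  state
}

stage_ssmd <- function(config, state, hdr) {
  res <- state$gene_results
  lib <- state$library
  ess <- unique(lib$gene[lib$category == "essential"])
  ne <- unique(lib$gene[lib$category == "nonessential"])
  s <- ssmd(stats::setNames(res$lfc, res$gene), ess, ne)
  rep <- data.frame(ssmd = s$ssmd, mean_essential = s$mean_essential,
                    mean_nonessential = s$mean_nonessential,
                    sd_essential = s$sd_essential,
                    sd_nonessential = s$sd_nonessential,
                    n_e = s$n_e, n_ne = s$n_ne,
                    low_quality = s$low_quality)
  write_tsv(rep, file.path(config$outdir, "ssmd.tsv"), hdr)
  state$report$ssmd <- s$ssmd
  state
}
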