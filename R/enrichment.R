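#' Enrichment statistics for pooled screens
#'
#' Self-contained replacements for external screen-test tools: median-ratio or
#' control-guide normalization, per-guide log2 fold changes with pseudocount,
#' a gene-level permutation test (guide-to-gene label permutation) with
#' Benjamini-Hochberg FDR, z-normalized effect sizes, strict hit thresholds,
#' and the SSMD screen-quality score computed from essential and
#' non-essential control sets.
#'
#' @name enrichment
NULL

#' Normalize a count table
#'
#' `median_ratio`: per-sample size factor = median over guides of
#' count / geometric-mean-across-samples, computed over guides without zeros
#' (the DESeq-style estimator). `control_genes`: the same median restricted to
#' guides of the supplied control genes.
#'
#' @param counts data frame with columns sgRNA, gene and one numeric column
#'   per sample (the [count_table()] dialect)
#' @param method `"median_ratio"` or `"control_genes"`
#' @param control_set character vector of control gene symbols (required for
#'   `control_genes`)
#' @return list(normalized = counts data frame with scaled sample columns,
#'   size_factors = named numeric)
#' @export
normalize_counts <- function(counts, method = c("median_ratio",
                                                "control_genes"),
                             control_set = NULL) {
  method <- match.arg(method)
  samp <- setdiff(names(counts), c("sgRNA", "gene"))
  stopifnot(length(samp) >= 1L)
  m <- as.matrix(counts[, samp, drop = FALSE])
  use <- rowSums(m == 0) == 0L
  if (method == "control_genes") {
    if (is.null(control_set) || !any(counts$gene %in% control_set)) {
      stop("control_genes normalization needs control genes present in the table")
    }
    use <- use & counts$gene %in% control_set
  }
  if (!any(use)) {
    stop("no usable guides for size-factor computation (all have zero counts",
         if (method == "control_genes") " among the control set", ")")
  }
  gm <- exp(rowMeans(log(m[use, , drop = FALSE])))
  sf <- apply(m[use, , drop = FALSE], 2L, function(col) median(col / gm))
  if (any(sf <= 0)) stop("non-positive size factor; check input counts")
  norm <- counts
  for (j in seq_along(samp)) norm[[samp[j]]] <- m[, j] / sf[j]
  list(normalized = norm, size_factors = sf)
}

#' Per-guide log2 fold change
#'
#' lfc = log2((test + pseudocount) / (ref + pseudocount)) on normalized
#' counts. Guides with zero counts in both compared samples are removed.
#'
#' @param test,ref numeric vectors of normalized counts over the same guide
#'   universe
#' @param guide_id,gene guide annotation vectors aligned with the counts
#' @param pseudocount added to both sides (default 1)
#' @return data frame: guide_id, gene, lfc, norm_counts_test, norm_counts_ref
#' @export
guide_lfc <- function(test, ref, guide_id, gene, pseudocount = 1) {
  stopifnot(length(test) == length(ref), length(test) == length(guide_id),
            pseudocount > 0)
  keep <- !(test == 0 & ref == 0)
  data.frame(
    guide_id = guide_id[keep], gene = gene[keep],
    lfc = log2((test[keep] + pseudocount) / (ref[keep] + pseudocount)),
    norm_counts_test = test[keep], norm_counts_ref = ref[keep],
    stringsAsFactors = FALSE
  )
}

#' Gene-level permutation test
#'
#' The gene score is the mean guide lfc (averaged additionally over internal
#' replicates when `replicate_lfcs` is supplied). The null distribution comes
#' from permuting guide-to-gene labels while preserving the number of guides
#' per gene; the two-sided Monte Carlo p-value uses +1 smoothing:
#' p = (1 + #\{|null| >= |obs|\}) / (n_perm + 1). With `exhaustive = TRUE`
#' (total guides <= 10) all label permutations are enumerated instead and
#' p = #\{|null| >= |obs|\} / n! (the identity permutation guarantees p > 0).
#' FDR is Benjamini-Hochberg across genes; z_lfc standardizes each gene lfc
#' against the mean and SD of all gene lfcs.
#'
#' @param stats data frame from [guide_lfc()] (columns guide_id, gene, lfc)
#' @param n_perm number of Monte Carlo permutations (>= 100)
#' @param replicate_lfcs optional list of per-internal-replicate guide_lfc
#'   data frames; guide lfcs are averaged across replicates per guide first
#' @param seed RNG seed for the permutations
#' @param exhaustive enumerate all permutations (small instances only)
#' @param lfc_threshold,fdr_threshold hit thresholds passed to [call_hits()]
#' @return data frame: gene, lfc, z_lfc, p_value, fdr, n_guides, hit
#' @export
gene_test <- function(stats, n_perm = 10000L, replicate_lfcs = NULL,
                      seed = 1L, exhaustive = FALSE,
                      lfc_threshold = 1.5, fdr_threshold = 0.01) {
  if (!exhaustive && n_perm < 100L) {
    stop("n_perm must be at least 100 for a usable permutation null")
  }
  if (!is.null(replicate_lfcs)) {
    all_lfc <- data.table::rbindlist(
      lapply(replicate_lfcs, function(d) d[, c("guide_id", "gene", "lfc")]))
    agg <- all_lfc[, .(lfc = mean(lfc)), by = .(guide_id, gene)]
    stats <- as.data.frame(agg)
  }
  stopifnot(all(c("guide_id", "gene", "lfc") %in% names(stats)))
  genes <- sort(unique(stats$gene))
  g_idx <- match(stats$gene, genes)
  lfc <- stats$lfc
  n_guides <- tabulate(g_idx, nbins = length(genes))
  gene_means <- function(v) as.vector(rowsum(v, g_idx)) / n_guides
  obs <- gene_means(lfc)

  if (exhaustive) {
    if (length(lfc) > 10L) stop("exhaustive enumeration limited to 10 guides")
    perms <- permutations_of(length(lfc))
    p <- numeric(length(genes))
    for (i in seq_len(nrow(perms))) {
      nl <- gene_means(lfc[perms[i, ]])
      p <- p + (abs(nl) >= abs(obs) - 1e-12)
    }
    p <- p / nrow(perms)
  } else {
    set.seed(seed)
    exceed <- integer(length(genes))
    for (i in seq_len(n_perm)) {
      nl <- gene_means(lfc[sample.int(length(lfc))])
      exceed <- exceed + (abs(nl) >= abs(obs) - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  mu <- mean(obs)
  sdv <- sd(obs)
  z <- if (is.na(sdv) || sdv == 0) rep(NA_real_, length(obs)) else (obs - mu) / sdv
  res <- data.frame(gene = genes, lfc = obs, z_lfc = z, p_value = p,
                    fdr = p.adjust(p, method = "BH"), n_guides = n_guides,
                    stringsAsFactors = FALSE)
  call_hits(res, lfc_threshold, fdr_threshold)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Flag screen hits at strict thresholds
#'
#' A gene is a hit iff lfc > `lfc_threshold` AND fdr < `fdr_threshold`
#' (both strict inequalities).
#'
#' @param results data frame with columns lfc and fdr
#' @param lfc_threshold log2 fold-change cut (default 1.5)
#' @param fdr_threshold FDR cut (default 0.01)
#' @return `results` with a logical `hit` column
#' @export
call_hits <- function(results, lfc_threshold = 1.5, fdr_threshold = 0.01) {
  stopifnot(all(c("lfc", "fdr") %in% names(results)))
  results$hit <- results$lfc > lfc_threshold & results$fdr < fdr_threshold
  results
}

#' Strictly standardized mean difference (SSMD)
#'
#' SSMD = (mean_e - mean_ne) / sqrt(sd_e^2 + sd_ne^2) over the log2 fold
#' changes of essential and non-essential control genes (sample SDs, n-1).
#' Because essential genes drop out, a well-powered screen yields a strongly
#' negative SSMD; the quality flag therefore uses |SSMD| against the cut
#' (default 0.5; screens below it are flagged low quality).
#'
#' @param lfcs named numeric vector of guide- or gene-level lfc
#'   (names = genes or guide ids resolvable via `genes`)
#' @param essential_set,nonessential_set character vectors of control gene
#'   symbols (must be disjoint)
#' @param genes optional gene annotation aligned with `lfcs` (defaults to
#'   `names(lfcs)`)
#' @param quality_cut |SSMD| below this flags the screen as low quality
#' @return an `ssmd_result` list: ssmd, mean/sd/n per set, low_quality flag
#' @export
ssmd <- function(lfcs, essential_set, nonessential_set, genes = names(lfcs),
                 quality_cut = 0.5) {
  if (length(intersect(essential_set, nonessential_set)) > 0L) {
    stop("essential and non-essential sets must be disjoint")
  }
  stopifnot(!is.null(genes), length(genes) == length(lfcs))
  e <- lfcs[genes %in% essential_set & is.finite(lfcs)]
  ne <- lfcs[genes %in% nonessential_set & is.finite(lfcs)]
  missing_e <- setdiff(essential_set, genes)
  missing_ne <- setdiff(nonessential_set, genes)
  if (length(missing_e) || length(missing_ne)) {
    warning(sprintf("%d essential and %d non-essential set members absent from data",
                    length(missing_e), length(missing_ne)))
  }
  if (length(e) < 2L || length(ne) < 2L) {
    stop("need at least 2 members of each control set with finite lfc")
  }
  val <- (mean(e) - mean(ne)) / sqrt(sd(e)^2 + sd(ne)^2)
  structure(list(ssmd = val,
                 mean_essential = mean(e), mean_nonessential = mean(ne),
                 sd_essential = sd(e), sd_nonessential = sd(ne),
                 n_e = length(e), n_ne = length(ne),
                 low_quality = abs(val) < quality_cut),
            class = "ssmd_result")
}

#' @export
print.ssmd_result <- function(x, ...) {
  cat(sprintf("SSMD = %.4f (essential: mean %.3f sd %.3f n=%d; non-essential: mean %.3f sd %.3f n=%d)%s\n",
              x$ssmd, x$mean_essential, x$sd_essential, x$n_e,
              x$mean_nonessential, x$sd_nonessential, x$n_ne,
              if (x$low_quality) " [LOW QUALITY]" else ""))
  invisible(x)
}

#' z-normalize effect sizes against a reference population
#'
#' @param lfcs numeric vector to transform
#' @param reference population defining the mean and SD (defaults to `lfcs`
#'   itself, i.e. all genes)
#' @return z-scores
#' @export
z_normalize <- function(lfcs, reference = lfcs) {
  sdv <- sd(reference)
  if (is.na(sdv) || sdv == 0) stop("reference population has zero sd")
  (lfcs - mean(reference)) / sdv
}

#' Paired-sample screen test
#'
#' Computes guide lfc per (test, ref) pair of samples (e.g. per donor) on the
#' normalized table, averages lfc per guide across pairs, and runs
#' [gene_test()].
#'
#' @param counts count table (sgRNA, gene, sample columns)
#' @param test_samples,ref_samples equal-length character vectors of paired
#'   sample names
#' @param norm_method,control_set passed to [normalize_counts()]
#' @param ... passed to [gene_test()]
#' @return [gene_test()] result
#' @export
screen_test <- function(counts, test_samples, ref_samples,
                        norm_method = "median_ratio", control_set = NULL,
                        ...) {
  stopifnot(length(test_samples) == length(ref_samples),
            length(test_samples) >= 1L)
  nrm <- normalize_counts(counts, norm_method, control_set)$normalized
  per_pair <- lapply(seq_along(test_samples), function(i) {
    guide_lfc(nrm[[test_samples[i]]], nrm[[ref_samples[i]]],
              nrm$sgRNA, nrm$gene)
  })
  gene_test(NULL, replicate_lfcs = per_pair, ...)
}
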