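#' Guide library construction and I/O
#'
#' A guide library is the universe of gRNAs in a pooled screen: one row per
#' guide with its 20-nt spacer, target gene and control category. All counting
#' stages match observed spacers against this reference.
#'
#' @name guide_library
NULL

GUIDE_CATEGORIES <- c("target", "essential", "nonessential", "safe_harbour")
BSMBI_SITES <- c("CGTCTC", "GAGACG")

new_guide_library <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("guide_id", "gene", "spacer", "category") %in% names(df)))
  if (anyDuplicated(df$spacer)) {
    dup <- df$guide_id[df$spacer %in% df$spacer[duplicated(df$spacer)]]
    stop("duplicate spacers in library for guides: ",
         paste(dup, collapse = ", "))
  }
  if (anyDuplicated(df$guide_id)) stop("duplicate guide ids in library")
  if (any(nchar(df$spacer) != 20L)) stop("all spacers must be 20 nt")
  if (!all(df$category %in% GUIDE_CATEGORIES)) {
    stop("unknown guide category; must be one of ",
         paste(GUIDE_CATEGORIES, collapse = ", "))
  }
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Build a synthetic guide library
#'
#' Creates a screen library sized like a typical focused in vivo screen:
#' `n_target_genes` genes with `guides_per_gene` guides each, plus control
#' guides against essential genes, non-essential (olfactory-receptor-like)
#' genes and a safe-harbour locus. Spacers are random 20-mers constrained to
#' survive standard cloning filters: no run of four or more T (premature
#' pol III termination) and no BsmBI recognition site (Golden Gate cloning).
#'
#' @param n_target_genes number of screened target genes
#' @param guides_per_gene guides designed per gene (targets and gene-level
#'   controls alike)
#' @param n_essential number of essential control genes
#' @param n_nonessential number of non-essential control genes
#' @param n_safe_harbour number of safe-harbour control guides (one pseudo-gene)
#' @param seed RNG seed; identical inputs give identical libraries
#' @return a `guide_library` data frame (guide_id, gene, spacer, category)
#' @examples
#' lib <- make_library(39, 8, 3, 3, 3, seed = 1)
#' table(lib$category)
#' @export
make_library <- function(n_target_genes, guides_per_gene,
                         n_essential = 0L, n_nonessential = 0L,
                         n_safe_harbour = 0L, seed = 1L) {
  stopifnot(n_target_genes >= 0, guides_per_gene >= 1,
            n_essential >= 0, n_nonessential >= 0, n_safe_harbour >= 0)
  n_total <- (n_target_genes + n_essential + n_nonessential) * guides_per_gene +
    n_safe_harbour
  if (n_total < 1L) stop("library must contain at least one guide")
  set.seed(seed)

  genes <- c(
    rep(sprintf("GENE%03d", seq_len(n_target_genes)), each = guides_per_gene),
    rep(sprintf("ESS%03d", seq_len(n_essential)), each = guides_per_gene),
    rep(sprintf("OR%03d", seq_len(n_nonessential)), each = guides_per_gene),
    rep("SAFE", n_safe_harbour)
  )
  category <- c(
    rep("target", n_target_genes * guides_per_gene),
    rep("essential", n_essential * guides_per_gene),
    rep("nonessential", n_nonessential * guides_per_gene),
    rep("safe_harbour", n_safe_harbour)
  )
  spacers <- draw_clean_spacers(n_total)
  df <- data.frame(
    guide_id = paste0(genes, "_", stats::ave(seq_along(genes), genes,
                                             FUN = seq_along)),
    gene = genes, spacer = spacers, category = category,
    stringsAsFactors = FALSE
  )
  new_guide_library(df)
}

# rejection-sample spacers passing the design filters, unique within library
draw_clean_spacers <- function(n, max_rounds = 50L) {
  out <- character(0)
  for (i in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0L) break
    cand <- random_dna(2L * need + 10L, 20L)
    bad <- grepl("TTTT", cand, fixed = TRUE) |
      grepl(BSMBI_SITES[1], cand, fixed = TRUE) |
      grepl(BSMBI_SITES[2], cand, fixed = TRUE)
    out <- unique(c(out, cand[!bad]))
  }
  if (length(out) < n) stop("spacer construction failed after bounded retries")
  out[seq_len(n)]
}

#' Read / write a guide library TSV
#'
#' Plain-text interchange format: tab-separated with columns
#' guide_id, gene, spacer, category.
#'
#' @param path file path
#' @return `read_library` returns a `guide_library`
#' @export
read_library <- function(path) {
  new_guide_library(as.data.frame(read_tsv(path)))
}

#' @rdname read_library
#' @param library a `guide_library`
#' @export
write_library <- function(library, path) {
  write_tsv(as.data.frame(library), path)
}
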