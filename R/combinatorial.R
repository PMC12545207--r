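#' Combinatorial dual-guide screens
#'
#' Dual-guide vectors deliver two gRNAs from one transcript; each spacer is
#' paired with a short internal barcode (iBAR). During lentiviral packaging
#' and PCR, template switching can recombine the two halves of different
#' library constructs. Because every spacer-iBAR pairing is unique in the
#' library, a read whose two halves each match the library but whose
#' combination does not is diagnostic of recombination. Features are read out
#' purely positionally (no anchor search) and matched with zero mismatches.
#'
#' @name combinatorial
NULL

#' Dual-guide read layout (positional slicing)
#'
#' Offsets are 1-based inclusive start positions; the shipped defaults place
#' spacer1/iBAR1 on read 1 and spacer2/iBAR2 on read 2.
#'
#' @param spacer_length spacer width
#' @param ibar_length iBAR width
#' @param r1_spacer,r1_ibar,r2_spacer,r2_ibar feature start positions
#' @return a `dual_layout` list
#' @export
dual_layout <- function(spacer_length = 20L, ibar_length = 6L,
                        r1_spacer = 1L, r1_ibar = 21L,
                        r2_spacer = 1L, r2_ibar = 21L) {
  structure(list(spacer_length = as.integer(spacer_length),
                 ibar_length = as.integer(ibar_length),
                 r1_spacer = as.integer(r1_spacer),
                 r1_ibar = as.integer(r1_ibar),
                 r2_spacer = as.integer(r2_spacer),
                 r2_ibar = as.integer(r2_ibar)),
            class = "dual_layout")
}

#' Build a synthetic dual-guide library
#'
#' Pairs the spacers of a gene panel in an all-by-all design (genes,
#' essential controls and a safe-harbour locus). Spacers recur across
#' constructs, but every construct receives its own iBAR at each position --
#' exactly the property that makes recombination between constructs
#' detectable.
#'
#' @param genes character vector of target gene symbols
#' @param n_essential number of essential control genes
#' @param seed RNG seed
#' @return a `dual_library` data frame: construct_id, spacer1, ibar1, spacer2,
#'   ibar2, gene1, gene2
#' @export
make_dual_library <- function(genes, n_essential = 2L, seed = 1L) {
  set.seed(seed)
  panel <- c(genes,
             sprintf("ESS%02d", seq_len(n_essential)),
             "SAFE")
  spacers <- draw_clean_spacers(length(panel))
  half <- data.frame(gene = panel, spacer = spacers, stringsAsFactors = FALSE)
  grid <- expand.grid(i = seq_len(nrow(half)), j = seq_len(nrow(half)))
  n <- nrow(grid)
  ibars <- unique_umis(2L * n, 6L)
  df <- data.frame(
    construct_id = sprintf("%s__%s", half$gene[grid$i], half$gene[grid$j]),
    spacer1 = half$spacer[grid$i], ibar1 = ibars[seq_len(n)],
    spacer2 = half$spacer[grid$j], ibar2 = ibars[n + seq_len(n)],
    gene1 = half$gene[grid$i], gene2 = half$gene[grid$j],
    stringsAsFactors = FALSE
  )
  key <- paste(df$spacer1, df$ibar1, df$spacer2, df$ibar2)
  stopifnot(!anyDuplicated(key))
  class(df) <- c("dual_library", "data.frame")
  df
}

#' Simulate dual-guide reads with a recombination knob
#'
#' Reads are drawn multinomially over constructs with optional per-gene
#' fitness weighting (applied multiplicatively per position). A fraction
#' `recombination` of reads swaps its read-2 half (spacer2 + iBAR2) with that
#' of a different random construct, emulating template switching.
#'
#' @param library a `dual_library`
#' @param n_reads number of read pairs
#' @param recombination fraction of reads with swapped halves
#' @param error_rate per-base substitution probability
#' @param weights optional per-construct sampling weights
#' @param layout a [dual_layout()]
#' @param seed RNG seed
#' @return list(read1, read2, manifest) where manifest records the true
#'   construct and whether the read was recombined
#' @export
simulate_dual_reads <- function(library, n_reads, recombination = 0,
                                error_rate = 0, weights = NULL,
                                layout = dual_layout(), seed = 1L) {
  set.seed(seed)
  w <- weights %||% rep(1, nrow(library))
  idx <- sample.int(nrow(library), n_reads, replace = TRUE, prob = w)
  partner <- idx
  rec <- runif(n_reads) < recombination
  if (any(rec)) {
    # swap in a read-2 half from a different construct
    partner[rec] <- vapply(idx[rec], function(i) {
      j <- sample.int(nrow(library) - 1L, 1L)
      if (j >= i) j + 1L else j
    }, integer(1L))
  }
  r1 <- paste0(library$spacer1[idx], library$ibar1[idx])
  r2 <- paste0(library$spacer2[partner], library$ibar2[partner])
  r1 <- mutate_seqs(r1, error_rate)
  r2 <- mutate_seqs(r2, error_rate)
  ids <- sprintf("dual:read%07d", seq_len(n_reads))
  list(read1 = r1, read2 = r2, id = ids,
       manifest = data.frame(read_id = ids,
                             construct_id = library$construct_id[idx],
                             recombined = rec & partner != idx,
                             stringsAsFactors = FALSE))
}

#' Extract dual-guide features by position
#'
#' @param read1,read2 character vectors
#' @param layout a [dual_layout()]
#' @return data frame spacer1, ibar1, spacer2, ibar2 (NA where the read is
#'   too short for an offset)
#' @export
extract_dual_features <- function(read1, read2, layout = dual_layout()) {
  slice <- function(x, from, len) {
    out <- substr(x, from, from + len - 1L)
    out[nchar(out) < len] <- NA_character_
    out
  }
  data.frame(
    spacer1 = slice(read1, layout$r1_spacer, layout$spacer_length),
    ibar1 = slice(read1, layout$r1_ibar, layout$ibar_length),
    spacer2 = slice(read2, layout$r2_spacer, layout$spacer_length),
    ibar2 = slice(read2, layout$r2_ibar, layout$ibar_length),
    stringsAsFactors = FALSE
  )
}

#' Match dual-guide features against the library
#'
#' Joint 4-tuple hash lookup with zero mismatches. On joint failure, each
#' (spacer, iBAR) half is looked up among the library halves at its position:
#' both halves found but no joint row = recombinant; anything else =
#' unmatched.
#'
#' @param features data frame from [extract_dual_features()]
#' @param library a `dual_library`
#' @return data frame: classification (matched/recombinant/unmatched),
#'   construct_id (NA unless matched)
#' @export
match_dual <- function(features, library) {
  key <- paste(features$spacer1, features$ibar1,
               features$spacer2, features$ibar2, sep = "|")
  libkey <- paste(library$spacer1, library$ibar1,
                  library$spacer2, library$ibar2, sep = "|")
  hit <- match(key, libkey)
  half1 <- paste(features$spacer1, features$ibar1, sep = "|") %in%
    paste(library$spacer1, library$ibar1, sep = "|")
  half2 <- paste(features$spacer2, features$ibar2, sep = "|") %in%
    paste(library$spacer2, library$ibar2, sep = "|")
  complete <- !is.na(features$spacer1) & !is.na(features$ibar1) &
    !is.na(features$spacer2) & !is.na(features$ibar2)
  classification <- ifelse(!is.na(hit), "matched",
                           ifelse(complete & half1 & half2, "recombinant",
                                  "unmatched"))
  data.frame(classification = classification,
             construct_id = library$construct_id[hit],
             stringsAsFactors = FALSE)
}

#' Dual-guide screen QC
#'
#' percent_perfect = matched / total reads; percent_recombination =
#' recombinant / (matched + recombinant), i.e. among classifiable reads;
#' fold_10_90 = 90th / 10th percentile (linear interpolation) of per-construct
#' matched counts over the full library (zeros kept).
#'
#' @param matches data frame from [match_dual()]
#' @param library a `dual_library`
#' @return a `dual_qc` list: percent_perfect, percent_recombination,
#'   fold_10_90, construct_counts, n_total
#' @export
dual_qc <- function(matches, library) {
  stopifnot(nrow(matches) >= 1L)
  n_total <- nrow(matches)
  n_match <- sum(matches$classification == "matched")
  n_rec <- sum(matches$classification == "recombinant")
  counts <- table(factor(matches$construct_id[matches$classification == "matched"],
                         levels = library$construct_id))
  counts <- as.integer(counts)
  q <- quantile(counts, c(0.1, 0.9), type = 7, names = FALSE)
  fold <- if (q[1] > 0) q[2] / q[1] else Inf
  structure(list(
    percent_perfect = n_match / n_total,
    percent_recombination = if (n_match + n_rec > 0) n_rec / (n_match + n_rec)
    else NA_real_,
    fold_10_90 = fold,
    construct_counts = data.frame(construct_id = library$construct_id,
                                  count = counts, stringsAsFactors = FALSE),
    n_total = n_total
  ), class = "dual_qc")
}

#' Positional fitness effect summary
#'
#' Essential-gene depletion read out separately for constructs that target an
#' essential gene only at vector position 1 (paired with a safe-harbour
#' spacer at position 2) and vice versa; a stronger (more negative) mean lfc
#' at one position indicates higher cutting efficiency there.
#'
#' @param construct_lfc data frame: construct_id, gene1, gene2, lfc
#' @param essential_genes character vector of essential gene symbols
#' @param neutral_genes genes considered phenotypically neutral partners
#'   (default "SAFE")
#' @return data frame: position, n_constructs, mean_lfc
#' @export
position_effect <- function(construct_lfc, essential_genes,
                            neutral_genes = "SAFE") {
  p1 <- construct_lfc$gene1 %in% essential_genes &
    construct_lfc$gene2 %in% neutral_genes
  p2 <- construct_lfc$gene2 %in% essential_genes &
    construct_lfc$gene1 %in% neutral_genes
  out <- data.frame(
    position = c(1L, 2L),
    n_constructs = c(sum(p1), sum(p2)),
    mean_lfc = c(if (any(p1)) mean(construct_lfc$lfc[p1]) else NA_real_,
                 if (any(p2)) mean(construct_lfc$lfc[p2]) else NA_real_)
  )
  out[out$n_constructs > 0L, , drop = FALSE]
}
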