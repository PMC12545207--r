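#' Guide counting from paired reads
#'
#' Implements the preprocessing stage of a pooled-screen pipeline: trim the
#' variable-length stagger and constant anchor off read 1, extract the 20-nt
#' spacer, match it exactly against the library, and (for the UMI readout)
#' key counts additionally by the UMI slice of read 2. QC mirrors the metrics
#' routinely pulled from screen-counting logs: total/mapped reads, alignment
#' rate, zero-count guides and the Gini index of the count distribution.
#'
#' @name guide_counting
NULL

#' Read layout for spacer extraction
#'
#' @param stagger_lengths permitted stagger lengths, scanned in increasing
#'   order
#' @param anchor constant sequence immediately 5' of the spacer
#' @param spacer_length spacer width (default 20)
#' @param umi_slice half-open 0-based interval `[from, to)` of read 2 taken as
#'   the UMI key (default `c(0, 26)`: the full 26-base read)
#' @param max_anchor_mismatches anchor mismatch tolerance (default 1,
#'   approximating standard adapter-trimmer behaviour)
#' @return a `read_layout` list
#' @export
read_layout <- function(stagger_lengths = 0:7,
                        anchor = DEFAULT_ANCHOR,
                        spacer_length = 20L,
                        umi_slice = c(0L, 26L),
                        max_anchor_mismatches = 1L) {
  stopifnot(nchar(anchor) >= 1L, spacer_length >= 15L,
            length(umi_slice) == 2L, umi_slice[1] >= 0L,
            umi_slice[2] > umi_slice[1])
  layout <- list(stagger_lengths = sort(as.integer(stagger_lengths)),
                 anchor = anchor,
                 spacer_length = as.integer(spacer_length),
                 umi_slice = as.integer(umi_slice),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches))
  class(layout) <- "read_layout"
  layout
}

#' Extract spacers from read-1 sequences
#'
#' Scans the permitted stagger lengths in increasing order; the first offset
#' at which the anchor matches with at most `max_anchor_mismatches`
#' mismatches wins, and the `spacer_length` bases following the anchor are
#' returned. Reads with no anchor hit (or too short) yield NA.
#'
#' @param reads character vector of read-1 sequences
#' @param layout a [read_layout()]
#' @return data frame with columns `spacer` (NA = no hit) and `stagger`
#' @export
extract_spacers <- function(reads, layout) {
  n <- length(reads)
  spacer <- rep(NA_character_, n)
  stagger <- rep(NA_integer_, n)
  alen <- nchar(layout$anchor)
  for (s in layout$stagger_lengths) {
    open <- is.na(spacer)
    if (!any(open)) break
    region <- substr(reads[open], s + 1L, s + alen)
    mm <- str_mismatches(region, layout$anchor)
    long_enough <- nchar(reads[open]) >= s + alen + layout$spacer_length
    hit <- !is.na(mm) & mm <= layout$max_anchor_mismatches & long_enough
    idx <- which(open)[hit]
    spacer[idx] <- substr(reads[idx], s + alen + 1L,
                          s + alen + layout$spacer_length)
    stagger[idx] <- s
  }
  data.frame(spacer = spacer, stagger = stagger, stringsAsFactors = FALSE)
}

#' @rdname extract_spacers
#' @param read1 a single read-1 sequence
#' @return `extract_spacer` returns a list(spacer, stagger) or NULL if no hit
#' @export
extract_spacer <- function(read1, layout) {
  res <- extract_spacers(read1, layout)
  if (is.na(res$spacer[1])) return(NULL)
  list(spacer = res$spacer[1], stagger = res$stagger[1])
}

#' Count guides from paired reads
#'
#' Spacers are matched exactly (zero mismatches) against the library by hash
#' lookup. With `with_umi = TRUE`, the UMI is the configured slice of read 2
#' and reads whose UMI contains an N are discarded before counting.
#'
#' @param read1,read2 character vectors of sequences (`read2` may be NULL when
#'   `with_umi = FALSE`)
#' @param library a `guide_library`
#' @param layout a [read_layout()]
#' @param with_umi build a per-(guide, UMI) count table as well?
#' @param sample sample label
#' @return list with `counts` (data frame guide_id, gene, count over the full
#'   library, zeros kept), `umi_counts` (data frame sample, guide_id, umi,
#'   count; NULL unless `with_umi`), and `qc` (a `count_qc` row)
#' @export
count_guides <- function(read1, read2 = NULL, library, layout = read_layout(),
                         with_umi = FALSE, sample = "sample01") {
  if (anyDuplicated(library$spacer)) {
    dup <- library$guide_id[library$spacer %in%
                              library$spacer[duplicated(library$spacer)]]
    stop("duplicate spacers in library for guides: ",
         paste(dup, collapse = ", "))
  }
  total <- length(read1)
  ex <- extract_spacers(read1, layout)
  trimmed <- !is.na(ex$spacer)
  gidx <- match(ex$spacer, library$spacer)

  keep <- !is.na(gidx)
  umi <- NULL
  if (with_umi) {
    stopifnot(length(read2) == total)
    from <- layout$umi_slice[1] + 1L
    to <- layout$umi_slice[2]
    umi <- substr(read2, from, to)
    n_ok <- !grepl("N", umi, fixed = TRUE) & nchar(umi) == to - from + 1L
    keep <- keep & n_ok
  }
  mapped <- sum(keep)
  counts <- tabulate(gidx[keep], nbins = nrow(library))
  count_df <- data.frame(guide_id = library$guide_id, gene = library$gene,
                         count = counts, stringsAsFactors = FALSE)

  umi_counts <- NULL
  if (with_umi) {
    dt <- data.table::data.table(guide_id = library$guide_id[gidx[keep]],
                                 umi = umi[keep])
    umi_counts <- as.data.frame(dt[, .(count = .N), by = .(guide_id, umi)])
    umi_counts <- data.frame(sample = rep(sample, nrow(umi_counts)),
                             umi_counts, stringsAsFactors = FALSE)
    umi_counts <- umi_counts[order(umi_counts$guide_id, umi_counts$umi), ]
    rownames(umi_counts) <- NULL
  }

  qc <- data.frame(
    sample = sample,
    total_reads = total,
    mapped_reads = mapped,
    alignment_rate = if (total > 0L) mapped / total else 0,
    zero_count_guides = sum(counts == 0L),
    gini = if (sum(counts) > 0) gini_index(counts) else NA_real_,
    trim_zero_fraction = if (total > 0L) sum(!trimmed) / total else 0,
    stringsAsFactors = FALSE
  )
  class(qc) <- c("count_qc", "data.frame")
  list(counts = count_df, umi_counts = umi_counts, qc = qc)
}

#' Gini index of a count distribution
#'
#' Mean absolute difference form: G = sum_ij |x_i - x_j| / (2 n^2 mu). 0 for
#' perfectly even counts, approaching 1 when reads concentrate on one guide.
#'
#' @param counts non-negative numeric vector with at least one positive value
#' @return Gini coefficient in \[0, 1); NA for an all-zero vector
#' @export
gini_index <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- length(counts)
  mu <- mean(counts)
  if (mu == 0) return(NA_real_)
  # O(n log n) via sorted cumulative form of the double sum
  x <- sort(counts)
  i <- seq_len(n)
  sum((2 * i - n - 1) * x) / (n^2 * mu)
}

#' Sample-level QC gate
#'
#' Default thresholds follow standard sorting-screen filters: alignment rate
#' at least 62.5 percent, at least 2 mapped reads per sorted cell and at
#' least 100 mapped reads per library guide. All thresholds are inclusive.
#'
#' @param qc a `count_qc` row from [count_guides()]
#' @param n_cells number of sorted cells behind the sample (NA skips the rule)
#' @param n_guides library size (used for reads-per-guide; NA skips the rule)
#' @param thresholds list(alignment, reads_per_cell, reads_per_guide)
#' @return list(pass = logical, reasons = character vector of violated rules)
#' @export
apply_sample_qc <- function(qc, n_cells = NA, n_guides = NA,
                            thresholds = list(alignment = 0.625,
                                              reads_per_cell = 2,
                                              reads_per_guide = 100)) {
  reasons <- character(0)
  if (qc$alignment_rate < thresholds$alignment) {
    reasons <- c(reasons, sprintf("alignment<%g", thresholds$alignment))
  }
  if (!is.na(n_cells) &&
      qc$mapped_reads / n_cells < thresholds$reads_per_cell) {
    reasons <- c(reasons, sprintf("reads_per_cell<%g",
                                  thresholds$reads_per_cell))
  }
  if (!is.na(n_guides) &&
      qc$mapped_reads / n_guides < thresholds$reads_per_guide) {
    reasons <- c(reasons, sprintf("reads_per_guide<%g",
                                  thresholds$reads_per_guide))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Assemble a multi-sample count table
#'
#' @param count_list named list of per-sample count data frames (all over the
#'   same library, as returned by [count_guides()])
#' @return data frame: sgRNA, gene, one integer column per sample
#' @export
count_table <- function(count_list) {
  stopifnot(length(count_list) >= 1L)
  base <- count_list[[1L]][, c("guide_id", "gene")]
  out <- data.frame(sgRNA = base$guide_id, gene = base$gene,
                    stringsAsFactors = FALSE)
  for (nm in names(count_list)) {
    stopifnot(identical(count_list[[nm]]$guide_id, base$guide_id))
    out[[nm]] <- count_list[[nm]]$count
  }
  out
}
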