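#' @importFrom data.table data.table fread fwrite setDT setnames rbindlist :=
#' @importFrom stats nls coef resid median sd quantile rbinom rnbinom rmultinom
#'   runif p.adjust complete.cases setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA strings
#'
#' @param n number of strings
#' @param len string length
#' @return character vector of length `n` over A/C/G/T
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Count character mismatches between equal-length strings
#'
#' Vectorised over `x`; `y` is a single pattern of the same width.
#' @keywords internal
str_mismatches <- function(x, y) {
  ny <- nchar(y)
  out <- integer(length(x))
  yc <- strsplit(y, "", fixed = TRUE)[[1]]
  for (j in seq_len(ny)) {
    out <- out + (substr(x, j, j) != yc[j])
  }
  out[nchar(x) < ny] <- NA_integer_
  out
}

#' Reverse complement of DNA strings
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Apply i.i.d. substitution errors to sequences
#'
#' Each base is substituted with probability `rate`, drawing uniformly from
#' the three alternative bases. Vectorised; handles multiple errors per read.
#' @keywords internal
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  flat <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_idx <- findInterval(flat - 1L, ends) + 1L
  pos <- flat - c(0L, ends)[read_idx]
  cur <- substr(rep(seqs[read_idx], 1L), pos, pos)
  # map each base to a uniformly chosen different base
  alt <- vapply(cur, function(b) {
    if (b %in% DNA_BASES) sample(setdiff(DNA_BASES, b), 1L) else "N"
  }, character(1L), USE.NAMES = FALSE)
  # multiple errors may hit the same read: apply in rounds so none is lost
  occ <- stats::ave(seq_along(read_idx), read_idx, FUN = seq_along)
  for (r in seq_len(max(occ))) {
    sel <- occ == r
    idx <- read_idx[sel]
    s <- seqs[idx]
    substr(s, pos[sel], pos[sel]) <- alt[sel]
    seqs[idx] <- s
  }
  seqs
}

#' Write a TSV with an optional provenance header
#' @keywords internal
write_tsv <- function(x, path, header_lines = NULL) {
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), path)
    suppressWarnings(data.table::fwrite(x, path, sep = "\t", append = TRUE,
                                        col.names = TRUE))
  } else {
    data.table::fwrite(x, path, sep = "\t")
  }
  invisible(path)
}

#' Read a TSV, skipping '#' comment lines
#' @keywords internal
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                    skip = grep_first_data_line(path))
}

grep_first_data_line <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  n <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (!startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
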