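#' Synthetic pooled-screen data
#'
#' The generator emulates the statistical structure of an in vivo pooled
#' CRISPR screen with an mRNA guide readout: lentiviral founding of clones
#' carrying one guide and one unique UMI, a transplantation bottleneck,
#' exponential clonal growth with per-gene fitness effects and overdispersed
#' drift, multinomial sequencing-depth sampling, per-base substitution error,
#' and variable-length primer staggers on read 1.
#'
#' @name synthetic_data
NULL

# read-1 layout constants: 8-base anchor = the 3' end of the U6 priming
# region immediately 5' of the spacer; scaffold = standard sgRNA scaffold.
DEFAULT_ANCHOR <- "AAACACCG"
DEFAULT_SCAFFOLD <- "GTTTAAGAGCTAAGCTGGAAACAGCATAGCAAGTTTAAATAAGG"
READ1_LENGTH <- 50L
READ2_LENGTH <- 26L
# constant vector sequence following the UMI on read 2
DEFAULT_UMI_FILL <- "TCTAGACCGGTGACGTCAGGTACGCC"

#' Screen design parameters for simulation
#'
#' Bundles everything the simulator needs: clone founding and bottleneck
#' sizes, growth model, sequencing depth and error, and read-layout details.
#'
#' @param n_clones_founding transduced founder clones per sample
#' @param bottleneck_fraction fraction of founder cells surviving
#'   transplantation (binomial thinning), in (0, 1]
#' @param n_generations generations of in vivo expansion
#' @param fitness_by_gene named numeric vector of per-generation selection
#'   coefficients s (gene -> s; absent genes are neutral, s = 0). A clone of a
#'   gene with coefficient s grows by factor (1+s) per generation.
#' @param depth sequenced read pairs per sample
#' @param error_rate per-base substitution probability, in [0, 0.1]
#' @param umi_length number of random UMI bases at the start of read 2
#' @param stagger_lengths integer set of stagger lengths preceding the anchor
#'   on read 1
#' @param nb_size negative-binomial dispersion (size) of clone growth noise
#' @param n_samples number of independent samples (animals/organs)
#' @param seed RNG seed used by the simulation stages
#' @param anchor,scaffold,umi_fill read-layout constants (defaults shipped)
#' @return a `screen_design` list
#' @export
screen_design <- function(n_clones_founding = 10000L,
                          bottleneck_fraction = 0.1,
                          n_generations = 10L,
                          fitness_by_gene = NULL,
                          depth = 1e6,
                          error_rate = 0.003,
                          umi_length = 12L,
                          stagger_lengths = 0:7,
                          nb_size = 10,
                          n_samples = 1L,
                          seed = 1L,
                          anchor = DEFAULT_ANCHOR,
                          scaffold = DEFAULT_SCAFFOLD,
                          umi_fill = DEFAULT_UMI_FILL) {
  stopifnot(depth >= 0, error_rate >= 0, error_rate <= 0.1,
            umi_length >= 1L, umi_length <= READ2_LENGTH,
            bottleneck_fraction > 0, bottleneck_fraction <= 1,
            n_generations >= 0L, n_clones_founding >= 1L,
            all(stagger_lengths >= 0L))
  design <- list(
    n_clones_founding = as.integer(n_clones_founding),
    bottleneck_fraction = bottleneck_fraction,
    n_generations = as.integer(n_generations),
    fitness_by_gene = fitness_by_gene,
    depth = depth,
    error_rate = error_rate,
    umi_length = as.integer(umi_length),
    stagger_lengths = as.integer(stagger_lengths),
    nb_size = nb_size,
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    anchor = anchor,
    scaffold = scaffold,
    umi_fill = umi_fill
  )
  class(design) <- "screen_design"
  design
}

#' Default fitness preset for a library
#'
#' Essential-gene controls deplete (s < 0); everything else is neutral unless
#' overridden. The default s = -0.3 per generation reflects strong dropout of
#' core-essential genes over a two-week expansion.
#'
#' @param library a `guide_library`
#' @param s_essential selection coefficient for essential control genes
#' @param overrides named numeric vector merged on top of the preset
#' @return named numeric vector gene -> s
#' @export
default_fitness <- function(library, s_essential = -0.3, overrides = NULL) {
  ess <- unique(library$gene[library$category == "essential"])
  s <- stats::setNames(rep(s_essential, length(ess)), ess)
  if (!is.null(overrides)) s[names(overrides)] <- overrides
  s
}

#' Simulate clonal truth for an in vivo screen
#'
#' Founder clones draw their guide uniformly from the library and receive a
#' unique random UMI. Transplantation is modelled as binomial thinning of
#' founder cells at `bottleneck_fraction`. Surviving clones then expand for
#' `n_generations` generations: the final cell count of a clone of gene g is
#' negative-binomial with mean `founding * (1 + s_g)^n_generations` and
#' dispersion `nb_size` (n_generations = 0 leaves counts untouched).
#'
#' @param library a `guide_library`
#' @param design a `screen_design`
#' @return list with `truth` (one clone-truth data frame per sample:
#'   umi, guide_id, gene, founding_count, final_count, and a `degenerate`
#'   attribute flagging fully extinct samples) and `expected_freq`
#'   (per-guide expected read frequencies after selection)
#' @export
simulate_invivo_screen <- function(library, design) {
  stopifnot(inherits(library, "guide_library"), nrow(library) >= 1L)
  set.seed(design$seed)
  s <- design$fitness_by_gene %||% numeric(0)
  s_guide <- ifelse(library$gene %in% names(s), s[library$gene], 0)
  growth <- (1 + s_guide)^design$n_generations
  expected_freq <- stats::setNames(growth / sum(growth), library$guide_id)

  truth <- lapply(seq_len(design$n_samples), function(i) {
    n <- design$n_clones_founding
    gi <- sample.int(nrow(library), n, replace = TRUE)
    umi <- unique_umis(n, design$umi_length)
    founding <- rep(1L, n)
    surv <- rbinom(n, founding, design$bottleneck_fraction)
    if (design$n_generations == 0L) {
      final <- surv
    } else {
      mu <- surv * (1 + s_guide[gi])^design$n_generations
      final <- integer(n)
      pos <- mu > 0
      final[pos] <- rnbinom(sum(pos), size = design$nb_size, mu = mu[pos])
    }
    df <- data.frame(
      umi = umi, guide_id = library$guide_id[gi], gene = library$gene[gi],
      founding_count = founding, final_count = final,
      stringsAsFactors = FALSE
    )
    attr(df, "degenerate") <- sum(final) == 0L
    attr(df, "sample") <- sprintf("sample%02d", i)
    df
  })
  list(truth = truth, expected_freq = expected_freq)
}

unique_umis <- function(n, len, max_rounds = 20L) {
  out <- character(0)
  for (i in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0L) break
    out <- unique(c(out, random_dna(need + ceiling(need * 0.05) + 1L, len)))
  }
  if (length(out) < n) stop("could not draw ", n, " unique UMIs of length ", len)
  out[seq_len(n)]
}

#' Emit paired sequencing reads from simulated clone truth
#'
#' Read 1 carries a variable-length stagger, the constant anchor, the 20-nt
#' spacer and the scaffold, truncated/padded to 50 bases. Read 2 carries the
#' clone UMI followed by constant vector sequence, 26 bases total
#' (`invivo_cropseq`), or constant sequence only (`dna_amplicon`).
#' Reads per clone are multinomial given final cell counts and `depth`;
#' substitution errors are applied i.i.d. at `error_rate`.
#'
#' @param truth one clone-truth data frame from [simulate_invivo_screen()]
#' @param library the `guide_library` the truth was simulated from
#' @param design the `screen_design`
#' @param readout `"invivo_cropseq"` (UMI on read 2) or `"dna_amplicon"`
#' @param sample sample label recorded in the manifest
#' @return list with `read1`, `read2` (character vectors), `id` (read ids) and
#'   `manifest` (data frame: read_id, guide_id, umi, sample)
#' @export
emit_reads <- function(truth, library, design,
                       readout = c("invivo_cropseq", "dna_amplicon"),
                       sample = attr(truth, "sample") %||% "sample01") {
  readout <- match.arg(readout)
  set.seed(design$seed + 1L)
  depth <- as.integer(round(design$depth))
  keep <- truth$final_count > 0
  if (depth == 0L || !any(keep)) {
    return(list(read1 = character(0), read2 = character(0), id = character(0),
                manifest = data.frame(read_id = character(0),
                                      guide_id = character(0),
                                      umi = character(0),
                                      sample = character(0))))
  }
  tt <- truth[keep, , drop = FALSE]
  n_per_clone <- as.integer(rmultinom(1L, depth,
                                      prob = tt$final_count / sum(tt$final_count)))
  clone_idx <- rep.int(seq_len(nrow(tt)), n_per_clone)
  spacer <- tt$spacer_cache %||%
    library$spacer[match(tt$guide_id, library$guide_id)]
  spacer <- spacer[clone_idx]
  umi <- tt$umi[clone_idx]
  n <- length(clone_idx)

  stag_len <- sample(design$stagger_lengths, n, replace = TRUE)
  stag_seq <- vapply(design$stagger_lengths, function(k)
    paste0(rep("T", k), collapse = ""), character(1L))
  names(stag_seq) <- as.character(design$stagger_lengths)
  # staggers are random bases in the primer pool; draw them per read
  stag <- substr(random_dna(n, max(c(design$stagger_lengths, 1L))),
                 1L, stag_len)
  stag[stag_len == 0L] <- ""

  r1 <- paste0(stag, design$anchor, spacer, design$scaffold)
  r1 <- substr(r1, 1L, READ1_LENGTH)
  short <- nchar(r1) < READ1_LENGTH
  if (any(short)) {
    pad <- strrep("A", READ1_LENGTH)
    r1[short] <- substr(paste0(r1[short], pad), 1L, READ1_LENGTH)
  }
  if (readout == "invivo_cropseq") {
    r2 <- substr(paste0(umi, design$umi_fill, strrep("A", READ2_LENGTH)),
                 1L, READ2_LENGTH)
  } else {
    r2 <- rep(substr(paste0(design$umi_fill, strrep("A", READ2_LENGTH)),
                     1L, READ2_LENGTH), n)
  }
  r1 <- mutate_seqs(r1, design$error_rate)
  r2 <- mutate_seqs(r2, design$error_rate)
  ids <- sprintf("%s:read%07d", sample, seq_len(n))
  list(
    read1 = r1, read2 = r2, id = ids,
    manifest = data.frame(read_id = ids, guide_id = tt$guide_id[clone_idx],
                          umi = umi, sample = sample,
                          stringsAsFactors = FALSE)
  )
}

#' Write emitted reads as paired FASTQ files
#'
#' Four-line FASTQ records with Phred+33 dummy quality ("I" throughout).
#'
#' @param reads result of [emit_reads()]
#' @param r1_path,r2_path output FASTQ paths
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_fastq(reads$read1, reads$id, r1_path)
  write_fastq(reads$read2, reads$id, r2_path)
  invisible(c(r1_path, r2_path))
}

write_fastq <- function(seqs, ids, path) {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", strrep("I", nchar(seqs)))
  writeLines(rec, path)
  invisible(path)
}

#' Read a FASTQ file into sequences
#'
#' @param path FASTQ path
#' @return named character vector (names = read ids)
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate a per-organ UMI read-count table
#'
#' Emulates the UMI count distribution of one organ sample: `n_clones` true
#' clones share a fixed sequencing budget (`clone_depth` reads, negative
#' binomial per clone around `clone_depth / n_clones`), on top of
#' `n_background` ambient/artefact UMIs with a heavy-tailed low read count
#' (1 + NB(mu = bg_mu, size = bg_size); the small upper tail that exceeds the
#' knee filter is what anchors the background shelf, as in real organ data).
#'
#' @param n_clones number of true clones
#' @param n_background number of background UMIs
#' @param clone_depth total reads allotted to clones
#' @param clone_size NB dispersion of per-clone reads
#' @param bg_mu,bg_size background read-count parameters
#' @param umi_length UMI width
#' @param seed RNG seed
#' @return data frame: umi, count, is_clone (truth flag)
#' @export
simulate_organ_umis <- function(n_clones, n_background = 50000L,
                                clone_depth = 1e6, clone_size = 2,
                                bg_mu = 1.5, bg_size = 0.25,
                                umi_length = 12L, seed = 1L) {
  set.seed(seed)
  clone_reads <- rnbinom(n_clones, mu = clone_depth / n_clones,
                         size = clone_size) + 1L
  bg_reads <- 1L + rnbinom(n_background, mu = bg_mu, size = bg_size)
  umis <- unique_umis(n_clones + n_background, umi_length)
  data.frame(umi = umis, count = c(clone_reads, bg_reads),
             is_clone = rep(c(TRUE, FALSE), c(n_clones, n_background)),
             stringsAsFactors = FALSE)
}
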