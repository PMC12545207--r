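# Shared fixtures and independent oracles, built in code at test time.

tiny_library <- function(seed = 101) {
  make_library(n_target_genes = 4, guides_per_gene = 2,
               n_essential = 1, n_nonessential = 1, n_safe_harbour = 2,
               seed = seed)
}

# brute-force Gini via the explicit double sum over all ordered pairs
gini_bruteforce <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mu)
}

# independent permutation enumerator (Heap's algorithm, unlike the package's
# recursive prefix construction)
heap_permutations <- function(v) {
  n <- length(v)
  out <- vector("list", factorial(n))
  cnt <- 0L
  c_ <- integer(n)
  a <- v
  cnt <- cnt + 1L; out[[cnt]] <- a
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      cnt <- cnt + 1L; out[[cnt]] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# reference Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact sigmoid points on a log10 rank grid
sigmoid_points <- function(L = -2.5, k = 8, x0 = 3, b = 2.6,
                           x = seq(1.8, 4.5, length.out = 200)) {
  y <- L / (1 + exp(-k * (x - x0))) + b
  data.frame(rank = 10^x, reads = 10^y, log10_rank = x, log10_reads = y)
}

# toy single-exon gene whose full length is coding (ends with a stop)
toy_gene <- function(seed = 7, n_codons = 40) {
  set.seed(seed)
  codons <- c("GCT", "GCA", "CAG", "CAA", "GAA", "TGG", "CGT", "ACG",
              "TTA", "GCC", "AGG", "ATT", "CCG", "AAA", "ACT", "CGA")
  body <- paste0(sample(codons, n_codons - 2, replace = TRUE), collapse = "")
  s <- paste0("ATG", body, "TAA")
  gene_model("TOY", s, exons = matrix(c(0L, nchar(s)), 1),
             cds = matrix(c(0L, nchar(s)), 1))
}

# brute-force guide enumeration oracle: test every position/strand directly
enumerate_bruteforce <- function(model, editor) {
  seqc <- model$sequence
  n <- nchar(seqc)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
  region <- cbind(pmax(0L, model$exons[, 1] - model$flank),
                  pmin(n, model$exons[, 2] + model$flank))
  in_region <- function(s0) any(s0 < region[, 2] & s0 + 20L > region[, 1])
  res <- list()
  for (p in 0:(n - 20L)) {
    # plus strand
    sp <- substr(seqc, p + 1, p + 20)
    pam <- substr(seqc, p + 21, p + 23)
    ok <- in_region(p) &&
      (editor$pam_mode == "pamless" ||
         (nchar(pam) == 3 && substr(pam, 2, 3) == "GG"))
    if (ok) res[[length(res) + 1L]] <- data.frame(
      spacer = sp, pam = pam, strand = "+", start = p)
    # minus strand: protospacer covering plus positions [q, q+20)
    q <- n - (p + 20L)
    sp_m <- substr(rc, p + 1, p + 20)
    pam_m <- substr(rc, p + 21, p + 23)
    ok_m <- in_region(q) &&
      (editor$pam_mode == "pamless" ||
         (nchar(pam_m) == 3 && substr(pam_m, 2, 3) == "GG"))
    if (ok_m) res[[length(res) + 1L]] <- data.frame(
      spacer = sp_m, pam = pam_m, strand = "-", start = q)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(spacer = character(0)))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

random_gene_model <- function(seed, len = 300) {
  set.seed(seed)
  s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  # two exons with an intron; CDS = exons (may contain stops -> bypass
  # translation validation, irrelevant for enumeration tests)
  e1 <- c(10L, 110L)
  e2 <- c(160L, 260L)
  m <- list(name = paste0("R", seed), sequence = s,
            exons = rbind(e1, e2), cds = rbind(e1, e2), flank = 20L,
            protein = "")
  class(m) <- "gene_model"
  m
}
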