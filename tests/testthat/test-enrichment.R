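make_counts <- function(m, genes = NULL) {
  n <- nrow(m)
  data.frame(sgRNA = paste0("g", seq_len(n)),
             gene = genes %||% rep(paste0("G", seq_len(n %/% 2)), each = 2),
             m, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("median-ratio normalization has the DESeq-style fixed points", {
  set.seed(61)
  base <- rpois(40, 200) + 1
  counts <- make_counts(data.frame(s1 = base, s2 = base))
  nrm <- normalize_counts(counts, "median_ratio")
  expect_equal(unname(nrm$size_factors), c(1, 1))
  expect_equal(nrm$normalized$s1, nrm$normalized$s2)

  doubled <- make_counts(data.frame(s1 = base, s2 = 2L * base))
  nrm2 <- normalize_counts(doubled, "median_ratio")
  expect_equal(unname(nrm2$size_factors[2] / nrm2$size_factors[1]), 2,
               tolerance = 1e-12)
  expect_equal(nrm2$normalized$s1, nrm2$normalized$s2, tolerance = 1e-12)
})

test_that("control-gene normalization anchors controls at zero lfc", {
  set.seed(62)
  base <- rpois(40, 500) + 1
  genes <- c(rep("TGT", 20), rep("NEG", 20))
  test <- ifelse(genes == "TGT", 5L * base, base)
  counts <- make_counts(data.frame(d0 = base, d14 = test), genes = genes)
  nrm <- normalize_counts(counts, "control_genes", control_set = "NEG")
  lfc <- guide_lfc(nrm$normalized$d14, nrm$normalized$d0,
                   counts$sgRNA, counts$gene, pseudocount = 0.5)
  expect_equal(mean(lfc$lfc[lfc$gene == "NEG"]), 0, tolerance = 0.05)
  expect_equal(mean(lfc$lfc[lfc$gene == "TGT"]), log2(5), tolerance = 0.05)

  expect_error(normalize_counts(counts, "control_genes"), "control")
})

test_that("guide_lfc arithmetic and zero-in-both removal", {
  lfc <- guide_lfc(test = c(31, 0, 5), ref = c(7, 0, 5),
                   guide_id = c("a", "b", "c"), gene = c("A", "B", "C"))
  expect_equal(lfc$lfc[lfc$guide_id == "a"], 2.0)
  expect_false("b" %in% lfc$guide_id)  # zero in both samples: dropped
  expect_equal(lfc$lfc[lfc$guide_id == "c"], 0)
})

test_that("gene_test equals an independent exhaustive oracle", {
  set.seed(63)
  lfc <- round(rnorm(6), 3)
  st <- data.frame(guide_id = paste0("g", 1:6),
                   gene = rep(c("A", "B", "C"), each = 2), lfc = lfc)
  res <- gene_test(st, exhaustive = TRUE)

  g_idx <- rep(1:3, each = 2)
  perms <- heap_permutations(lfc)
  obs <- as.vector(rowsum(lfc, g_idx)) / 2
  p_oracle <- vapply(1:3, function(j) {
    mean(vapply(perms, function(v)
      abs(mean(v[g_idx == j])) >= abs(obs[j]) - 1e-12, logical(1)))
  }, numeric(1))
  expect_equal(res$p_value[match(c("A", "B", "C"), res$gene)], p_oracle,
               tolerance = 1e-12)
  expect_equal(res$fdr, bh_stepup(res$p_value), tolerance = 1e-12)
})

test_that("identical guide lfcs give p = 1 for every gene", {
  st <- data.frame(guide_id = paste0("g", 1:6),
                   gene = rep(c("A", "B", "C"), each = 2), lfc = rep(0.7, 6))
  res <- gene_test(st, exhaustive = TRUE)
  expect_true(all(res$p_value == 1))
  res_mc <- gene_test(st, n_perm = 200, seed = 2)
  expect_true(all(res_mc$p_value == 1))
})

test_that("gene_test refuses tiny permutation counts", {
  st <- data.frame(guide_id = paste0("g", 1:4),
                   gene = rep(c("A", "B"), each = 2), lfc = rnorm(4))
  expect_error(gene_test(st, n_perm = 50), "at least 100")
})

test_that("a strong selective effect is detected against neutral genes", {
  lib <- make_library(40, 4, 0, 0, 0, seed = 64)
  design <- screen_design(n_clones_founding = 16000, bottleneck_fraction = 1,
                          n_generations = 10,
                          fitness_by_gene = c(GENE001 = 0.5), seed = 65)
  tr <- simulate_invivo_screen(lib, design)$truth[[1]]
  agg <- function(v) as.vector(rowsum(v, factor(tr$guide_id,
                                                levels = lib$guide_id)))
  counts <- data.frame(sgRNA = lib$guide_id, gene = lib$gene,
                       d0 = agg(tr$founding_count), d14 = agg(tr$final_count))
  # with 40 genes, BH needs p well below 2.5e-4 for fdr < 0.01: use enough
  # permutations for the smallest attainable p to clear it
  res <- screen_test(counts, "d14", "d0", n_perm = 5000, seed = 66)
  expect_true(res$hit[res$gene == "GENE001"])
  neutral <- res[res$gene != "GENE001", ]
  expect_gte(mean(!neutral$hit), 0.95)
})

test_that("internal replicates average into the gene score", {
  r1 <- data.frame(guide_id = c("g1", "g2"), gene = "A", lfc = c(1, 3))
  r2 <- data.frame(guide_id = c("g1", "g2"), gene = "A", lfc = c(2, 4))
  res <- gene_test(NULL, replicate_lfcs = list(r1, r2), n_perm = 100,
                   seed = 1)
  expect_equal(res$lfc, mean(c(1.5, 3.5)))
})

test_that("call_hits uses strict inequalities on both thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    lfc = c(1.5, 2.0, 2.0, 1.6),
                    fdr = c(0.001, 0.005, 0.02, 0.01))
  out <- call_hits(res)
  expect_identical(out$hit, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("ssmd reproduces hand-computed examples", {
  # equal distributions
  v <- c(E1 = -1, E2 = 0, E3 = 1, N1 = -1, N2 = 0, N3 = 1)
  s0 <- ssmd(v, c("E1", "E2", "E3"), c("N1", "N2", "N3"))
  expect_equal(s0$ssmd, 0)

  # means -2 and 0, both sds 1 -> -2/sqrt(2)
  e <- c(-3, -1)  # mean -2, sd sqrt(2)
  ne <- c(0.5, -0.5)  # mean 0, sd sqrt(0.5)
  s1 <- ssmd(setNames(c(e, ne), c("E", "E", "N", "N")), "E", "N")
  expect_equal(s1$ssmd, -2 / sqrt(2.5), tolerance = 1e-6)
  expect_equal(s1$ssmd, -1.2649, tolerance = 1e-4)

  s2 <- ssmd(setNames(c(-3, -2, -1, 1, 0, -1), rep(c("E", "N"), each = 3)),
             "E", "N")
  expect_equal(s2$ssmd, -2 / sqrt(2), tolerance = 1e-6)
  expect_equal(s2$ssmd, -1.4142, tolerance = 1e-4)

  expect_error(ssmd(v, c("E1", "N1"), c("N1", "N2")), "disjoint")
})

test_that("ssmd monotonicity: deeper dropout decreases it, noise shrinks it", {
  set.seed(67)
  for (i in 1:5) {
    e <- rnorm(20, mean = -2, sd = 0.5)
    ne <- rnorm(20, mean = 0, sd = 0.5)
    v1 <- ssmd(setNames(c(e, ne), rep(c("E", "N"), each = 20)), "E", "N")
    v2 <- ssmd(setNames(c(e - 1, ne), rep(c("E", "N"), each = 20)), "E", "N")
    expect_lt(v2$ssmd, v1$ssmd)
    v3 <- ssmd(setNames(c(scale(e)[, 1] * 2 + mean(e), ne),
                        rep(c("E", "N"), each = 20)), "E", "N")
    expect_lt(abs(v3$ssmd), abs(v1$ssmd))
  }
})

test_that("z_normalize matches arithmetic and is location invariant", {
  pop <- c(0, 0, 2, -2)
  z <- z_normalize(2, reference = pop)
  expect_equal(z, 2 / sd(pop), tolerance = 1e-12)
  expect_equal(z, 1.2247, tolerance = 1e-4)

  whole <- z_normalize(pop)
  expect_equal(mean(whole), 0, tolerance = 1e-12)
  expect_equal(sd(whole), 1, tolerance = 1e-12)

  expect_equal(z_normalize(pop + 5), whole, tolerance = 1e-12)
  expect_error(z_normalize(rep(1, 4)), "zero sd")
})

test_that("gene_test fdr matches the reference step-up implementation", {
  set.seed(68)
  for (i in 1:3) {
    n_genes <- sample(20:60, 1)
    st <- data.frame(guide_id = paste0("g", seq_len(4 * n_genes)),
                     gene = rep(paste0("G", seq_len(n_genes)), each = 4),
                     lfc = rnorm(4 * n_genes))
    res <- gene_test(st, n_perm = 200, seed = i)
    expect_equal(res$fdr, bh_stepup(res$p_value), tolerance = 1e-12)
  }
})
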