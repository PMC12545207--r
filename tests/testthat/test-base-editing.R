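abe <- function(pam = "NGG") editor_spec("ABEmax", "A>G", pam)
cbe <- function(pam = "NGG") editor_spec("AncBE4max", "C>T", pam)

test_that("guide enumeration equals a brute-force scan on random genes", {
  for (seed in 1:12) {
    model <- random_gene_model(seed)
    for (mode in c("NGG", "pamless")) {
      ed <- abe(mode)
      got <- enumerate_guides(model, ed)
      want <- enumerate_bruteforce(model, ed)
      expect_equal(nrow(got), nrow(want), info = paste(seed, mode))
      expect_identical(got$spacer, want$spacer)
      expect_identical(got$strand, want$strand)
      expect_identical(got$start, as.integer(want$start))
    }
  }
})

test_that("enumeration edge cases", {
  # sequence shorter than a guide+PAM yields nothing
  short <- list(name = "S", sequence = strrep("A", 15),
                exons = matrix(c(0L, 15L), 1), cds = matrix(c(0L, 15L), 1),
                flank = 0L, protein = "")
  class(short) <- "gene_model"
  expect_equal(nrow(enumerate_guides(short, abe())), 0)

  # no G anywhere: zero NGG guides on the plus strand
  noG <- list(name = "N", sequence = paste0(strrep("AT", 30)),
              exons = matrix(c(0L, 60L), 1), cds = matrix(c(0L, 60L), 1),
              flank = 0L, protein = "")
  class(noG) <- "gene_model"
  g <- enumerate_guides(noG, abe())
  expect_false(any(g$strand == "+"))

  # pamless: every position where a 20-mer fits in-region, both strands
  model <- random_gene_model(99, len = 100)
  model$exons <- matrix(c(0L, 100L), 1)
  model$cds <- matrix(c(0L, 100L), 1)
  model$flank <- 0L
  g2 <- enumerate_guides(model, abe("pamless"))
  expect_equal(nrow(g2), 2 * (100 - 20 + 1))
})

test_that("exclusion filters flag T stretches and BsmBI sites", {
  guides <- data.frame(
    spacer = c("ACGTTTTACGACGTACGTAC",   # TTTT
               "ACGACGTCTCACGTACGTAC",   # BsmBI forward
               "ACGAGAGACGACGTACGTAC",   # BsmBI reverse complement
               "ACGACGTACGACGTACGTAC"),  # clean
    pam = c("AGG", "AGG", "AGG", "AGG"), stringsAsFactors = FALSE)
  out <- filter_guides(guides)
  expect_identical(out$t_stretch, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$bsmbi, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(out$excluded, c(TRUE, TRUE, TRUE, FALSE))

  # BsmBI can straddle the spacer/PAM boundary
  straddle <- data.frame(spacer = paste0(strrep("A", 16), "CGTC"),
                         pam = "TCA", stringsAsFactors = FALSE)
  expect_true(filter_guides(straddle)$bsmbi)

  # idempotence: filtering the kept set excludes nothing further
  kept <- out[!out$excluded, ]
  expect_false(any(filter_guides(kept[, c("spacer", "pam")])$excluded))
})

test_that("predicted consequences match codon arithmetic", {
  # CDS: ATG CAG GCA TAC TAA ; gene entirely coding
  s <- "ATGCAGGCATACTAA"
  gm <- gene_model("T1", s, exons = matrix(c(0L, 15L), 1),
                   cds = matrix(c(0L, 15L), 1))
  expect_equal(gm$protein, "MQAY")

  # C-to-T at the CAG codon's C (position 4 on the plus strand) -> TAG stop
  g_plus <- data.frame(guide_id = "gp", spacer = substr(s, 4, 15),
                       strand = "+", start = 3L)
  # spacer shorter than 20 never occurs in real designs; embed instead
  seq2 <- paste0("GATTACAGATTACA", s, "GATTACAGATTACA")
  gm2 <- gene_model("T2", seq2, exons = matrix(c(14L, 29L), 1),
                    cds = matrix(c(14L, 29L), 1))
  # choose guide with spacer position 4 (1-based) at genomic 17 (the C of CAG)
  g <- data.frame(guide_id = "g1", spacer = substr(seq2, 15, 34),
                  strand = "+", start = 14L)
  pe <- predict_edits(g, cbe(), gm2, window = 4:4)
  expect_equal(pe$consequence, "nonsense")
  expect_equal(pe$outcomes$ref, "C")
  expect_equal(pe$outcomes$alt, "T")
  expect_equal(pe$outcomes$residue, 2L)
  expect_equal(pe$outcomes$aa_ref, "Q")
  expect_equal(pe$outcomes$aa_alt, "*")

  # A-to-G at a synonymous third position: GCA -> GCG, both Ala
  g2 <- data.frame(guide_id = "g2", spacer = substr(seq2, 10, 29),
                   strand = "+", start = 9L)
  # genomic position 22 = third base of GCA codon; spacer pos = 22-9+1 = 14
  pe2 <- predict_edits(g2, abe(), gm2, window = 14:14)
  expect_equal(pe2$consequence, "silent")

  # no editable base in the window -> empty outcome
  pe3 <- predict_edits(g2, cbe(), gm2, window = 14:14)
  expect_true(is.na(pe3$consequence))
  expect_equal(nrow(pe3$outcomes), 0)
})

test_that("splice-site edits take precedence and introns/UTRs annotate", {
  # exon1 [0,30) - intron [30,50) with donor GT / acceptor AG - exon2 [50,80)
  s <- paste0("ATGGCTCAGGTTCCGGAAGCTTGGCGTACG",
              "GTAAGTCCCCCCCCCCCCAG",
              "TTAGCCAGGATTTGGCCGCAGACTCCGTAA")
  exons <- rbind(c(0L, 30L), c(50L, 80L))
  cds <- rbind(c(3L, 30L), c(50L, 77L))  # exon ends are UTR here
  gm <- list(name = "SP", sequence = s, exons = exons, cds = cds,
             flank = 20L, protein = "")
  class(gm) <- "gene_model"

  # acceptor-site A at genomic position 48 (0-based): splice_site
  g <- data.frame(guide_id = "gd", spacer = substr(s, 35, 54), strand = "+",
                  start = 34L)
  stopifnot(substr(s, 49, 49) == "A")
  pe <- predict_edits(g, abe("pamless"), gm, window = 15:15)
  expect_equal(pe$consequence, "splice_site")

  # mid-intron C at genomic position 40: intron
  g_in <- data.frame(guide_id = "gi", spacer = substr(s, 30, 49),
                     strand = "+", start = 29L)
  stopifnot(substr(s, 41, 41) == "C")
  pe_in <- predict_edits(g_in, cbe("pamless"), gm, window = 12:12)
  expect_equal(pe_in$consequence, "intron")

  # exonic base outside the CDS at genomic position 0: utr
  g_utr <- data.frame(guide_id = "gu", spacer = substr(s, 1, 20),
                      strand = "+", start = 0L)
  stopifnot(substr(s, 1, 1) == "A")
  pe_utr <- predict_edits(g_utr, abe("pamless"), gm, window = 1:1)
  expect_equal(pe_utr$consequence, "utr")
})

test_that("control design fills all four quota cells deterministically", {
  set.seed(82)
  region <- paste0(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  ctrl <- design_controls(abe(), region, n = 8, seed = 5)
  expect_equal(nrow(ctrl), 8)
  cells <- table(ctrl$group, ctrl$pam_class)
  expect_true(all(cells == 2))
  # window composition honoured
  w <- substr(ctrl$spacer, 5, 7)
  expect_true(all((grepl("A", w) & !grepl("C", w))[ctrl$group == "A_only"]))
  expect_true(all((grepl("C", w) & !grepl("A", w))[ctrl$group == "C_only"]))

  ctrl2 <- design_controls(abe(), region, n = 8, seed = 5)
  expect_identical(ctrl, ctrl2)

  # all-G/T region cannot satisfy A-only or C-only windows
  gt <- paste0(strrep("GT", 200))
  expect_error(design_controls(abe(), gt, n = 8, seed = 1), "quota")
})

test_that("self-edit expansion obeys the 2^m - 1 law", {
  lib <- data.frame(
    guide_id = c("a", "b", "c"),
    spacer = c("CCCACACCCCCCCCCCCCCC",   # A at 4, A at 6 -> m=2
               "CCCCCCCCCCCCCCCCCCCC",   # m=0
               "CCCAAACCCCCCCCCCCCCC"),  # A at 4,5,6 -> m=3
    stringsAsFactors = FALSE)
  ref <- expand_self_edit_reference(lib, abe())
  expect_equal(sum(ref$origin == "self_edited" & ref$guide_id == "a"), 3)
  expect_equal(sum(ref$origin == "self_edited" & ref$guide_id == "b"), 0)
  expect_equal(sum(ref$origin == "self_edited" & ref$guide_id == "c"), 7)
  expect_false(any(duplicated(ref$sequence)))
})

test_that("colliding variants are dropped, parents keep their originals", {
  # two spacers whose single edits converge on the same sequence
  lib <- data.frame(
    guide_id = c("p", "q"),
    spacer = c("CCCACGCCCCCCCCCCCCCC",   # A4 -> G gives CCCGCG...
               "CCCGCACCCCCCCCCCCCCC"),  # A6 -> G gives CCCGCG...
    stringsAsFactors = FALSE)
  expect_warning(ref <- expand_self_edit_reference(lib, abe()), "collided")
  expect_true(all(c("p", "q") %in% ref$guide_id[ref$origin == "original"]))
  expect_false(any(duplicated(ref$sequence)))
})

test_that("expanded references recover self-edited reads, plain ones do not", {
  lib <- make_library(20, 4, 0, 0, 0, seed = 83)
  ed <- abe()
  ref <- expand_self_edit_reference(lib, ed)
  set.seed(84)
  n <- 5000
  idx <- sample.int(nrow(lib), n, replace = TRUE)
  reads <- lib$spacer[idx]
  # self-edit 30% of reads carrying an editable base
  editable <- vapply(reads, function(s) {
    any(strsplit(s, "")[[1]][4:8] == "A")
  }, logical(1), USE.NAMES = FALSE)
  sel <- which(editable & runif(n) < 0.3)
  reads[sel] <- vapply(reads[sel], function(s) {
    sp <- strsplit(s, "")[[1]]
    hits <- (4:8)[sp[4:8] == "A"]
    take <- hits[runif(length(hits)) < 0.7]
    if (length(take) == 0) take <- hits[1]
    sp[take] <- "G"
    paste0(sp, collapse = "")
  }, character(1), USE.NAMES = FALSE)

  with_exp <- count_spacers(reads, ref)
  plain <- count_spacers(reads, data.frame(guide_id = lib$guide_id,
                                           sequence = lib$spacer))
  expect_gte(with_exp$n_assigned / n, 0.99)
  n_edited <- sum(reads != lib$spacer[idx])
  expect_equal(plain$n_assigned, n - n_edited)
  # per-guide totals under expansion match the true draw
  truth <- as.integer(table(factor(lib$guide_id[idx],
                                   levels = unique(ref$guide_id))))
  expect_identical(with_exp$counts$count, truth)
})

test_that("validation-guide selection takes the union of per-donor tops", {
  set.seed(85)
  z_same <- matrix(rnorm(100), 100, 2, dimnames = list(paste0("g", 1:100)))
  z_same[, 2] <- z_same[, 1]
  sel <- select_validation_guides(z_same, fraction = 0.035)
  expect_length(sel, ceiling(0.035 * 100))  # identical donors: one set of 4

  z_anti <- z_same
  z_anti[, 2] <- -z_anti[, 1]
  sel2 <- select_validation_guides(z_anti, fraction = 0.035)
  expect_gt(length(sel2), 4)

  expect_length(select_validation_guides(z_same, fraction = 0), 0)

  # depleted direction selects the other tail
  dep <- select_validation_guides(z_same, fraction = 0.035,
                                  direction = "depleted")
  expect_false(any(dep %in% sel))
})

test_that("mutagenesis map averages z per residue and labels the top", {
  effects <- data.frame(guide_id = c("g1", "g2", "g3"),
                        z_lfc = c(3, 1, 3))
  ann <- data.frame(guide_id = c("g1", "g2", "g3", "g3"),
                    residue = c(16L, 16L, 20L, NA),
                    consequence = c("missense", "missense", "nonsense",
                                    "intron"),
                    aa_ref = c("G", "G", "Q", NA),
                    aa_alt = c("D", "E", "*", NA))
  mm <- mutagenesis_map(effects, ann, top_n = 1)
  expect_equal(mm$map$mean_z[mm$map$residue == 16], 2)
  expect_equal(mm$map$mean_z[mm$map$residue == 20], 3)
  expect_equal(mm$top$label, "Q20*")

  # silent/utr guides never enter the map
  ann2 <- ann
  ann2$consequence <- "silent"
  empty <- mutagenesis_map(effects, ann2)
  expect_equal(nrow(empty$map), 0)
})

test_that("mutagenesis map recovers planted hot residues", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n_res <- 60
    hot <- sample(n_res, 3)
    guides <- data.frame(guide_id = paste0("g", 1:180),
                         z_lfc = rnorm(180, 0, 0.5))
    ann <- data.frame(guide_id = guides$guide_id,
                      residue = rep(1:n_res, each = 3),
                      consequence = "missense", aa_ref = "A", aa_alt = "V")
    boost <- ann$residue %in% hot
    guides$z_lfc[boost] <- guides$z_lfc[boost] + 3
    mm <- mutagenesis_map(guides, ann, top_n = 3)
    hits <- hits + sum(hot %in% mm$top$residue)
  }
  expect_gte(hits / 60, 0.9)
})

test_that("editing quantification follows the conversion + indel-free rule", {
  ref <- "ACGTACGTAAGGCCTTACGATCGATCGGATCCGTAGCTAGCTAACCGGTT"
  expected <- data.frame(pos = c(9, 10), ref = c("A", "A"),
                         alt = c("G", "G"))
  edited1 <- ref; substr(edited1, 9, 9) <- "G"
  edited_both <- ref; substr(edited_both, 9, 10) <- "GG"
  with_del <- paste0(substr(edited1, 1, 20), substr(edited1, 22, 50))
  with_ins <- paste0(substr(edited1, 1, 20), "T", substr(edited1, 21, 50))
  other_sub <- ref; substr(other_sub, 30, 30) <- "A"

  q <- quantify_editing(c(ref, edited1, edited_both, with_del, with_ins,
                          other_sub), ref, expected)
  # edited: edited1 and edited_both only
  expect_equal(q$n_edited, 2)
  expect_equal(q$fraction_edited, 2 / 6)
  expect_equal(q$n_excluded, 0)

  none <- quantify_editing(rep(ref, 4), ref, expected)
  expect_equal(none$fraction_edited, 0)

  junk <- strrep("T", 50)
  qj <- quantify_editing(c(edited1, junk), ref, expected)
  expect_equal(qj$n_excluded, 1)
  expect_equal(qj$fraction_edited, 1)
})
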