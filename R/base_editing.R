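#' Tiling base-editing library design and quantification
#'
#' Base editors convert A to G (ABE) or C to T (CBE) inside a window of the
#' protospacer without double-strand breaks. A tiling library enumerates all
#' guides across a gene body (all exons plus a flank into each intron/UTR),
#' removes guides that break gRNA transcription (T stretches) or cloning
#' (BsmBI sites), and annotates the mutations each guide introduces by
#' re-translating the edited CDS. Because near-PAM-less editors also edit the
#' integrated gRNA cassette itself, counting uses an expanded reference that
#' includes all self-edited spacer variants. Spacer positions are numbered
#' 1..20 from the PAM-distal end.
#'
#' @name base_editing
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
SEVERITY <- c(nonsense = 1L, splice_site = 2L, missense = 3L, silent = 4L,
              utr = 5L, intron = 6L)

#' Gene model on a genomic segment
#'
#' Coordinates are 0-based half-open on `sequence` (the plus strand of the
#' provided segment).
#'
#' @param name gene symbol
#' @param sequence genomic sequence (character, A/C/G/T)
#' @param exons two-column matrix (start, end) of exon intervals, sorted and
#'   non-overlapping
#' @param cds two-column matrix of coding intervals (within exons); their
#'   concatenation in order is the CDS, which must translate without an
#'   internal stop
#' @param flank design flank into introns/UTRs (default 20)
#' @return a `gene_model` list
#' @export
gene_model <- function(name, sequence, exons, cds, flank = 20L) {
  exons <- matrix(as.integer(exons), ncol = 2L)
  cds <- matrix(as.integer(cds), ncol = 2L)
  stopifnot(all(exons[, 2] > exons[, 1]), all(cds[, 2] > cds[, 1]))
  if (nrow(exons) > 1L) {
    stopifnot(all(diff(exons[, 1]) > 0),
              all(exons[-1L, 1] >= exons[-nrow(exons), 2]))
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside) stop("cds interval ", i, " is not contained in an exon")
  }
  model <- list(name = name, sequence = toupper(sequence), exons = exons,
                cds = cds, flank = as.integer(flank))
  prot <- translate_cds(model$sequence, cds)
  if (grepl("\\*.", prot)) stop("spliced CDS contains an internal stop codon")
  model$protein <- sub("\\*$", "", prot)
  class(model) <- "gene_model"
  model
}

splice_seq <- function(sequence, intervals) {
  paste0(vapply(seq_len(nrow(intervals)), function(i)
    substr(sequence, intervals[i, 1] + 1L, intervals[i, 2]), character(1L)),
    collapse = "")
}

translate_cds <- function(sequence, cds) {
  s <- splice_seq(sequence, cds)
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (nchar(s) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Base-editor specification
#'
#' @param editor_name label (e.g. "ABEmax", "CBE4max-SpRY")
#' @param conversion `"A>G"` or `"C>T"` on the protospacer strand
#' @param pam_mode `"NGG"` or `"pamless"`
#' @param design_window spacer positions (1-based, PAM-distal end = 1) used
#'   when designing mutation-specific or control guides (default 5..7, the
#'   central editing window)
#' @param self_edit_window spacer positions considered editable on the
#'   integrated cassette itself (default 4..8)
#' @return an `editor_spec` list
#' @export
editor_spec <- function(editor_name, conversion = c("A>G", "C>T"),
                        pam_mode = c("NGG", "pamless"),
                        design_window = 5:7, self_edit_window = 4:8) {
  conversion <- match.arg(conversion)
  pam_mode <- match.arg(pam_mode)
  stopifnot(all(design_window >= 1L & design_window <= 20L),
            all(self_edit_window >= 1L & self_edit_window <= 20L))
  ref <- substr(conversion, 1L, 1L)
  alt <- substr(conversion, 3L, 3L)
  structure(list(editor_name = editor_name, ref = ref, alt = alt,
                 pam_mode = pam_mode,
                 design_window = as.integer(design_window),
                 self_edit_window = as.integer(self_edit_window)),
            class = "editor_spec")
}

design_region <- function(model) {
  iv <- cbind(pmax(0L, model$exons[, 1] - model$flank),
              pmin(nchar(model$sequence), model$exons[, 2] + model$flank))
  iv
}

overlaps_region <- function(start0, end0, region) {
  out <- rep(FALSE, length(start0))
  for (i in seq_len(nrow(region))) {
    out <- out | (start0 < region[i, 2] & end0 > region[i, 1])
  }
  out
}

#' Enumerate candidate guides across a gene model
#'
#' Scans both strands of the model sequence. In NGG mode a guide requires the
#' trinucleotide immediately 3' of the 20-mer protospacer to match NGG; in
#' PAM-less mode every position where a full 20-mer fits is a guide. A guide
#' is kept when its protospacer overlaps the design region (exons +/- flank).
#'
#' @param model a [gene_model()]
#' @param editor an [editor_spec()]
#' @return data frame: guide_id, spacer, pam, strand, start (0-based genomic
#'   start of the protospacer on the plus strand)
#' @export
enumerate_guides <- function(model, editor) {
  seqlen <- nchar(model$sequence)
  need_pam <- editor$pam_mode == "NGG"
  if (seqlen < (if (need_pam) 23L else 20L)) {
    return(data.frame(guide_id = character(0), spacer = character(0),
                      pam = character(0), strand = character(0),
                      start = integer(0)))
  }
  region <- design_region(model)
  rows <- list()
  # plus strand: protospacer [p, p+20), PAM [p+20, p+23)
  starts <- 0:(seqlen - 20L)
  spacer <- substr(rep(model$sequence, length(starts)),
                   starts + 1L, starts + 20L)
  pam <- substr(rep(model$sequence, length(starts)),
                starts + 21L, starts + 23L)
  ok <- overlaps_region(starts, starts + 20L, region)
  if (need_pam) ok <- ok & nchar(pam) == 3L & substr(pam, 2L, 3L) == "GG"
  if (any(ok)) {
    rows[[1L]] <- data.frame(spacer = spacer[ok], pam = pam[ok],
                             strand = "+", start = starts[ok],
                             stringsAsFactors = FALSE)
  }
  # minus strand: protospacer is revcomp of [q, q+20); PAM revcomp of
  # [q-3, q)
  rc <- revcomp(model$sequence)
  starts_rc <- 0:(seqlen - 20L)  # on the revcomp sequence
  spacer_m <- substr(rep(rc, length(starts_rc)), starts_rc + 1L,
                     starts_rc + 20L)
  pam_m <- substr(rep(rc, length(starts_rc)), starts_rc + 21L,
                  starts_rc + 23L)
  g_start <- seqlen - (starts_rc + 20L)  # plus-strand start of protospacer
  ok_m <- overlaps_region(g_start, g_start + 20L, region)
  if (need_pam) ok_m <- ok_m & nchar(pam_m) == 3L & substr(pam_m, 2L, 3L) == "GG"
  if (any(ok_m)) {
    rows[[2L]] <- data.frame(spacer = spacer_m[ok_m], pam = pam_m[ok_m],
                             strand = "-", start = g_start[ok_m],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(guide_id = character(0), spacer = character(0),
                      pam = character(0), strand = character(0),
                      start = integer(0)))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$guide_id <- sprintf("%s_%05d_%s", model$name, out$start, out$strand)
  rownames(out) <- NULL
  out[, c("guide_id", "spacer", "pam", "strand", "start")]
}

#' Exclusion filters for designed guides
#'
#' Excludes guides whose spacer contains a run of four or more T (premature
#' pol III termination) and guides whose spacer plus PAM context contains a
#' BsmBI recognition site (CGTCTC or its reverse complement GAGACG), which
#' would be cut during Golden Gate / Gibson cloning.
#'
#' @param guides data frame with columns spacer and pam
#' @return `guides` with logical columns `t_stretch`, `bsmbi`, `excluded`
#' @export
filter_guides <- function(guides) {
  ctx <- paste0(guides$spacer, guides$pam)
  guides$t_stretch <- grepl("TTTT", guides$spacer, fixed = TRUE)
  guides$bsmbi <- grepl("CGTCTC", ctx, fixed = TRUE) |
    grepl("GAGACG", ctx, fixed = TRUE)
  guides$excluded <- guides$t_stretch | guides$bsmbi
  guides
}

# genomic 0-based coordinate of spacer position i (1 = PAM-distal)
spacer_pos_to_genomic <- function(start, strand, i) {
  ifelse(strand == "+", start + i - 1L, start + 20L - i)
}

classify_site <- function(pos0, model) {
  ex <- model$exons
  n_ex <- nrow(ex)
  # splice sites: the two intronic bases flanking internal exon boundaries
  for (i in seq_len(n_ex)) {
    if (i < n_ex && pos0 >= ex[i, 2] && pos0 <= ex[i, 2] + 1L) {
      return("splice_site")  # donor side
    }
    if (i > 1L && pos0 >= ex[i, 1] - 2L && pos0 <= ex[i, 1] - 1L) {
      return("splice_site")  # acceptor side
    }
  }
  in_cds <- any(pos0 >= model$cds[, 1] & pos0 < model$cds[, 2])
  if (in_cds) return("cds")
  in_exon <- any(pos0 >= ex[, 1] & pos0 < ex[, 2])
  if (in_exon) return("utr")
  "intron"
}

cds_offset <- function(pos0, cds) {
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    if (pos0 >= cds[i, 1] && pos0 < cds[i, 2]) {
      return(off + (pos0 - cds[i, 1]))
    }
    off <- off + (cds[i, 2] - cds[i, 1])
  }
  NA_integer_
}

#' Predict editing outcomes of one guide
#'
#' Converts every editor reference base inside the chosen spacer window
#' (jointly) and annotates each edited base: `splice_site` when it falls in
#' the two intronic bases at an exon boundary, otherwise by re-translating
#' the spliced CDS carrying all window edits (`nonsense` when a stop is
#' introduced, `missense`/`silent` from the protein comparison), and
#' `utr`/`intron` outside the CDS. The summary consequence is the most severe
#' per-base outcome (nonsense > splice_site > missense > silent > utr >
#' intron).
#'
#' @param guide one row of [enumerate_guides()] output (guide_id, spacer,
#'   strand, start)
#' @param editor an [editor_spec()]
#' @param model the [gene_model()] the guide was designed on
#' @param window spacer positions to edit (default the editor's design
#'   window)
#' @return list(outcomes = data frame (spacer_pos, genomic_pos, ref, alt,
#'   consequence, residue, aa_ref, aa_alt), consequence = summary string or
#'   NA when no base is editable)
#' @export
predict_edits <- function(guide, editor, model,
                          window = editor$design_window) {
  sp <- strsplit(guide$spacer, "", fixed = TRUE)[[1]]
  editable <- window[sp[window] == editor$ref]
  if (length(editable) == 0L) {
    return(list(outcomes = data.frame(), consequence = NA_character_))
  }
  gpos <- spacer_pos_to_genomic(guide$start, guide$strand, editable)
  if (guide$strand == "+") {
    ref_plus <- rep(editor$ref, length(editable))
    alt_plus <- rep(editor$alt, length(editable))
  } else {
    ref_plus <- rep(unname(COMPLEMENT[editor$ref]), length(editable))
    alt_plus <- rep(unname(COMPLEMENT[editor$alt]), length(editable))
  }
  stopifnot(substr(rep(model$sequence, length(gpos)), gpos + 1L, gpos + 1L)
            == ref_plus)

  # apply all window edits jointly, then re-translate once
  edited_seq <- model$sequence
  for (i in seq_along(gpos)) {
    substr(edited_seq, gpos[i] + 1L, gpos[i] + 1L) <- alt_plus[i]
  }
  prot_ref <- model$protein
  prot_alt <- sub("\\*.*$", "", translate_cds(edited_seq, model$cds))

  out <- lapply(seq_along(editable), function(i) {
    site <- classify_site(gpos[i], model)
    residue <- NA_integer_; aa_ref <- NA_character_; aa_alt <- NA_character_
    consequence <- site
    if (site == "cds") {
      off <- cds_offset(gpos[i], model$cds)
      residue <- off %/% 3L + 1L
      full_alt <- translate_cds(edited_seq, model$cds)
      aa_ref <- substr(prot_ref, residue, residue)
      aa_alt <- substr(full_alt, residue, residue)
      consequence <- if (aa_alt == "*") "nonsense"
      else if (aa_alt != aa_ref && nzchar(aa_ref)) "missense"
      else "silent"
    }
    data.frame(spacer_pos = editable[i], genomic_pos = gpos[i],
               ref = ref_plus[i], alt = alt_plus[i],
               consequence = consequence, residue = residue,
               aa_ref = aa_ref, aa_alt = aa_alt, stringsAsFactors = FALSE)
  })
  outcomes <- do.call(rbind, out)
  summary_cons <- outcomes$consequence[which.min(SEVERITY[outcomes$consequence])]
  list(outcomes = outcomes, consequence = summary_cons)
}

#' Design safe-harbour control guides with composition quotas
#'
#' Controls are split 50/50 into guides whose editing window contains at
#' least one A but no C (inert for C-to-T editors) and at least one C but no
#' A (inert for A-to-G editors); within each group, half carry an NGG PAM and
#' half a non-NGG PAM, i.e. 25 percent of `n` per cell. `n` must be divisible
#' by 4 so the quotas are exact.
#'
#' @param editor an [editor_spec()] (its design window defines "editing
#'   window" here)
#' @param region_seq safe-harbour sequence to design in
#' @param n number of controls (multiple of 4)
#' @param seed RNG seed for the within-cell sampling
#' @return data frame of selected guides with columns group
#'   ("A_only"/"C_only") and pam_class ("NGG"/"non-NGG")
#' @export
design_controls <- function(editor, region_seq, n, seed = 1L) {
  stopifnot(n >= 4L, n %% 4L == 0L)
  # safe-harbour regions are not coding; skip the CDS translation check
  model <- structure(
    list(name = "SAFE", sequence = toupper(region_seq),
         exons = matrix(c(0L, nchar(region_seq)), ncol = 2L),
         cds = matrix(c(0L, nchar(region_seq)), ncol = 2L),
         flank = 0L, protein = ""),
    class = "gene_model")
  pamless <- editor_spec(editor$editor_name, paste0(editor$ref, ">", editor$alt),
                         "pamless", editor$design_window,
                         editor$self_edit_window)
  cand <- enumerate_guides(model, pamless)
  cand <- filter_guides(cand)
  cand <- cand[!cand$excluded, , drop = FALSE]
  win <- editor$design_window
  wseq <- substr(cand$spacer, min(win), max(win))
  has_a <- grepl("A", wseq, fixed = TRUE)
  has_c <- grepl("C", wseq, fixed = TRUE)
  cand$group <- ifelse(has_a & !has_c, "A_only",
                       ifelse(has_c & !has_a, "C_only", NA_character_))
  cand$pam_class <- ifelse(nchar(cand$pam) == 3L &
                             substr(cand$pam, 2L, 3L) == "GG", "NGG", "non-NGG")
  set.seed(seed)
  per_cell <- n %/% 4L
  cells <- expand.grid(group = c("A_only", "C_only"),
                       pam_class = c("NGG", "non-NGG"),
                       stringsAsFactors = FALSE)
  picks <- list()
  for (i in seq_len(nrow(cells))) {
    pool <- which(!is.na(cand$group) & cand$group == cells$group[i] &
                    cand$pam_class == cells$pam_class[i])
    if (length(pool) < per_cell) {
      stop(sprintf("region cannot satisfy quota %s / %s (need %d, have %d)",
                   cells$group[i], cells$pam_class[i], per_cell,
                   length(pool)))
    }
    picks[[i]] <- cand[sample(pool, per_cell), , drop = FALSE]
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Expand a guide reference with self-edited spacer variants
#'
#' Near-PAM-less editors edit the integrated gRNA cassette itself. For every
#' spacer, each non-empty subset of editor reference bases inside the
#' self-editing window (default positions 4-8) yields a variant sequence that
#' must still count towards its parent guide. Variants colliding with another
#' parent's original spacer or with a variant of a different parent are
#' dropped with a warning.
#'
#' @param library a `guide_library` (or data frame with guide_id, spacer)
#' @param editor an [editor_spec()]
#' @return data frame: guide_id, sequence, origin ("original"/"self_edited")
#' @export
expand_self_edit_reference <- function(library, editor) {
  stopifnot(!anyDuplicated(library$spacer))
  win <- editor$self_edit_window
  refs <- lapply(seq_len(nrow(library)), function(i) {
    spacer <- library$spacer[i]
    sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
    hits <- win[sp[win] == editor$ref]
    m <- length(hits)
    if (m == 0L) return(NULL)
    variants <- character(2^m - 1L)
    v <- 0L
    for (mask in seq_len(2^m - 1L)) {
      s <- sp
      sel <- hits[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
      s[sel] <- editor$alt
      v <- v + 1L
      variants[v] <- paste0(s, collapse = "")
    }
    data.frame(guide_id = library$guide_id[i], sequence = variants,
               origin = "self_edited", stringsAsFactors = FALSE)
  })
  var_df <- data.table::rbindlist(refs)
  orig <- data.frame(guide_id = library$guide_id, sequence = library$spacer,
                     origin = "original", stringsAsFactors = FALSE)
  if (nrow(var_df) > 0L) {
    var_df <- as.data.frame(var_df)
    # drop variants that collide with an original spacer of another parent
    clash_orig <- var_df$sequence %in% orig$sequence
    # drop variants shared by two or more parents
    tab <- table(var_df$sequence)
    multi <- names(tab)[tab > 1L]
    cross <- var_df$sequence %in% multi &
      stats::ave(as.integer(factor(var_df$guide_id)), var_df$sequence,
                 FUN = function(z) length(unique(z))) > 1L
    # duplicates within one parent cannot occur (subsets are distinct)
    drop <- clash_orig | cross
    if (any(drop)) {
      warning(sum(drop), " self-edit variants collided across parents and were dropped")
      var_df <- var_df[!drop, , drop = FALSE]
    }
  } else {
    var_df <- var_df[0L, ]
  }
  out <- rbind(orig, as.data.frame(var_df))
  rownames(out) <- NULL
  out
}

#' Count observed spacers against a (possibly expanded) reference
#'
#' Exact hash matching of observed spacer sequences to reference sequences;
#' variant hits are credited to their parent guide.
#'
#' @param spacers character vector of observed spacer sequences
#' @param reference data frame with columns guide_id and sequence (e.g. from
#'   [expand_self_edit_reference()])
#' @return list(counts = data frame guide_id, count over all parents;
#'   n_assigned, n_total)
#' @export
count_spacers <- function(spacers, reference) {
  stopifnot(!anyDuplicated(reference$sequence))
  parents <- unique(reference$guide_id)
  hit <- match(spacers, reference$sequence)
  gid <- reference$guide_id[hit]
  counts <- table(factor(gid, levels = parents))
  list(counts = data.frame(guide_id = parents, count = as.integer(counts),
                           stringsAsFactors = FALSE),
       n_assigned = sum(!is.na(hit)), n_total = length(spacers))
}

#' Select validation guides from screen z-scores
#'
#' Takes the top `fraction` of guides (ceiling of fraction x n, ties broken
#' by guide id) by the average z-score across donors and, separately, by each
#' donor's own z-score, and returns the union. `direction = "enriched"` ranks
#' by decreasing z, `"depleted"` by increasing z.
#'
#' @param z matrix or data frame of z-scores, guides x donors, with rownames
#'   = guide ids
#' @param fraction top fraction per criterion (default 0.035)
#' @param direction `"enriched"` or `"depleted"`
#' @return character vector of selected guide ids (sorted)
#' @export
select_validation_guides <- function(z, fraction = 0.035,
                                     direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  z <- as.matrix(z)
  stopifnot(!is.null(rownames(z)), ncol(z) >= 2L)
  if (fraction <= 0) return(character(0))
  k <- ceiling(fraction * nrow(z))
  top_by <- function(score) {
    ord <- order(if (direction == "enriched") -score else score, rownames(z))
    rownames(z)[ord[seq_len(k)]]
  }
  sel <- top_by(rowMeans(z))
  for (j in seq_len(ncol(z))) sel <- union(sel, top_by(z[, j]))
  sort(sel)
}

#' Residue-level mutagenesis map
#'
#' Restricts guides to those predicted to introduce missense or nonsense
#' mutations, assigns each guide to the residue(s) it mutates, averages the
#' z-normalized lfc per residue, and labels the top residues with their
#' predicted amino-acid changes.
#'
#' @param guide_effects data frame: guide_id, z_lfc
#' @param annotations data frame: guide_id, residue, consequence, aa_ref,
#'   aa_alt (one row per predicted edited residue, e.g. accumulated from
#'   [predict_edits()])
#' @param top_n number of top residues to label (by score, enriched side)
#' @return list(map = data frame residue, n_guides, mean_z; top = labelled
#'   top-`top_n` rows with `label` like "G12D")
#' @export
mutagenesis_map <- function(guide_effects, annotations, top_n = 15L) {
  ann <- annotations[annotations$consequence %in% c("missense", "nonsense") &
                       !is.na(annotations$residue), , drop = FALSE]
  merged <- merge(ann, guide_effects[, c("guide_id", "z_lfc")],
                  by = "guide_id")
  if (nrow(merged) == 0L) {
    return(list(map = data.frame(residue = integer(0), n_guides = integer(0),
                                 mean_z = numeric(0)),
                top = data.frame()))
  }
  dt <- data.table::as.data.table(merged)
  map <- dt[, .(n_guides = length(unique(guide_id)), mean_z = mean(z_lfc),
                aa_ref = aa_ref[1L],
                aa_alt = aa_alt[which.max(z_lfc)][1L]),
            by = residue]
  map <- as.data.frame(map[order(residue)])
  top <- map[order(-map$mean_z), , drop = FALSE]
  top <- head(top, top_n)
  top$label <- paste0(top$aa_ref, top$residue, top$aa_alt)
  list(map = map[, c("residue", "n_guides", "mean_z")], top = top)
}

#' Quantify editing from amplicon reads
#'
#' A read counts as successfully edited when its end-to-end alignment to the
#' reference contains at least one expected reference-to-alternative base
#' conversion at an expected site and no insertions or deletions. Reads whose
#' alignment identity falls below `min_identity` are excluded as unalignable
#' and reported.
#'
#' @param reads character vector of amplicon read sequences
#' @param reference amplicon reference sequence
#' @param expected data frame: pos (1-based reference position), ref, alt
#' @param min_identity percent identity below which a read is excluded
#' @return list(fraction_edited, n_edited, n_total, n_excluded)
#' @export
quantify_editing <- function(reads, reference, expected, min_identity = 50) {
  stopifnot(nrow(expected) >= 1L)
  ref_at <- substr(rep(reference, nrow(expected)), expected$pos, expected$pos)
  stopifnot(identical(ref_at, as.character(expected$ref)))
  if (length(reads) == 0L) {
    return(list(fraction_edited = NA_real_, n_edited = 0L, n_total = 0L,
                n_excluded = 0L))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(reference),
    type = "global")
  pid <- Biostrings::pid(aln)
  usable <- pid >= min_identity
  ins <- Biostrings::nindel(aln)@insertion[, "Length"]
  del <- Biostrings::nindel(aln)@deletion[, "Length"]
  indel_free <- ins == 0L & del == 0L
  pat <- as.character(Biostrings::alignedPattern(aln))
  has_conv <- vapply(seq_along(reads), function(i) {
    if (!indel_free[i]) return(FALSE)
    any(substr(rep(pat[i], nrow(expected)), expected$pos, expected$pos) ==
          expected$alt)
  }, logical(1L))
  edited <- usable & indel_free & has_conv
  n_usable <- sum(usable)
  list(fraction_edited = if (n_usable > 0) sum(edited) / n_usable else NA_real_,
       n_edited = sum(edited), n_total = length(reads),
       n_excluded = sum(!usable))
}
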