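---
title: "Models and methods behind cropscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cropscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropscreen)
```

`cropscreen` implements the informatics of pooled CRISPR screens in
engineered T cells, from raw paired reads to guide counts, clone numbers,
enrichment statistics, screen-quality scores and base-editing mutagenesis
maps. This vignette explains the models, the tunable parameters and the
numerical choices, and states plainly what the synthetic-data generator does
and does not establish.

## The screening system

A pooled screen transduces T cells with a lentiviral guide library at low
multiplicity of infection, so each cell carries one guide. In the in vivo
readout modelled here, the guide cassette sits in the vector's 3' LTR and is
transcribed into an abundant polymerase-II mRNA; the guide is read from
read 1 and a clone-identifying UMI from read 2 (50 and 26 sequencing cycles,
respectively). Each transduced founder cell carries a unique UMI, so UMIs
enumerate clones, and UMI prefixes partition one sample into 4^k internal
replicates.

## The synthetic-data generator

`make_library()`, `simulate_invivo_screen()` and `emit_reads()` generate the
full causal chain the analysis assumes:

1. **Founding.** Each founder clone draws its guide uniformly from the
   library and a unique random UMI (default 12 bases; read 2 pads the UMI
   with constant vector sequence to 26 bases, and the analysis keys on the
   full 26-base slice by default, matching the processed readout).
2. **Bottleneck.** Transplantation thins founder cells binomially at
   `bottleneck_fraction` (default 0.1) - engraftment is the dominant loss.
3. **Growth.** A clone of a gene with selection coefficient *s* grows to a
   negative-binomial final count with mean (1+s)^g after g generations
   (default g = 10, dispersion `nb_size` = 10). The NB captures overdispersed
   clonal drift; the paper-scale preset gives essential-gene controls
   s = -0.3 per generation. Zero generations is the exact identity, so
   bottleneck-free, growth-free simulations are deterministic fixtures.
4. **Sequencing.** Reads per clone are multinomial given final counts and
   `depth`; read 1 is stagger (0-7 random bases) + an 8-base constant anchor
   (the 3' end of the U6 priming region) + the 20-nt spacer + scaffold,
   truncated to 50 bases; substitution errors are i.i.d. per base (default
   0.003, a typical Illumina error rate).

`simulate_organ_umis()` generates per-organ UMI count tables directly for the
clone-counting analytics: clones share a fixed read budget (default 1e6
reads, NB per clone), background UMIs (ambient mRNA, PCR artefacts; default
50,000) draw 1 + NB(mu = 1.5, size = 0.25) reads. The heavy background tail
matters: roughly 2% of background UMIs exceed the 10-read fitting filter and
anchor the lower plateau of the knee curve. With background at strictly ~1
read the filtered curve has no lower shelf and the sigmoid's inflection is
not identifiable - a property we verified empirically before fixing this
stated world.

**What a green test establishes.** The generator reproduces the statistical
skeleton (clonal founding, bottleneck, selection, drift, depth sampling,
sequencing error, read layout). It does not emulate PCR amplification bias,
index hopping, UMI collisions beyond random chance, chimera formation (except
the explicit dual-guide recombination knob), or biological covariance between
guides of one gene. Passing tests demonstrate correctness of the analytics
under the stated model, not performance on any particular real dataset.

## Guide counting

Read 1 is scanned over the permitted stagger lengths in increasing order; the
first offset where the anchor matches with at most one mismatch (default)
wins, and the following 20 bases are the spacer. Spacers match the library
exactly (zero mismatches, hash lookup); unmapped spacers are dropped and
accounted in QC rather than collapsed into an "other" row. For the UMI
readout, reads whose UMI slice contains an N are discarded before counting.
QC reports total/mapped reads, alignment rate, zero-count guides, the Gini
index (computed in the O(n log n) Lorenz form, equal to the pairwise
mean-difference definition) and the fraction of reads that failed trimming.
Sample-level gates default to alignment >= 62.5%, >= 2 mapped reads per
sorted cell and >= 100 mapped reads per guide, all inclusive.

The anchor-mismatch tolerance is an explicit, configurable stand-in for an
adapter trimmer's error model; ties across staggers resolve to the smallest
stagger, deterministically.

## Clone counting from knee plots

UMIs are ranked by read count (ties broken lexicographically) and the curve
log10(reads) versus log10(rank) is fitted with the four-parameter sigmoid

  y = L / (1 + exp(-k (x - x0))) + b

after disregarding the top 50 UMIs and all UMIs with fewer than 10 reads
(exclusions applied in that order; the excluded top UMIs are real clones and
do count toward the final estimate). The inflection x0 separates clones from
background: the clone count is the number of UMIs with rank <=
round(10^x0), half-up, clamped to the table size.

Numerical choices: the model has an exact reparameterization degeneracy
(L, k, b) -> (-L, -k, b + L); fits are canonicalized to k > 0. Fitting uses
multi-start nonlinear least squares (stats::nls): x0 starts at the 25/50/75%
quantiles of x, k in {1, 5, 20} of both signs, L and b chosen from the data
direction. Each start is pre-optimized with Nelder-Mead before the nls
polish because Gauss-Newton alone frequently ends in singular gradients on
knees whose lower shelf is short after the 10-read filter; the best residual
sum of squares wins, and a Nelder-Mead minimum is accepted only when no nls
start converges. Noiseless curves are recovered to 1e-6 in every parameter;
across simulated organs of 100-5,000 clones the median absolute relative
error of the clone count is well under the 20% acceptance bound.

## Enrichment statistics

Counts are normalized by median-of-ratios size factors (all guides without
zeros, or restricted to a negative-control gene set). Guide-level effects are
lfc = log2((test + 1)/(ref + 1)); guides with zero counts in both compared
samples are removed. The gene score is the mean guide lfc, averaged over
internal replicates or donor pairs when provided. Because the study's
external gene-test tools are out of scope, the gene-level test is a fully
specified label permutation: guide-to-gene labels are permuted preserving
guides per gene; the two-sided Monte Carlo p uses +1 smoothing,
p = (1 + #{|null| >= |obs|})/(n_perm + 1), with Benjamini-Hochberg FDR across
genes. On instances of up to 10 guides the test can enumerate all label
permutations exactly (identity included, p = #{|null| >= |obs|}/n!). This is
a methodological stand-in validated by simulation (type-I error within
[0.03, 0.075] at alpha = 0.05 on neutral screens), not a reimplementation of
any external tool. Hits require lfc > 1.5 and FDR < 0.01, both strict.

Screen quality uses the strictly standardized mean difference over control
log2 fold changes,

  SSMD = (mean_e - mean_ne) / sqrt(sd_e^2 + sd_ne^2),

with sample SDs. Essential-gene dropout makes the signed SSMD negative in a
good screen, so the low-quality flag applies the published 0.5 cut to
|SSMD|; the signed value is always reported.

## Dual-guide screens and recombination

Dual-guide vectors pair each spacer with an internal barcode (iBAR); each
construct's (spacer, iBAR) pairings are unique, so template switching during
packaging or PCR produces reads whose halves each match the library while
their combination does not. Features are sliced positionally (no anchor
search) and matched jointly with zero mismatches; on joint failure, both
halves matching classifies the read as recombinant, anything else as
unmatched. percent_recombination uses classifiable reads
(matched + recombinant) as the denominator - unmatched reads carry no
information about recombination; this choice is configurable and documented
because the source analyses do not state theirs. Representation evenness is
the ratio of the 90th to the 10th percentile of per-construct counts, with
linearly interpolated percentiles (type 7).

## Base-editing design and quantification

Tiling design enumerates every 20-mer protospacer on both strands whose
sequence overlaps the design region (all exons plus 20 bp into each intron or
UTR), with an NGG PAM required immediately 3' in NGG mode and no PAM
constraint in PAM-less mode (strand-distinct guides sharing a spacer are
kept). Guides containing TTTT (pol III terminator) or a BsmBI site
(CGTCTC/GAGACG, spacer + PAM context, configurable) are excluded with flags.
Spacer positions are numbered 1-20 from the PAM-distal end; the design window
(control and mutation-specific design) is 5-7, the self-editing window 4-8.

Outcome prediction converts every editor reference base in the chosen window
jointly, then re-translates the spliced CDS: an edited base in the two
intronic bases at an exon boundary is a splice-site mutation (taking
precedence); otherwise introduced stops are nonsense, protein changes
missense, identical proteins silent; exonic non-CDS bases are UTR and the
rest intronic. The per-guide summary consequence is the most severe per-base
outcome (nonsense > splice_site > missense > silent > utr > intron).

Safe-harbour controls satisfy the composition quotas exactly: half the set
has >= 1 A and no C in the editing window (inert to C-to-T editors), half the
converse; each group splits evenly between NGG and non-NGG PAMs, so n must be
a multiple of 4.

Near-PAM-less editors edit the integrated cassette itself, so counting uses
an expanded reference: for each spacer, every non-empty subset of editor
reference bases in positions 4-8 yields a variant credited to its parent
(2^m - 1 variants for m editable bases). Variants colliding across parents
are dropped with a warning; parents always keep their originals. Amplicon
editing quantification aligns reads end-to-end (Biostrings global alignment)
and calls a read edited iff it has at least one expected conversion and no
insertions or deletions; reads under 50% identity are excluded and reported.

Validation-guide selection takes the top fraction (default 3.5%, ceiling, tie
break by guide id) by mean z-score across donors and by each donor
separately, and returns the union. The mutagenesis map restricts guides to
missense/nonsense consequences, averages z-normalized lfc per residue and
labels the top residues with predicted amino-acid changes.

## Workflow

`run_pipeline()` executes configured stages in dependency order
(simulate, count, clones, split_replicates, test, ssmd) from a single config
(R list or JSON). Stochastic stages require a seed; every output table
carries a provenance header (package version, config hash, seed). The config
hash excludes the output directory, so the same analysis written elsewhere is
identical up to the byte. Stage failure halts the run naming the stage.

## Known limitations

- The gene-level permutation test is a stand-in; it does not reproduce the
  numerical output of the external rank-aggregation or MLE tools used in the
  source study.
- UMIs are taken verbatim (as in the source analysis); no error-collapsing
  of near-duplicate UMIs is attempted, so sequencing errors in UMIs inflate
  background at a rate the knee filter absorbs.
- The clone-count estimator depends on a background shelf surviving the
  10-read filter; samples sequenced so shallowly that all background falls
  below it return poorly identified fits (reported as such rather than
  guessed).
- Base-editing outcome prediction assumes complete conversion of all window
  bases; partial-editing and bystander-probability models are out of scope.
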