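---
title: "Calling and comparing imprinted genes in triparental maize crosses"
author: "imprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing imprinted genes in triparental maize crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
```

## The problem

Genomic imprinting is parent-of-origin-dependent gene expression: a
maternally expressed gene (MEG) transcribes predominantly from the allele
inherited from the seed parent, a paternally expressed gene (PEG) from the
pollen parent. Imprinting is distinguished from ordinary allele-specific
expression by reciprocal crosses — a genuine imprint follows the parent, so
the favoured allele switches when the cross direction is reversed, whereas a
founder-allele effect keeps favouring the same allele.

`imprintr` implements the full analysis for a *triparental* maize design: an
F1 hybrid of two inbred lines (B73 and Mo17) is crossed reciprocally with a
third line (CAU5), alongside the two biparental reciprocal pairs (B73 x CAU5
and Mo17 x CAU5). Four reciprocal pairs are analysed in two seed tissues,
the diploid embryo and the triploid endosperm. The package covers:

1. informative-SNP selection and per-gene allelic read counting;
2. chi-square dosage tests and MEG/PEG calling per reciprocal pair;
3. conservation set algebra across cross pairs (does adding a parent to the
   cross change a gene's imprinted status?);
4. imprinted-gene cluster detection within 1-Mb windows;
5. promoter cis-regulatory element (CRE) scanning;
6. expression subgroup assignment (endosperm-primary vs constitutive);
7. a seeded synthetic-data generator providing ground truth for all of the
   above.

## Dosage model and the chi-square test

Under biallelic expression the expected maternal transcript fraction is
determined by genome dosage: $f = 1/2$ in the embryo (one maternal, one
paternal copy) and $f = 2/3$ in the endosperm (two maternal copies, one
paternal). For a gene with $m$ maternal and $p$ paternal reads
($n = m + p$), the caller computes the 1-df Pearson statistic

$$\chi^2 = \frac{(m - nf)^2}{nf} + \frac{(p - n(1-f))^2}{n(1-f)},$$

with the upper-tail $\chi^2_1$ p-value, uncorrected for multiple testing and
without continuity correction — a plain Pearson test against the dosage
null. An optional FDR adjustment exists but is off by default.

```{r}
chi2_dosage_test(18, 2, "embryo")
```

## Calling rules

A gene is testable in one cross direction when its summed allelic reads are
at least `min_reads` (default 20). A testable gene in one direction is
provisionally:

* **embryo** — MEG if $p < 0.05$ and maternal fraction $> 2/3$; PEG if
  $p < 0.05$ and paternal fraction $> 2/3$ (the "2:1 threshold", with >66%
  read as the rational 2/3 and all threshold inequalities strict);
* **endosperm** — MEG if $p < 0.05$ and maternal fraction $> 0.80$; PEG if
  $p < 0.05$ and paternal fraction $> 0.50$ (note the asymmetry: the 2:1
  dosage null means a paternal excess beyond 50% is already a strong
  departure);
* otherwise biallelic.

The two directions of a reciprocal pair are then combined: by default a gene
is MEG (PEG) only when *both* directions independently classify it MEG
(PEG) — the strict-AND reading, conservative and robust to one-directional
artifacts. A pooled mode (`mode = "pooled"` in `call_all()`) instead tests
the summed counts of the two directions, for users who prefer power over
stringency; the read filter still applies per direction, and a gene
untestable in either direction is untestable for the pair in both modes —
a one-direction signal is never reported as imprinted. These were genuinely
open choices; strict AND is the default because a parent-of-origin claim
should survive each direction on its own, which is also what makes a
founder-allele effect (same allele favoured in both directions, hence
opposite maternal fractions) fall out as biallelic automatically.

The 20-read rule is likewise applied per direction rather than to the pooled
pair, so every reported imprint rests on two independently informative
samples.

```{r}
counts <- data.frame(gene_id = c("g1", "g2"),
                     maternal_reads = c(18L, 13L), paternal_reads = c(2L, 7L))
classify_direction(counts, "embryo")
```

## Conservation sets

For each comparison group the calls from the two triparental pairs
(BM-C/C-BM and MB-C/C-MB) are compared against one biparental reference
pair — BC/CB for the "Mo17-added" group, MC/CM for the "B73-added" group.
Per comparison a gene belongs to one of three sets: imprinted only in the
triparental pair, only in the reference, or in both (sets I–VI for the
Mo17-added group and the mirrored VII–XII for B73-added). A gene is
**non-conserved** when its status differs from the reference in *both*
comparisons, i.e. membership in $(I \cup II) \cap (IV \cup V)$ — the two
"differs" sets of one comparison are mutually exclusive, so a literal
four-way intersection would always be empty, and the union-of-differences
reading is the only set-theoretically sensible one. A gene is **conserved**
when imprinted in all compared pairs ($III \cap VI$). Genes untestable in
any compared pair are excluded from the set logic entirely ("unclassified"):
absence of evidence is not a status change. By default "imprinted in both"
does not require the same direction (MEG vs PEG) in both pairs; a
`same_direction = TRUE` mode tightens this.

## Clusters, chromosomes, cross-species joins

Imprinted-gene clusters chain consecutive genes (sorted by anchor position,
default the gene start; midpoint is available) whose gap is at most 1 Mb —
single-linkage chaining, so a cluster may span more than 1 Mb overall while
every consecutive gap stays within the window. Chromosome summaries count
distinct imprinted genes per chromosome and tissue, and
`interspecies_join()` merges user-supplied ortholog imprinting tables
(rice, sorghum, Arabidopsis, ...) to report per-species conservation rates
over the genes present in the join.

## Promoter cis-elements

Promoters are the 1.5 kb immediately upstream of the translation start;
hits are reported as 0-based offsets from the promoter 5' end
(`offset_to_atg_distance()` converts to distance from the ATG). The scanner
matches IUPAC consensus strings at every position on both strands,
reporting all overlapping matches; `N` in a sequence never matches. The
bundled 13-class table (six hormone-responsive, four light-responsive,
three stress-responsive elements) uses common PlantCARE-style consensus
strings; these defaults are implementation choices — element databases
define sites in several ways — and the table is a plain data.frame meant to
be replaced by the user's own definitions when exact consensi matter. All
verification relies on motifs planted at recorded positions, not on any
particular consensus being "correct".

## Expression subgroups

Relative expression is each gene's FPKM divided by its maximum over all
samples (all-zero genes map to zero rather than NaN). Rows are clustered by
average-linkage hierarchical clustering with Euclidean distance and the tree
is cut into $k = 2$ groups; the cluster whose mean relative expression in
endosperm samples most exceeds its mean elsewhere is the endosperm-primary
subgroup, the rest constitutive. The choice $k = 2$ is the minimal reading
of a two-subgroup partition and is configurable; rows are ordered
lexicographically by gene id before clustering so results do not depend on
input order, and the cut never exceeds the number of distinct profiles, so
degenerate all-identical input collapses to a single cluster instead of an
arbitrary split.

## The synthetic-data generator

Real allele-specific calls require deposited sequencing data; the generator
replaces them with fixtures whose truth is known exactly, which is what
makes every downstream stage testable.

* **Truth**: each gene is MEG, PEG, biallelic, or untestable with
  configurable fractions; biallelic genes sit exactly on the dosage null
  ($\theta = 1/2$ embryo, $2/3$ endosperm). Defaults (5% MEG, 5% PEG, 5%
  untestable) reflect the scale of imprinting found in endosperm
  transcriptomes.
* **Counts**: per gene and sample, total depth is the sum of three i.i.d.
  Poisson replicate draws (replicates are merged before testing, matching
  the analysis convention), and maternal reads are beta-binomial around the
  gene's tissue $\theta$ with intraclass correlation `overdispersion`
  (binomial at 0). Defaults: merged depth 100, MEG $\theta = 0.95$, PEG
  $\theta = 0.05$ embryo / $0.20$ endosperm — strong but not absolute
  imprints, as observed fractions rarely reach 0 or 1.
* **Untestable genes** are simulated by truncating depth below the 20-read
  rule, not by dropping rows, so the filter itself is exercised.
* **SNPs**: founder alleles are drawn by pattern, dominated by sites where
  the two hybrid founders agree and the tester differs (informative for all
  four pairs); every gene is guaranteed one such SNP so SNP-level fixtures
  cover all genes. Gene totals are split multinomially over informative
  sites, so aggregation recovers them exactly.
* **Role swap**: `swap_roles = TRUE` relabels which side counts as maternal.
  In the embryo this maps $\theta \to 1-\theta$; in the endosperm the 2:1
  dosage re-applies to the swapped per-copy rates. With per-copy maternal
  and paternal rates $r_m, r_p$ and
  $\theta = 2r_m/(2r_m + r_p)$, exchanging roles gives
  $\theta' = 2r_p/(2r_p + r_m) = 4(1-\theta)/(4 - 3\theta)$, which fixes the
  biallelic $2/3$ and sends an endosperm MEG at $0.95$ to $\approx 0.174$.
  This is the device used to verify label anti-symmetry (true MEGs must
  present as PEGs after the swap).
* **Promoters** are i.i.d. uniform nucleotides with 1–3 motif instances
  planted per gene at recorded, non-overlapping offsets; chance background
  hits are possible and allowed, so tests assert recovery of planted hits,
  never their absence elsewhere.
* **FPKM**: imprinted genes are split between a planted endosperm-primary
  profile (high in endosperm, near-zero elsewhere) and a constitutive one,
  with log-normal noise.

What the generator does **not** emulate: read-mapping bias toward the
reference genome (real pipelines mitigate it by aligning against a
SNP-substituted genome; synthetic counts are bias-free by construction),
sequencing error (third-allele reads default to zero, though the counting
layer handles and tallies them), correlated replicate structure, and any
linkage between imprinting status and genomic position. The simulated gene
spacing (20–120 kb) is also much denser than a real maize chromosome, so
simulated 1-Mb cluster counts are far higher than real data would give.
Passing tests therefore demonstrate the correctness of the statistical
machinery and bookkeeping, not the field performance of the thresholds on
real tissue dissections (where, e.g., maternal contamination of endosperm
is a known hazard and is out of scope here).

## Numerical and design notes

* The chi-square is computed in closed form; with both expected counts
  $\geq$ 10 at the 20-read filter, the asymptotic test is adequate and is
  exactly what the method prescribes.
* Multi-gene SNPs are rejected at load time (counts would be ambiguous);
  any SNP within a gene's annotated span counts toward it.
* Third-allele reads are discarded and tallied, not errors — sequencing
  error tolerance.
* All output tables are written with fixed formatting; a fixed seed gives
  byte-identical files across runs, which the test suite verifies.
* Problem sizes used in verification: the chi-square oracle sweep covers
  every count pair with total up to 500; false-positive control uses 10,000
  biallelic genes at merged depths 100 and 30; recovery uses 1,000 genes at
  depth 200 with 5% MEGs and 5% PEGs; cluster and motif scanners are checked
  against brute-force oracles on 200 and 500 random instances respectively.
  These sizes make Monte-Carlo bounds comfortably tight while keeping the
  whole suite fast.

## Known limitations

* The caller is the prescribed chi-square with fixed fraction thresholds;
  it does not model overdispersion (no beta-binomial test) even though the
  generator can produce it — at high overdispersion the type-I rate of the
  chi-square exceeds its nominal level, which is a property of the method
  being implemented, not a defect of the implementation.
* Endosperm maternal contamination is not modelled or corrected.
* Conservation labels depend on testability in *all* compared pairs, so
  low-coverage genes drop out of the set algebra entirely.
* The default motif consensi are reasonable stand-ins, not authoritative
  PlantCARE exports.
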