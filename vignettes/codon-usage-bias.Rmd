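---
title: "Quantifying codon usage bias in gene programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying codon usage bias in gene programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The question

Synonymous codons are not used interchangeably. When a transcriptional
program — for instance the gene set induced during osteoblast
differentiation, where RNA polymerase III activity and tRNA supply are
themselves regulated — favours genes with a particular codon repertoire,
the codon composition of the induced genes will differ measurably from the
genome-wide background. `codonbias` asks exactly that question: *do the
genes in a subset (defined by differential expression or by annotation)
use synonymous codons differently from an exhaustive coding-sequence
background?*

## The statistic: within-family selection rates

For a gene $g$ with codon counts $n_{g,c}$ and the standard genetic code
partitioning the 61 sense codons into synonymous families $F(c)$, the
**selection rate** of codon $c$ in gene $g$ is

$$ s_{g,c} \;=\; \frac{n_{g,c}}{\sum_{c' \in F(c)} n_{g,c'}} , $$

the fraction of the amino acid's codons that gene contributes to $c$ — a
per-gene relative synonymous codon usage normalised to sum to 1 within
each family. A codon is only in competition with the alternative
synonymous codons decoding the same amino acid, which is how we read the
notion of a rate "against the other potential isodecoders": in the tRNA
literature *isodecoder* strictly means tRNA genes sharing an anticodon,
but a tRNA-side quantity is not computable from coding sequences alone,
so the codon-side reading (synonymous competitors within a family) is
used and documented here.

Two conventions matter and are applied throughout:

* **Missing, never zero.** A family with no observed codon in a gene
  yields `NA` selection rates for all its codons. Imputing 0 would drag
  group means of short genes toward 0 and bias every downstream test.
  Codon *usage* rates (count over total sense count) are also computed,
  but selection rates are the primary per-gene statistic because the
  group comparison uses per-observation t-tests.
* **Stop codons** are counted at parse time (I/O is lossless) but excluded
  from usage and selection statistics.

## The comparison model

Given a per-gene selection-rate matrix, a subset $S$ and a background $B$
(by default every profiled gene, with $S$ removed so the groups are
disjoint and independent), each sense codon is tested with a two-tailed
two-sample Student's t-test (equal variances pooled; Welch available via
`var_equal = FALSE`). The effect size reported is

$$ \Delta_c = \frac{\bar s_{S,c} - \bar s_{B,c}}{\bar s_{B,c}}, $$

the relative change in mean selection rate, with a log2 ratio as an
alternative column. The full comparison set — all codons tested in one
invocation — is corrected by the Benjamini–Hochberg step-up procedure,
implemented in `bh_adjust()` exactly as the textbook step-up
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1) and cross-checked
in the tests against both a brute-force $O(m^2)$ oracle and
`stats::p.adjust`.

Degenerate cases are reported, not hidden:

* A codon with fewer than `min_n` (default 10) non-missing values in
  either group is returned untested (`NA` statistics) rather than
  silently dropped.
* Single-codon families (ATG, TGG) have selection rate constantly 1
  where observed; both groups then have zero variance and, with equal
  means, the codon is reported with $t = 0$, $p = 1$ and flagged
  `degenerate`. (Zero variance with *unequal* means yields $p = 0$.)
* A background mean of exactly 0 makes the relative change undefined;
  the change is `NA` but the test is still performed.

## Gene subsets

Subsets come from two sources mirroring common RNA-seq practice:

* `filter_de()` screens a DESeq2-style results table with **strict**
  inequalities, `padj < 0.05` and `|log2FC| > 0.7` by default, in either
  or one direction. Strictness is deliberate: rows sitting exactly on a
  threshold are excluded, and missing `padj` excludes a gene. Duplicate
  gene ids are tolerated only when their records agree.
* `membership_subset()` reads GMT or two-column TSV membership lists
  (e.g. the genes annotated to GO:0001649, osteoblast differentiation),
  taking the union when a term spans several lines.

`overlap_counts()` provides exact Venn-region accounting for 2–4 subsets:
every gene of the union is assigned to the unique region given by its
membership pattern, so region counts always partition the union.

## Sequence input

`read_cds_fasta()` reads GENCODE-style FASTA (pipe-delimited headers,
configurable field positions) or plain headers; bodies are uppercased and
`U` mapped to `T`. `validate_cds()` then applies either a strict contract
(length a multiple of 3, pure ACGT) or a lenient one (trailing partial
codon truncated, codons containing `N` dropped, rejection only when no
informative codon remains); every rejection carries a reason code and is
written to a report. Because gene-level statistics need one CDS per gene
and annotation releases carry several transcripts,
`select_representative()` keeps the longest CDS by default (ties broken
by smallest transcript id) — the common convention for gene-level codon
statistics; `first` is available when the input is already curated. The
reading frame is taken as position 0 of the provided CDS; no ORF search
is attempted.

## The synthetic-data generator

Real codon bias is confounded with amino-acid composition, GC content,
expression level and phylogeny. To give every pipeline stage a
truth-bearing substrate, `simulate_weight_model()` draws, per family, a
weight vector from a symmetric Dirichlet (concentration 1 by default —
weights uniform on the simplex, a deliberately diffuse prior that
produces strongly and weakly biased families alike; `Inf` gives exactly
uniform weights). `apply_bias()` multiplies designated codon weights by a
factor and renormalises the affected families, so the injected shift —
including the compensatory *decrease* of the family siblings — is known
exactly. `simulate_cds_set()` then emits genes as `ATG` + body + one
uniform stop, each body position drawing an amino acid (uniform over 20
by default; a mammalian-composition preset is included) and then a codon
from the weight model. Body lengths are negative-binomial
(mean 400 codons, dispersion 10 by default, floored at 30 codons so
per-gene selection rates are estimable). Internal stops are never
generated, every sequence passes strict validation, and all generators
are byte-deterministic given their seed. `simulate_de_table()` plants an
exact number of threshold-passing rows, explicit boundary rows sitting
*on* the thresholds, and a fraction of missing `padj`.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: correlated codon usage along a gene,
amino-acid composition differences between gene sets, GC/isochore
structure, expression weighting, and annotation errors in real CDS sets.
The generator validates the statistical machinery, not the biology.

## Calibration and recovery checks

The acceptance suite exercises the study conditions used throughout the
package's statistical checks: two groups of 300 genes, bodies averaging
300 codons. Under the null (one weight model for both groups, 200
replicates) the per-codon rejection rate at $p < 0.05$ must sit in
$[0.03, 0.075]$. With a shift of 3 injected into six designated codons in
six different families, the injected codons must reach $q < 0.05$ with
the correct sign in at least 90% of cases while codons in *unaffected*
families stay below a 5% false-positive rate — codons sharing a family
with a target are excluded from the false-positive count because the
family renormalisation genuinely shifts them; treating a true signal as a
false positive would make the check incoherent. These sizes keep the
whole suite comfortably under a minute per check while leaving the
binomial noise of the rate estimates an order of magnitude below the
acceptance bands.

## Pipeline and outputs

`run_codon_bias()` orchestrates read → validate → representative →
profiles → subsets → compare → write from a single YAML configuration,
emitting per-subset comparison TSVs, a pooled relative-change matrix
(counts summed over the subset, family-normalised, compared to the
pooled background — the heatmap-style summary), Venn regions when two or
more DE tables are given, a rejection report and a JSON manifest with
input checksums and per-stage record counts. The `codonbias_cli()`
subcommands (`simulate`, `profile`, `filter-de`, `compare`, `overlap`,
`run`) each mirror one library operation and compose through files;
profile matrices are serialised at full precision (`%.17g`) precisely so
the file-composed route is bit-identical to the in-memory route. All
tabular output is TSV with `NA` for missing; the manifest carries
timestamps, so run-to-run determinism is defined over the data outputs
(all TSVs) and the manifest minus its timing fields.

Two analysis choices were genuinely open and are fixed as package
defaults rather than claims about upstream conventions: the relative
change formula (difference over background mean, with the log ratio as an
alternative column), and the background for a comparison (exhaustive
profiled set minus the subset by default, with a `background` option to
restrict to, say, the expressed set). Similarly, whether BH correction
should pool several invocations into one family is left to the caller:
each `compare_codon_usage()` call corrects its own full comparison set,
and callers running several comparisons can pool by adjusting the
concatenated p-values with `bh_adjust()` themselves.

## Limitations

* Per-gene selection rates are ratios of small counts for rare amino
  acids in short genes; the t-test's normality assumption is only
  asymptotically justified, which is why calibration is checked by
  simulation rather than assumed.
* The equal-variance default follows the named test; when subset and
  background differ greatly in size and spread, Welch
  (`var_equal = FALSE`) is the safer choice.
* Genes absent from the CDS set are silently absent from comparisons (a
  warning fires past a configurable fraction); id-space mismatches
  between DE tables and the FASTA must be resolved upstream.
* No phylogenetic or expression weighting: every gene contributes one
  observation.
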