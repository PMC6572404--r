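---
title: "Methods and design of methscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of methscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscan)
```

## Scope

`methscan` analyses plant whole-genome bisulfite sequencing (WGBS) data
from the per-cytosine count report onwards.  Sodium bisulfite converts
unmethylated cytosine to uracil (sequenced as T) while 5-methylcytosine
stays C, so after alignment each cytosine carries a methylated count
$s^+$ and an unmethylated count $s^-$.  Everything upstream — trimming,
alignment, deduplication, count extraction — is out of scope: the package
consumes a 7-column cytosine report (chrom, 1-based position, strand,
$s^+$, $s^-$, context, trinucleotide) and a GFF3/BED annotation.
Internally all coordinates are 0-based half-open; 1-based closed
coordinates appear only at the format boundaries (cytosine report, GFF3).
This single convention removes a whole class of off-by-one bugs between
modules.

## The methylation model

**Contexts.** Plant methyltransferase pathways distinguish the two bases
3' of a cytosine on its own strand: CG, CHG and CHH, where H is A, C or T.
`classify_context()` reads those two bases (reverse-complemented for '-'
strand sites) and returns `Unknown` within 2 bp of a contig end or when a
context base is not A/C/G/T.  The simulator classifies contexts with an
independent character-array scan, and the test suite adds a third,
regex-based double-strand scan; the three implementations are required to
agree exactly.

**Site calling.** At a site with coverage $n = s^+ + s^-$ the methylated
count is modelled as $s^+ \sim \mathrm{Bin}(n, r)$ with methylation rate
$r$.  A site is called methylated by a one-sided exact binomial test of
$H_0\!: r = e$ against $r > e$, where $e$ is the bisulfite
conversion-failure rate (default 0.005): under complete non-methylation,
residual C reads arise only from failed conversion.  P-values are
corrected across tested sites (Benjamini–Hochberg by default) and
compared with `alpha` (default 0.05).  The binomial model fixes the
distributional assumption but not the decision rule; the null rate, the
correction and the threshold are deliberate reconstructions, exposed as
arguments (`conversion_error`, `correction`, `alpha`) and recorded in
output metadata, so the rule is never hidden.  Zero-coverage sites stay
`untested` and their ML is undefined (`NA`), never 0 — silently treating
them as unmethylated would deflate every downstream average.

**Methylation level.** ML of a site is $s^+ / (s^+ + s^-)$.  All
aggregated MLs (windows, features, metagene bins, DMRs) are *weighted*:
counts are pooled before dividing.  The alternative — averaging per-site
fractions — over-weights low-coverage sites and breaks the conservation
property that the pooled counts of a partition sum to the counts of its
parts, which the test suite checks explicitly.  Genome-scale summaries
use 10 kb windows tiled from coordinate 0; the terminal partial window is
kept so that conservation holds exactly.

## 9-mer sequence preference

For sequence-preference analysis each methylated cytosine contributes the
9-mer with the cytosine at position 5 (4 bases each side, read 5'→3' on
the site's strand).  Two outputs: a position frequency matrix over
methylated sites (logo-ready; the centre column is all-C by
construction), and per-9-mer percent methylation.  The percentage is
interpreted as methylated sites / tested sites × 100 within the 9-mer
class — a read-count-weighted variant would conflate coverage with
preference.  Motifs observed at fewer than 10 tested sites are flagged
low-confidence because a percentage over a handful of sites is unstable.

## Profiles and expression classes

Feature-level MLs pool counts over promoters (2 kb upstream of the TSS,
strand-aware), exons, introns (gene span minus exons) and repeats; a site
inside several features of one class counts once per class.

Metagene profiles use fixed-width flank bins (2 kb in 20 × 100 bp bins)
and proportional gene-body bins (20), strand-flipped for '-' genes.  The
bin counts are a design choice — the typical resolution of published
metagene curves — not a biological constant, and are arguments.  Genes
shorter than the body-bin count are excluded (they cannot fill the bins);
genes overlapping a neighbour's flank still contribute to both, the
simplest rule that conserves counts.

Expression classes follow the FPKM-quartile convention: `none` below
FPKM 1; quartiles computed over expressed genes only; `low`, `medium`,
`high` split at the lower/upper quartiles.  Two boundary rules had to be
fixed: FPKM exactly 1 is expressed (`low`), since the `none` rule is
strictly `< 1`; and quartile-boundary ties go to the lower class.  For
group comparisons, `none`+`low` form the Low group and `medium`+`high`
the High group, compared per region (upstream 2 kb / body / downstream
2 kb) with a two-sided Mann–Whitney U test on *per-gene* weighted MLs.
Testing per-site values instead would pseudo-replicate within genes; the
gene is the sampling unit here.

## DMR calling

Differential methylation between two samples is tested in sliding windows
(1000 bp window, 100 bp step).  Per window, counts of context sites
covered at `min_cov` (default 4) or more in *both* samples are pooled
into a 2×2 sample-by-state table and tested with the two-sided Fisher
exact test (summing hypergeometric probabilities not exceeding the
observed table's, the standard exact convention, with the usual 1e-7
relative tolerance for floating-point ties).  Windows with fewer than
`min_sites` (default 5) qualifying sites are undefined.  Kept windows
need `p < alpha` and an absolute weighted-ML difference of at least
`min_ml_diff` (default 0.1) — with deep coverage the exact test reaches
significance at biologically trivial differences, so an effect-size floor
is essential.  Same-direction windows overlapping or within `merge_gap`
(default = step) merge into DMRs.

Two numerical decisions deserve emphasis.  First, `alpha` defaults to
0.01, the stricter of the two thresholds in circulation for this design,
and is an argument.  Second, a merged DMR is re-scored by pooling counts
over its union span rather than combining window p-values: overlapping
windows share reads, so independence-based combination rules (Fisher's
method, Stouffer) are invalid here.  `p_min`, the best constituent-window
p, is reported alongside.  DMRs are called per context; pooling contexts
would let dense CHH sites swamp CG signal.  Direction is that of sample B
relative to A (`hypo` when $ML_B < ML_A$; an exact tie is labelled
`hyper`, which in practice cannot pass the ML-difference filter).

The remaining filter defaults (`min_cov` 4, `min_sites` 5) are the
package's own, chosen as typical for sliding-window WGBS callers, and are
recorded in the run manifest.  Genes are DMR-associated when a DMR
intersects the gene body or its 2 kb flanks; the (DMR, gene) compartment
follows the precedence promoter > exon > intron > downstream, while
repeat overlap is reported independently.  The genome-wide compartment
distribution instead assigns each DMR a single compartment by maximal
base-pair overlap (ties by the same precedence) so the shares sum to
100%.

## Integration with expression

Differential-expression calls are *consumed*, not produced: the
expression model belongs to RNA-seq pipelines, and this package only
applies the thresholds — status `up` when linear fold change ≥ 2 and
FDR ≤ 0.05, both inclusive, `down` symmetrically.  Enrichment of DEG
statuses within DMR-associated gene sets uses the two-sided Fisher exact
test per (direction × status) pair over a gene universe, defaulting to
all annotated genes; the universe is an argument because no background is
canonical.  The odds ratio is the sample cross-product, with a flagged
0.5 continuity correction when a cell is zero (applied to the odds ratio
only, never the p-value).  `venn_counts()` and the `2^-ddCt` utility
round out the reporting.

## Clone (Sanger) bisulfite validation

The traditional validation assay clones a bisulfite-PCR amplicon and
Sanger-sequences ~10 clones.  `align_clone()` aligns each clone globally
to the amplicon with affine gaps, scoring reference-C versus clone-T as a
match (that is what conversion does to unmethylated cytosines); the
reverse pairing (reference T, clone C) stays a mismatch.  Traceback
tie-breaking is deterministic (diagonal, then up, then left), implemented
in C++ and mirrored by a plain-R oracle in the tests.  Clones under 70%
alignment identity are rejected and reported.  At each amplicon cytosine
the clone bases are tallied: percent methylation is
$100 \cdot C / (C + T)$, with any other call (mutation, gap) excluded
from the denominator.  Region summaries pool counts per context over
promoter-relative coordinates; the convention is that −1 is the base
immediately upstream of the TSS and position 0 does not exist, matching
how such regions are labelled in practice.  Conversion efficiency —
$100 \cdot T/(C+T)$ over designated unmethylated control sites (non-CG by
default) — is provided as the standard QC figure.  Clones are not
deduplicated: the protocol picks independent colonies.

## The simulator

`sim_config()` fixes the study conditions; every generator is
deterministic under the seed, and truth tables (per-site rates, planted
DMR spans, planted DEG status) are first-class outputs because
parameter-recovery tests need them.  Defaults: a 2 × 100 kb genome at GC
0.4 (a typical plant value), 60 non-overlapping genes of 1–5 exons,
40 repeats in intergenic space, per-context methylation rates
CG 0.6 / CHG 0.4 / CHH 0.08 (the high-CG, intermediate-CHG, low-CHH
ordering characteristic of flowering-plant methylomes), Poisson coverage
with mean 30 (routine WGBS depth), and a conversion-failure probability
of 0.005.  Conversion error is modelled meth-ward only (an unmethylated C
reading as C), the dominant artifact class in real bisulfite data;
false unmethylation is omitted.  Coverage is Poisson rather than fixed
so the zero- and low-coverage code paths are exercised.  Planted DMRs
override per-context rates inside stated regions per sample; planted
expression coupling forces genes whose promoter overlaps a hypo-DMR to be
up-regulated with probability `planted_assoc`.

What the simulator does *not* emulate — and what passing tests therefore
do not certify about real data: biological replicate dispersion (the
emulated design has one library per organ), non-uniform base composition
(isochores, repeat families), mapping bias, read-level sequencing error,
PCR duplicates, and methylation autocorrelation beyond the planted
regions.  Results on real data additionally depend on upstream alignment
quality, which is out of scope by design.

## Verification problem sizes

The acceptance layer runs: the classifier against a regex oracle on
50 × 10 kb genomes; the exact test against combinatorial enumeration of
all 2×2 tables with row margins ≤ 40 (~740 000 tables); the site caller
on 10⁴ null sites; DMR recovery with ten planted 2 kb CG DMRs
(rates 0.8 vs 0.2, coverage 30) over five seeds; rate recovery on a 1 Mb
genome; the metagene flat limit on 200 genes; enrichment power/null
calibration over 10 seeds each; clone-rate recovery at 50 clones; and a
byte-identical pipeline rerun.  These sizes were chosen to make the
statistical bounds tight (3 standard errors, exact binomial confidence
intervals) while keeping a routine laptop run in minutes.

## Known limitations

Three-way (rather than pairwise) DMR models, replicate-aware dispersion
modelling, GO/KEGG enrichment of DMR genes (external databases), and logo
rendering are out of scope.  The Fisher window test conditions on margins
and so is conservative at low coverage; with one library per sample,
p-values quantify read-sampling noise, not biological variability —
DMR lists from unreplicated designs are screening results, and the clone
module exists precisely to validate individual loci.
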