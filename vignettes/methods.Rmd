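---
title: "Models and methods behind scnome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scnome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the conventions, and the
deliberate design choices in `scnome`: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the known
limits are.

## The measurement model

NOMe-seq-style assays treat nuclei with a GpC methyltransferase before
bisulfite conversion. Afterwards a sequenced cytosine carries two
superimposed signals: endogenous CpG methylation and enzymatic GpC
methylation laid down only in accessible chromatin. The trinucleotide
context separates them. `WCG` (upstream A/T, downstream G) cytosines can
only be methylated endogenously; `GCH` (upstream G, downstream A/C/T)
cytosines can only be methylated by the enzyme; `WCH` cytosines should be
methylated by neither, so any unconverted `WCH` signal measures bisulfite
failure. `GCG` is ambiguous between the two channels and `CCG`/`CCH`
satisfy neither upstream rule; both are excluded, as are chromosome-edge
cytosines without a flanking base. Because the upstream base is either
W or G but never both, every cytosine receives exactly one label — the
test suite checks this partition against an independent brute-force scan.

Contexts are strand-specific (the trinucleotide is read 5'→3' on the
site's own strand) and calls are therefore reported per strand; merging
complementary CpG calls is left to downstream consumers, since the GpC
channel has no meaningful cross-strand merge. Call tables use 1-based
cytosine positions (the cytosine-report dialect); all BED output is
0-based half-open. Internally the simulator keeps 0-based half-open
coordinates everywhere and converts only at I/O boundaries.

## Read structure and demultiplexing

Split-pool libraries put two ligation barcodes at fixed offsets in
read 1, separated by constant linkers. Linker matching uses Hamming
distance at the fixed offset, with `linker_max_mismatch = 1` by default:
the ligation chemistry fixes the positions, so an indel-tolerant search
would only invite spurious matches, while one mismatch absorbs an
ordinary sequencing error. Reads failing a linker are counted as unknown
structure; no recovery of indel-shifted reads is attempted.

Barcodes are corrected per slot against their own whitelist by
Levenshtein distance. The unique nearest entry at distance ≤ 2 is
accepted; a minimum above 2, or a tie at the minimum, discards the read
as unknown barcode. Ties are discarded rather than broken because a
wrong barcode assignment contaminates another cell's profile — a worse
failure mode than losing one read. The PCR index is taken from the read
header, assumed already separated by the sequencer.

The whitelist generator guarantees pairwise Levenshtein distance ≥ 3,
which makes single-error correction exact: an observed barcode one error
from its origin is at least two from every other entry, so the minimum
is unique. Two errors concentrated in one barcode are *not* always
recoverable at separation 3 — they can tie at distance 2 (discarded) or,
rarely, land nearer a neighbouring entry. Under a per-base barcode error
rate of a few percent, reads carry mostly 0–1 barcode errors and
assignment accuracy stays above 99%; the validation suite uses exactly
this regime.

With `n` cells in a tube drawing uniformly from `B` barcode
combinations, the probability that a given cell shares its combination
is `1 − (1 − 1/B)^(n−1)`: about 4.2% at `n = 200`, `B = 48 × 96`. This
per-cell definition is exposed alongside a Monte-Carlo counterpart
(fraction of cells in multiply-occupied combinations) and the two agree
within Monte-Carlo error; both rise with `n` and fall with `B`. Other
collision statistics in circulation (e.g. doubling for cross-species
detectability in barnyard designs) can be derived from these but are not
silently substituted.

## Methylation calling and QC

Per site and cell, the methylation level is the ratio of reads showing
the unconverted base to reads showing either state; sites with no
coverage are absent, not zero. A plus-strand record informs plus-strand
cytosines (read C = methylated, T = unmethylated); a minus-strand record
informs minus-strand cytosines, which in plus orientation appear at
reference G (read G = methylated, A = unmethylated). Any other observed
base at a site is ignored. Records are deduplicated per cell on
(chromosome, start, strand) before calling, keeping the first record in
input order; identical coordinates in different cells are never
collapsed.

Per-cell QC reports the global WCG% and GCH% as the mean of per-site
levels times 100, and the conversion rate as
`100 × (1 − pooled mitochondrial WCH methylation)`. Pooling counts
(rather than averaging per-site ratios) makes the conversion estimate a
binomial proportion, unbiased across coverage profiles; on simulated
data with a 0.5% failure rate and ~1e5 WCH calls it recovers
99.5% ± 0.1.

The bundled aligner is an exact matcher for synthetic genomes only: it
collapses C→T (and G→A for the complementary chemistry) in both the read
and the reference and requires a unique exact hit across the four
strand/collapse combinations. It exists so end-to-end runs need no
external aligner; production data should be mapped with a real bisulfite
aligner and fed in as aligned records. Consequences of the collapse: a
fully methylated read maps identically to its unmethylated twin, and a
read with no informative conversion can be genuinely strand-ambiguous,
in which case it is dropped as unmapped.

## NDR calling

Accessibility is called on pseudo-bulk: GCH counts summed over a cell
group, because single-cell GCH coverage is far too sparse for
region-level tests. Windows of 100 bp advance in 20-bp steps anchored at
coordinate 0; trailing partial windows are kept if they contain a site.
Each window's (methylated, unmethylated) split is tested against the
chromosomal background with a Pearson chi-square on the 2x2 table at
1 df without continuity correction — the canonical two-proportion test
for count data at this scale. The background excludes the window's own
counts so a window never tests against itself; at genome scale the
difference is negligible, on small test chromosomes it avoids
self-contamination. One numerical note: the cross-product term is
computed in double precision because the 2x2 products overflow 32-bit
integers at realistic pooled depths.

Significant windows must have p < 1e-10, strictly more than 5 GCH
sites, coverage ≥ 1, and methylation *above* background. The direction
filter is added deliberately: NDRs are by construction
GpC-hypermethylated, and without it the significance filter would also
call hyper-protected (nucleosome-dense) regions; it can be switched off
to retrieve those. Overlapping or book-ended significant windows merge,
matching the default of the standard BED interval-merge; each region
records its smallest window p and coverage-weighted mean GCH
methylation.

On a 1-Mb synthetic genome with 20 planted 600-bp NDRs at methylation
0.8 versus 0.2 background and 50x pooled coverage, the caller reaches
recall and precision 1.0 with boundaries within one window length of
truth. Boundary error is scored per truth region against the union span
of its overlapping calls, so a region split by a local run of
site-sparse windows still counts both outer boundaries.

## Bin matrices, embedding, clustering

The clustering matrix is cells x fixed bins (250 kb by default) of mean
site methylation, with explicit missingness. Filters run cells first,
then bins — cells covering fewer than 10 000 bins are dropped, then bins
observed in less than 50% of the remaining cells — with strict-less
boundaries in both cases (a cell at exactly 10 000 and a bin at exactly
50% survive). The filter is idempotent. Missing entries are imputed with
the cell's own mean over observed bins, which preserves each cell's mean
exactly and adds no between-cell structure. Embedding is centred PCA
(top 50 components, capped at the data rank), a k-nearest-neighbour
graph (k = 15) on the component scores, Leiden community detection
(resolution 1.0 — k and resolution are not dictated by the method and
are exposed as parameters), and UMAP for layout; every stage is seeded
and the whole path is deterministic under a fixed seed.

Promoter-level methylation pools counts (sum methylated over sum total)
across a group's cells rather than averaging per-cell ratios: with
per-cell coverage of a promoter often being one or two reads, a mean of
ratios is dominated by binary single-read cells. The mean-of-cells
alternative is available behind a flag, and a per-cell Wilcoxon on
promoter ratios is left to the consumer. A joint methylation +
accessibility embedding, where needed, is a plain concatenation of the
two channels' principal components — a labelled approximation, not a
weighted-neighbour integration.

## Copy number

Copy ratios are read counts in 1-Mb windows, normalized to each entity's
total, divided by the same quantity for a diploid reference (a normal
pseudo-bulk when available, else the median profile across cells), and
median-re-anchored per entity. The re-anchoring matters: without it an
entity's own gains deflate all its ratios through the total-count
normalization (a 3-copy chromosome occupying a tenth of the genome would
read 1.43 instead of 1.5). It assumes most windows sit at reference
ploidy — the standard mostly-diploid assumption, which fails for
near-triploid genomes. Copy number is `round(ploidy × ratio)`; windows
with zero reference counts are masked and excluded from the per-entity
coefficient of variation. There is no GC or mappability correction and
no segmentation model: at megabase windows and clone-scale questions a
ratio profile suffices, and clone assignment is ordinary hierarchical
clustering (Ward, Euclidean) of ratio vectors.

## Epigenetic age and mitotic score

The age model is massively univariate: per CpG site, OLS of the bulk
reference β on chronological age, with the Pearson correlation recorded.
Sites with constant β are dropped (their correlation is undefined) and
counted. The top 10% of usable sites by |r| form the predictive set.

Prediction binarizes a cell's covered levels at 0.5 (ties round up — a
documented convention, configurable) and maximizes the Bernoulli profile
log-likelihood over a candidate age grid, with the per-site success
probability `clamp(intercept + slope × age, 0.001, 0.999)`. The clamp
prevents infinite log-likelihoods where the linear predictor leaves
[0, 1]; site contributions are unweighted, with a weight hook exposed.
The grid extends the training range by ±20 years at 0.1-year steps so
that accelerated ageing beyond the training maximum remains
representable; ties break to the lowest age and set a flatness flag.
Cells overlapping fewer than 100 predictive sites are refused rather
than guessed — no imputation of unobserved sites is attempted, which is
a deliberate simplification relative to transformer-based imputation
front-ends.

Validation is generative: cells drawn from the fitted model at known
ages (2000 covered predictive sites) are dated with RMSE well under 10
years and correlation above 0.99 at the default noise level, and a
constant positive methylation offset at age-positive sites — a
tumour-like shift — raises the mean predicted age of the shifted group.
Fivefold cross-validation stratifies folds by age quantile and
downsamples each held-out sample to 2300 sites to mimic single-cell
sparsity. In the exact noiseless limit the age-independent simulated
sites become constant and leave the model, so that limit is exercised on
a fully age-linear reference, where the cross-validated correlation
exceeds 0.98.

The mitotic score is the mean pooled methylation over a user-supplied
clock CpG set — the clock list itself is an input, not shipped — and
site-set concordance between clocks is tested with the upper-tail
hypergeometric probability.

## The synthetic-data generator

All validation data come from one seeded generator. It emulates: uniform
random genomes; the two-round barcode ligation with per-base barcode
errors; strand-correct bisulfite chemistry (unmethylated C→T with
probability `1 − conversion_failure` on the fragment's own strand, G→A
appearance in plus orientation for minus-strand fragments); planted
accessible regions as a GCH methylation contrast (0.8 inside vs 0.2
outside by default — a strong but realistic pseudo-bulk contrast);
planted CNV clones as read-density multipliers; bin-level group
methylation profiles for clustering; and age-linear β trajectories
(slopes ±0.002–0.008 per year, clipped to [0, 1], Gaussian noise
σ = 0.05) for the clock. Per-cell methylation states are drawn once per
covered site, so overlapping reads of one cell always agree with the
truth sidecar.

It does **not** emulate: sequence-composition bias, CpG islands' spatial
autocorrelation, realistic error profiles or quality scores, PCR
duplicate families beyond exact coordinate duplicates, chimeras, or
M-bias. Passing tests therefore demonstrate correctness of the
algorithms under their stated models, not robustness to every artefact
of real libraries; the demultiplexer, for instance, is validated against
substitution errors only, and the NDR caller against a clean two-level
methylation landscape.

Problem sizes used in the validation suite — a 1-Mb genome for NDR
recovery, 200 cells for the clock, 40 cells x 50-Mb genome for CNV,
90 cells for clustering, 10 000 Monte-Carlo replicates for collision
rates — were chosen as the smallest scales at which the relevant
statistics are in their asymptotic regime (pooled depths ≥ 50x,
≥ 1e4 reads per CNV window, ≥ 1e5 WCH calls for conversion).

## Known limitations

* The exact matcher caps reference size at 10 Mb and gives up on any
  multi-locus read; it is not a production aligner.
* Pseudo-bulk NDR calling provides no per-cell accessibility calls and
  no differential testing between groups (intersect NDR sets instead).
* The mostly-diploid assumption of the CNV baseline; no allele-specific
  or breakpoint-precise inference.
* The clock's per-site independence assumption ignores co-methylation;
  its grid argmax has no uncertainty interval beyond the flatness flag.
* Promoter differences are rankings, not significance calls.
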