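---
title: "Methods: low-input Capture-C analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-input Capture-C analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threecap)
library(tibble)
```

# The analysis model

Capture-C converts spatial chromatin proximity into ligation junctions
between restriction fragments and enriches sequencing libraries for junctions
involving chosen viewpoint fragments (gene promoters). The analysis therefore
works on one shared coordinate system: the partition of the genome into
restriction fragments.

## Fragment coordinate system

`digest_reference()` scans each chromosome for the recognition motif (DpnII,
`GATC`, by default) and cuts at the first base of every occurrence, so each
internal fragment carries the motif at its 5' end. The convention is a
declared choice — enzyme overhang chemistry is irrelevant to coordinate
bookkeeping — and the same convention is used by `digest_read()`, which makes
the in-silico digest of a ligated fragment pair split exactly at the
junction. Coordinates are 0-based half-open throughout; BED and bedGraph
share this convention and SAM input is shifted on ingest. Motif scanning is
case-insensitive and `N` bases never match, so masked references digest
conservatively. Zero-length fragments (a cut at position 0) are suppressed.

`locate_fragment()` assigns an interval to the fragment containing its
midpoint, `floor((start + end) / 2)`. Midpoint assignment is robust to small
alignment overhangs across a cut site and gives every interval exactly one
fragment.

## Classification

Slices of a read (the mapped sub-alignments of one sequenced molecule) are
placed on the map and partitioned into three roles. Slices on a viewpoint
group's target fragments are *capture* slices. Duplicated-gene promoters
(e.g. the two alpha-globin promoters) are declared as one viewpoint *group*;
hits to either member are capture slices of the group, never double-capture,
because such interactions cannot be distinguished bioinformatically. Reads
touching targets of two distinct groups are discarded as `double-capture`.
Slices overlapping the group's exclusion zone — by default the viewpoint
fragment(s) ± 1000 bp, exposed as `exclusion_bp` — are *excluded*: ligation
events that close to the viewpoint are dominated by uninformative proximity
ligation. Remaining slices are *reporters*; multiple reporter slices in one
fragment count once per read, since one molecule is one interaction event.
The 1000 bp default is a declared convention (proximity exclusion is standard
practice; no published value is prescribed for this assay), and it is the
same zone the simulator blanks out, so simulated truth matches what the
analysis can see.

## The stringent coordinate-UMI duplicate filter

The random shear ends of a molecule serve as two independent UMIs: the left
key is the 5'-most mapped coordinate of the first slice, the right key the
3'-most coordinate of the last slice, in read order. (We store the half-open
end for the right key; only coordinate differences enter the filter, so the
1 bp offset against an inclusive convention is immaterial.)

Two reads are duplicates when their keys are identical, or nearly identical:
sequencing and mapping errors shift shear ends by a base or two and make
duplicates look unique, which in low-complexity libraries produces spurious
peaks. The filter links reads whose keys lie within summed L1 distance
`max_wobble` (default 2, i.e. "one or two differences", with chromosomes
required equal; the two ends are treated symmetrically), takes single-linkage
clusters, and retains one representative per cluster — the read with the most
exact-key copies, ties broken by smallest (chromosome, left, right, read id)
for determinism. Retaining a representative dampens rather than erases
genuine signal; the stricter reading that deletes wobble-linked clusters
outright is available as `drop_wobble_clusters = TRUE`. Whether per-end or
summed distances were intended, and whether wobble matches were collapsed or
removed, is not prescribed anywhere; both readings are implemented and the
defaults are the package's choice.

The implementation is not all-pairs: exact keys are collapsed first, then for
every offset `(dl, dr)` with `0 < |dl| + |dr| <= max_wobble` the shifted key
is looked up in a hash, which enumerates exactly the neighbour edges in
`O(w^2 n)`; union-find merges them. An all-pairs connected-components oracle
exists only in the test suite. Deduplication is performed per viewpoint group
with cis and trans reads together — a molecule is unique irrespective of its
reporter's chromosome.

The filter is deliberately conservative: genuinely distinct molecules whose
shear coordinates happen to fall within the wobble tolerance are merged, so
retained counts *under*-estimate unique interactions. This is a property of
coordinate UMIs, not a defect; `dedup_truth_summary()` quantifies it on
simulated data.

## Profiles

A raw profile counts retained informative reads per reporter fragment (a
read reporting k distinct fragments contributes one to each).
`pool_profiles()` sums the raw member profiles of a duplicated-promoter
group. `normalize_profile()` multiplies by `scale / total` with the total
taken genome-wide — cis and trans — so the default profile sums to 100,000
interactions; cis-only scaling is behind a flag for sensitivity analysis.
`window_profile()` smooths with a centred running mean over an odd number of
fragments (default 5, a typical 4C-style window; no specific width is
prescribed). The window unit is fragments, not bp, because the restriction
fragment is the method's resolution unit; bp windows would conflate
fragment-size variation. Windows truncate at chromosome edges (the mean uses
the available fragments) and never span chromosomes, so the profile total is
not conserved in general — the tests assert instead that a constant profile
is a fixed point and that interior windows equal a brute-force sliding mean.
Replicate means and differential profiles operate on per-replicate normalized
profiles; the differential standard error is `sqrt(SE_A^2 + SE_B^2)` with
each term the standard error of the replicate mean (0 for one replicate).

## QC statistics

`cis_fraction()` is computed per reporter-fragment event on post-dedup
interactions. `digestion_efficiency()` uses a calibrated ddCt:
`(Ct_site − Ct_control)` on the 3C library minus the same difference on
undigested genomic DNA (which absorbs primer-pair differences), and
`100 (1 − E^{−ddCt})` clipped to [0, 100] with per-cycle amplification
`E = 2` by default; the Ct comparison is named by the assay, the arithmetic
is this package's declared convention, and `E` is exposed for non-ideal
assays. `quantify_mass()` fits Ct against `log2(mass)` so the ideal slope is
−1 and inverts the fitted line.

## C-String counts

Probes target fragment ends: the left probe is the top strand of the first
`probe_length` bp, the right probe the bottom strand (reverse complement) of
the last `probe_length` bp, so either end of a denatured junction molecule
can be counted. Probe length defaults to 50 nt, a typical hybridization-probe
length and configurable. Counts are normalized per sample to 1000 over the
probed set only — the instrument sees nothing else — and the Capture-C side
of a comparison is renormalized over the same probed set before the Pearson
correlation, which makes the two vectors commensurable. No
background/positive-control correction is modelled (raw counts in).
Differential counts reuse the profile subtraction arithmetic, with the SE of
the replicate mean as the uncertainty.

# The simulator

`simulate_library()` exists so that classification, filtering and profile
construction can be validated against known truth. It mirrors the library
logic — ligation, shearing, PCR — without pretending to be a sequencer.

**Interaction distribution.** Cis fragment *i* receives weight
`(1 + peak_i) · d_i^{-alpha}` with `d_i` the midpoint distance to the nearest
viewpoint member, floored at the viewpoint fragment length to avoid the
singularity; trans fragments share mass `t` uniformly; viewpoint and
exclusion-zone fragments get zero. Defaults: `alpha = 1` (the canonical
near-inverse distance decay of contact frequency), `t = 0.2` (a well-fixed
library detects most unique interactions in cis), enhancer peaks are supplied
per fixture. Only two-fragment junction molecules are simulated — a viewpoint
and one reporter — which suffices to exercise every analysis stage;
higher-order concatemers are a possible extension.

**Shearing.** Insert sizes are normal, rounded, truncated to [50, 500] bp
with defaults 200/30 (sonication to ~200 bp). The insert must span the
junction: the viewpoint-side length is drawn from the feasible range, under
sonication uniformly, under tagmentation weighted by `gc_weight` (default 3,
a moderate Tn5-like bias; >= 1) at G/C bases at *both* cut positions, since
the transposase cuts both ends. When a fragment pair cannot hold the drawn
insert, the size is redrawn truncated to the locally feasible range —
equivalent to bounded retries — and pairs that cannot hold even the 50 bp
minimum are skipped and counted. Coordinate-biased breakpoints make
independent molecules shear at identical coordinates more often; such
molecules are indistinguishable from PCR duplicates, which is the mechanism
by which tagmentation underperforms at high input, and
`umi_collision_rate()` measures it from the truth table.

**PCR duplication.** Each molecule is emitted `1 + G` times,
`G ~ Geometric(mean rho)` (default 1). Each duplicate independently, with
probability `epsilon`, has exactly one UMI coordinate shifted by ±1 or ±2 bp
(uniform over the eight combinations); originals are never wobbled. The
default `epsilon = 0.05` is a free parameter — no measured wobble rate is
available to anchor it — and the geometric/one-end model is the simplest that
produces the failure mode the stringent filter targets.

**What is and is not emulated.** Reads are emitted pre-aligned, so mapping
ambiguity, body sequencing errors, chimeric mis-ligations, optical
duplicates and capture-efficiency variation are out of scope; a FASTQ export
exists for interoperability only. Passing tests therefore demonstrate that
the analysis recovers what the generative model planted, not that these real
data artefacts are handled.

# Study conditions and numerical choices in the tests

Test fixtures are generated in code at fixed seeds and sized so the whole
suite runs in well under ten minutes on one CPU:

* *Profile recovery*: a ~680-fragment two-chromosome toy locus (130 kb +
  50 kb), viewpoint mid-chromosome, three planted peaks with weight 50 at
  12–35 kb — a strong enhancer's enrichment over local background — with
  100,000 molecules, no duplication. The recovered normalized cis profile is
  compared with the true distribution (Pearson r >= 0.95, peaks in the top
  five). With no PCR duplication there is nothing to remove, so the profile
  is built from classified reads directly: at this toy scale 100,000
  molecules saturate the per-fragment coordinate space and the wobble filter
  would measure UMI-space saturation rather than recovery (the filter has its
  own criteria). Genome-scale data does not saturate this way.
* *Duplicate filtering*: random UMI sets (n <= 500) against the all-pairs
  oracle at wobble 0/1/2/5; and a sparse multiplexed design — 48
  single-fragment viewpoints on 12 x 2 Mb chromosomes, shallow decay
  `alpha = 0.3`, `t = 0.3`, 5000 molecules, `rho = 1` — where coordinate-UMI
  space is far from saturated, so with `epsilon = 0` the filter retains
  exactly the distinct true UMIs. Distinct molecules closer than the wobble
  tolerance merge by design; the fixture makes the expected number of such
  pairs ~0.01–0.02, so a rare seed can still produce one.
* *Cis/trans recovery*: two 150 kb chromosomes, 10,000 molecules, trans
  fractions 0.1/0.3/0.6; measured cis percentage within three binomial
  standard errors, monotone in t.
* *Tagmentation collisions*: a 30 kb GC-rich (60%) locus, `gc_weight = 5`,
  5000 vs 20,000 molecules, collision rates averaged over five replicate
  simulations per condition (single runs at the smaller depth are too noisy
  for a stable ordering).

Degenerate inputs fail fast and loudly: empty genomes, even windows,
zero-total profiles or samples, zero-variance correlation inputs, missing Ct
combinations and inverted intervals are errors, not warnings.

# Known limitations

* Coordinate UMIs saturate on small, deeply sampled loci; retained counts
  then undercount true complexity. This mirrors the real assay's behaviour
  and is quantified, not corrected.
* The simulator's decay-plus-peaks distribution is a stand-in for a real
  interaction landscape; it contains no TAD structure, no mappability or GC
  bias in capture efficiency, and no multi-way contacts.
* Mapping-quality handling is a single threshold on SAM ingest; realistic
  alignment artefacts are out of scope.
* The digestion-efficiency formula assumes perfectly doubling qPCR unless
  `amp_efficiency` says otherwise.
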