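---
title: "Methods and design of viromer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of viromer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`viromer` is the analysis layer that sits after basecalling, demultiplexing,
assembly and viral classification in a long-read or hybrid virome workflow.
This vignette records the models and rules it implements, the parameters that
matter and their defaults, what the bundled simulator does and does not
emulate, and the design decisions taken where more than one defensible choice
existed.

## Coordinate and identity conventions

All intervals are 0-based half-open internally; SAM's 1-based positions are
converted on ingest (`read_sam()`), PAF's native 0-based coordinates pass
through unchanged. A single convention removes the classic off-by-one drift
between pileups, interval merging and truth manifests.

Alignment identity is residue matches over alignment-block length — the PAF
column-10 / column-11 ratio, i.e. gaps count against identity
(gap-compressed variants are not used). Where CIGARs carry `=`/`X`
operations, mismatch and indel counts come from the CIGAR; plain `M` CIGARs
leave the mismatch count to an `NM` tag or the caller.

## Read QC

The filter trims the first 50 bases of every read (residual barcode
sequence), then removes reads whose **post-trim** length is below 1,000 bp or
whose **post-trim mean** per-base Phred quality is below 9. Trim-then-filter
order is deliberate: a 1,040 bp raw read fails, a 1,050 bp read passes.
"Quality below 9" is interpreted as the mean of per-base scores, matching the
semantics of the standard Nanopore filtering tools; the mean/median choice is
not observable for reads with flat quality strings and changes little
otherwise. Reads removed for both reasons are reported once, under `length`.
`qc_filter()` marks its output (`qc_trimmed`), so re-running it never
re-trims — the filter is idempotent.

Library-size bias before assembly comparisons is removed by
`subsample_reads()`, seeded sampling without replacement down to the
smallest library. Read-length distributions are compared with a two-sided
Mann–Whitney U test (normal approximation with tie correction), and median
lengths are reported with a percentile bootstrap interval — by default
50,000 draws with replacement per replicate, 1,000 replicates, the 2.5 and
97.5 percentiles of the replicate medians. Both are standard large-sample
choices; the bootstrap parameters are arguments, and the calibration test in
the suite runs 200 simulated libraries at 500 draws × 400 replicates to keep
the run short while still measuring coverage.

## Chimera detection

Amplified long-read libraries contain PCR chimeras: single reads formed by
joining fragments of two templates. Genuine reads are supported end-to-end
by overlaps with other reads; no genuine overlap spans a chimeric junction.
`detect_chimeras()` therefore accumulates, per read, the coverage profile of
all overlap intervals landing on it and flags reads containing an internal
span of at least `min_gap_bp` (300) with coverage below `min_cov` (4), at
least `end_slack_bp` (200) away from both read ends, with both flanks
reaching `min_cov`. The flank condition separates junction gaps from mere
low-coverage reads; the end slack separates them from ordinary coverage
ramps at read ends. The three defaults mirror the published scrubbing
concept this detector reimplements and are exposed as arguments.

The detector's operating point depends on overlap depth: at 20× with the
defaults, sensitivity on simulated chimeras is effectively 1 and the false
positive rate is at the per-mille level (driven by Poisson coverage dips).
Below ~10× the gap criterion loses power — the tool reports whatever the
profiles support and leaves depth management to the user.

## Viral populations and the enhanced virome

Contigs enter population construction when they are at least 2.5 kbp (the
floor fed to the viral classifier), carry a VirSorter category in
{1, 2, 4, 5} and are at least 5 kbp. Dereplication uses the community
convention for viral populations: ≥ 95% nucleotide identity over ≥ 70% of
the *shorter* sequence. Pair coverage merges overlapping aligned intervals
before measuring; pair identity is the block-length-weighted mean over
contributing alignments. Clustering is greedy longest-first with first-fit
assignment and no reassignment passes — deterministic, and the behaviour of
the widely used clustering scripts: sort by length (ties broken
lexicographically by id), join the first existing representative that meets
both thresholds, else found a new cluster. The representative is therefore
always the longest member.

An *enhanced* virome pools the filtered viral contigs of two or more
assemblies (short-read, hybrid, long-read), namespaces colliding ids as
`label:id`, dereplicates the pool, and attributes each population to the
assemblies that contributed members: present in all, shared by some, or
unique to one. Rank abundance uses mean mapped-read depth over the
representative, normalised per million mapped reads. The underlying
abundance measure for rank curves is genuinely underdetermined in the
literature (depth, mapped reads, length-normalised counts all appear); the
depth-per-million default is documented here and the input is any alignment
table, so callers can apply their own weighting upstream. The top decile is
the first `floor(N/10)` populations — 516 of 5,161 — with rank ties broken
by representative id.

## Microdiversity

Reads are recruited to contigs at ≥ 95% identity over ≥ 70% of the read
(inclusive bounds: "at 95% identity" reads as a threshold attained).
Contig-level selection is strict: breadth **>** 0.70 and mean depth **>**
10×, where breadth counts positions with any aligned base and mean depth is
total aligned bases over the whole contig length. The whole-contig
denominator (rather than covered-positions-only) is the conservative
reading; both thresholds and the summary are arguments.

Pileups are built in-library from CIGAR walks; a base contributes only with
base quality ≥ 20 (`min_base_quality`). This base-level rule carries the
intent of a PHRED < 20 variant-call filter into a pipeline that has no
external variant caller, and is documented as an approximation: it filters
evidence, not calls. `N` bases never count.

A variant base is a **true SNP** when it is carried by at least 4 reads and
exceeds 1% of the position's counted coverage; multi-allelic positions
produce one call per alternate base and positions with reference `N` are
skipped. Per-site diversity is the unbiased estimator

$$\pi_s = \frac{C}{C-1}\Bigl(1 - \sum_b f_b^2\Bigr),$$

whose expectation equals the population heterozygosity $2f(1-f)$ for a
two-allele site at minor frequency $f$ regardless of coverage $C$; sites
with $C < 2$ are undefined and excluded. The upstream workflows this package
follows do not print their estimator; the unbiased per-site heterozygosity
is the standard choice and is validated in the test suite by parameter
recovery ($f \in \{0.05, 0.1, 0.2\}$, depth 200, relative error of the
median below 10%).

A contig's summary π is the **median over true-SNP sites only**, and 0 — not
missing — when no site passes the truth rule, so unpolymorphic contigs
remain in downstream comparisons. A mean-over-sites alternative is a
`summary` switch. Group contrasts (`compare_microdiversity()`) use pairwise
Mann–Whitney U tests with the effect direction attached.

## Assembly metrics

N50 is the largest length *L* such that contigs ≥ *L* contain at least half
the assembly's bases. Error profiles against a trusted reference count
mismatches and indels over the supplied (primary) alignments; the
per-100-kbp figures use indel *events* while percent accuracy uses indel
*bases*, both over a denominator of aligned (matched-column) bases so that
unaligned contig tails cannot dilute error rates. Both event and base counts
are returned.

The ORF caller is deliberately simple: in each of the six frames, every
stop-to-stop stretch yields at most one ORF, from its first ATG to the stop
(stop excluded from the length, default minimum 30 aa, reverse-strand
coordinates mapped to the forward strand). It is a transparent stand-in for
a trained gene predictor: absolute protein-length medians are not comparable
to model-based callers, relative contrasts between assemblies of the same
sample are.

## The simulator: what it emulates, and what it does not

`sim_genomes()` draws i.i.d. bases at a per-genome GC fraction; defaults
(3 genomes, 38.2–129.4 kbp, GC 35.7–44.7%) emulate a small dsDNA phage mock
community. `sim_strain()` plants substitution-only variants at known
positions and frequency. `sim_long_reads()` places fragments uniformly on
circular genomes (phage chromosomes are circular or circularly permuted;
this also removes linear edge effects from coverage statistics), draws
log-normal lengths parameterised by their median, applies per-base
substitution/insertion/deletion errors at an indel-dominated Nanopore-like
default (1%/2%/3%), and, at `chimera_rate`, concatenates two independent
fragments, recording the junction. `sim_short_reads()` emits 2 × 125 bp
pairs from normal-sized inserts with substitution-only errors, optionally
sampling each insert from a minor strain haplotype. All generators are
seeded and byte-reproducible, and every read carries a truth record with
pre-error coordinates.

Truth-derived all-vs-all overlaps (`sim_read_overlaps()`) replace an
external aligner. One modelling choice matters for chimera detection: real
local alignments do not extend cleanly across a sequence breakpoint, so the
emitter trims a fixed `end_trim` (250 bp) from both ends of every overlap.
Staggered genuine overlaps still tile a genuine read, but at a chimeric
junction *every* overlap ends, opening a ~500 bp zero-coverage window that
the detector's 300 bp gap criterion sees. The margin is a property of the
emitter, not the detector, and is an argument.

The simulator does **not** model pore-level signal, homopolymer-specific
error, quality-score/error correlation beyond a per-read mean,
amplification bias other than the chimera rate, or real phage gene content.
Passing tests therefore demonstrate the correctness of the *rules and
estimators* on data satisfying their stated assumptions — not robustness to
every artifact of real flowcells. The error-robustness test (0.1%
substitution error, no true variants, ≤ 10⁻³ of sites called true SNPs)
covers the specific concern that raw sequencing error could inflate π.

## Numerical and scale choices

Degenerate inputs are pinned down explicitly: empty read sets pass through
QC as empty; a contig pair with no alignments has similarity (0, 0); a
Mann–Whitney comparison of identical pooled values returns p = 1; bootstrap
intervals of constant samples collapse to a point; `site_pi` at coverage
< 2 is `NA` and excluded; contigs with no true SNPs report π = 0. Rank ties
and clustering ties are always broken lexicographically so repeated runs are
byte-identical.

Test and validation problem sizes are chosen to be desk-scale while keeping
estimator noise well inside the asserted tolerances: 5–10 kbp genomes at
100–200× for π recovery (median over 40 sites × 10 seeds), 150 kbp of
genomes at 20× for chimera operating characteristics, 50 simulated contig
sets for dereplication, 200 libraries of 500 reads for bootstrap
calibration. The acceptance script (`scripts/acceptance.R`) re-runs all of
these from a single command-line seed.

## Known limitations

* Indel variants are out of scope for microdiversity: SNPs only, as in the
  upstream definition of the truth rule.
* No haplotype phasing or strain reconstruction; a strain mixture is
  summarised by per-site frequencies.
* The chimera detector needs all-vs-all overlaps and adequate depth; it
  does not attempt split-read realignment.
* `read_sam()` handles the single-segment subset of SAM used here (header,
  POS, CIGAR, SEQ, QUAL, optional NM); BAM/CRAM ingestion is delegated to
  Rsamtools upstream of the package if needed.
* Population abundance currently reflects whatever alignment set the caller
  supplies; the package does not itself enforce the mapping thresholds
  inside `rank_abundance()`.
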