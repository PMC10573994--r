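---
title: "Methods: simulating and analysing Sleeping Beauty integration sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Sleeping Beauty integration sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The Sleeping Beauty (SB) transposase integrates its cargo almost
exclusively at TA dinucleotides, duplicating the TA on insertion. Fusing
the transposase to a nucleolar protein such as B23/nucleophosmin
retargets part of the integration activity towards nucleolar chromatin:
the p-arms of the acrocentric chromosomes that carry the nucleolus
organizer regions (NORs), and the chromatin domains physically
associated with the nucleolus (NADs) or the nuclear lamina (LADs).
Measuring that retargeting from sequencing data is a multi-stage
pipeline: junction-library reads are cleaned and mapped, insertion sites
are called under read-support rules, and site counts are compared
between transposase conditions region by region.

`sbsites` implements that pipeline end to end, driven by a synthetic
data module that emulates the sequencing libraries and genome
annotations such a study uses. Every stage is an ordinary exported
function, so the same code path serves simulated and real inputs
(`load_genome()`, `read_fastq_pairs()` accept FASTA/BED/FASTQ of the
same shapes).

## The target model

Insertion probability is defined only at TA sites. For TA site $i$ the
sampling weight is

$$w_i \;=\; \prod_{R \ni i} \theta_R \;\times\; \begin{cases} w_{\mathrm{pal}} & \text{context}_i = \texttt{ATATATAT}\\ 1 & \text{otherwise,} \end{cases}$$

where the product runs over the labelled region sets containing the
site, $\theta_R \ge 0$ is the per-region multiplicative bias (default
1), and $w_{\mathrm{pal}} \ge 1$ weights sites whose 8-mer window
centred on the TA is exactly the palindromic AT repeat `ATATATAT` — the
consensus that SB target-site logos show. Insertions are drawn i.i.d.
with probabilities $w_i / \sum_j w_j$; sites may recur, mirroring
independent transposition events. A retargeted fusion transposase is
emulated by $\theta = 1.64$ on the acrocentric p-arms (the scale of the
effect the enrichment statistics are designed to detect), with milder
biases available for NAD/LAD/TF-peak sets.

The palindromic-context weight is exposed but defaults to 1: the logo
shape tells us the preference exists, but no published effect size pins
its magnitude, so the unweighted model is the default and the weight is
exercised only as a directional contract (a weight of 8 must raise
flanking A/T frequencies above the weight-1 baseline).

Two conventions keep bookkeeping unambiguous. All coordinates are
0-based, half-open. The insertion coordinate is always the offset of the
T of the target TA on the + strand, for either insertion orientation: SB
duplicates the TA, so both orientations share one canonical coordinate,
which is what deduplication, support counting and enrichment key on.

## The synthetic genome

`build_genome()` produces a desk-scale genome whose statistical
structure matches what the analysis must cope with:

* three acrocentric chromosomes (150 kb each) with a p13 / p12 / p11.2 /
  q band layout; two non-acrocentric chromosomes (200 kb) with p / q.
  The 20 kb acrocentric p-arm splits 5 / 10 / 5 kb over its three bands.
* the p12-like band emulates a NOR: it is built from exact tandem copies
  of a single 500 bp repeat unit (20 copies by default), so junction
  reads from it are genuinely multi-mapping, and its TA density target
  (0.01/bp) is well below the flanking bands (0.05/bp). The builder
  measures the realized densities and regenerates a chromosome in the
  (practically never observed) case the ordering fails, so the TA-poor
  NOR invariant is a guarantee, not a tendency.
* TA density is controlled through base composition: an i.i.d. sequence
  with $P(A) = P(T) = \sqrt{d}$ has expected TA density $d$ (possible
  for $d \le 0.25$; anything above is rejected as an unreachable
  composition target). The alphabet excludes N, so TA eligibility never
  needs an undefined-base rule.
* outside p12, short `ATATATAT` runs are planted at 0.2 per kb,
  emulating the (AT)n microsatellites of real genomes. An i.i.d.
  genome of this size would contain only a handful of
  palindromic-context TA sites — too few for the palindrome weight to
  have a measurable substrate — whereas real genomes are full of them;
  the planted rate is a realism choice made once, giving roughly 180
  such sites genome-wide.
* annotation sets are placed where their biology puts them: one NAD-like
  domain immediately distal to each acrocentric p-arm, LAD-like domains
  mostly on acrocentric q-arms, UBTF-like peaks inside p13/p11.2, and
  Pol II/III-like control peaks on the non-acrocentric chromosomes. This
  makes region-level targeting bias propagate into NAD/LAD/peak counts
  the way nucleolar retargeting does.

With these defaults the acrocentric p-arms hold about 4% of the
genome's TA weight. That share matters: the percent increase measured
on normalized in-region shares attenuates a per-site bias ratio
$\theta$ to $100\,(\theta / (1 + (\theta - 1) f) - 1)$ for weight share
$f$, so a small $f$ — as in the real genome, where acrocentric p-arms
are a few percent of the assembly — keeps the measured increase close
to the per-site ratio.

## The junction library

Each insertion event is first expanded into sonication fragments
(`expand_insertions()`, Poisson with mean 8 by default): in the wet
protocol every insertion clone grows through two weeks of selection, so
genomic DNA contains many copies of each insertion and shearing
recovers several distinct fragments per site. Those distinct shear
points are what "independent supporting reads" counts downstream.

Each fragment becomes `barcode + IR tail + genomic flank`, the flank
starting at the TA and running in the fragment's orientation for
(shear length − |IR|) bases. Shear lengths are Normal(600, 150)
rejection-sampled into the 200–500 bp size-selection window — the
simplest law matching the two constraints the protocol fixes (600 bp
mean sonication, 200–500 gel excision). Reads are 2×150: read 1 is the
fragment prefix, read 2 the reverse complement of its suffix.
Substitution errors are injected per base (default 0.001); a
configurable fraction of molecules (default 5%) carries plasmid
backbone instead of genome after the IR; PCR duplicates are Poisson
extra copies of the *post-error* parent, so they are byte-identical and
removable by exact-sequence deduplication, with rare additional errors
of their own at a tenth of the base rate. Qualities are constant: the
only quality-derived rule with analytical consequence downstream is the
≥ 30 bp minimum length, which is enforced on sequence length.

## Read processing

The pre-mapping stage mirrors the published tool order: demultiplex by
exact barcode prefix; require the IR-specific primer at its expected
offset within 6 mismatches; require the residual IR between primer and
junction within 2 mismatches (the primer budget is published, the
residual-IR budget is not — 2 is the exposed default); discard flanks
whose first 50 nt share any 25-mer with the backbone (either strand);
deduplicate byte-identical pairs *before* merging; merge mates whose
reverse-complemented read 2 overlaps read 1 by ≥ 10 bases at ≤ 10%
mismatch (largest acceptable overlap wins; read 1's base wins inside
the overlap, an arbitrary but fixed tie-break), keeping read 1 alone
for non-mergeable pairs; and drop junctions shorter than 30 bases. The
stage reports a reason-code partition of its input
(`in = out + rejected`), which the tests assert exactly.

## Mapping and site calling

The mapper is a deliberately small seed-and-verify aligner: exact
31-mers at query offsets 0 and 32 (both orientations) propose loci,
each verified by full-length Hamming distance within 5% of the read
length. Ties at the best distance form the candidate set. `unique` mode
maps only reads with exactly one best locus — the regime for the
genome-wide site table; `random` mode assigns one best locus uniformly
at random — the regime that keeps the repetitive NOR-like bands
countable. Indels are out of scope by construction (the simulator emits
substitutions only), which keeps the mapper small enough to verify
against constructed truth.

Sites are called by grouping mapped reads on (chromosome, TA
coordinate); strand does not split groups. Support is the number of
distinct shear keys — fragment identities — in the group, with
thresholds of 5 (unique regime) and 1 (random regime). Shear keys are
realized as (junction length, mate sequence) rather than a mapped mate
coordinate, because the mate is not independently aligned; in the
noiseless regime this induces the same equivalence classes as shear
coordinates, and PCR-duplicate copies that acquired extra errors can
inflate support only at the per-base duplicate error rate. Called
positions whose reference dinucleotide is not TA (possible under
sequencing error) are kept but flagged, and excluded from enrichment by
default, honouring SB's absolute TA requirement.

## Enrichment statistics

For each labelled region set, condition counts form the 2×2 table
`[in_A, out_A; in_B, out_B]`. The effect size is the percent increase
of B's normalized share, $100\,((c_B/N_B)/(c_A/N_A) - 1)$, with an
infinity sentinel when A's count is zero, plus a matching sample odds
ratio. Significance is the two-sided Fisher exact probability computed
by hypergeometric enumeration — the sum of probabilities of all tables
with the observed margins not exceeding the observed table's
probability (relative tie tolerance $1+10^{-7}$, the convention
standard implementations use). When no table is more probable than the
observed one the p-value is returned as exactly 1 rather than a
floating-point sum. The tests hold this implementation to exhaustive
enumeration over all tables with margins ≤ 40 at $10^{-10}$.

P-values are reported raw, one per region, matching how such per-region
tables are usually read; a flag adds Benjamini–Hochberg adjustment for
users who want it. Sites are points, so "in region" is point overlap of
the TA coordinate with the half-open region union, counting each site
once under overlapping regions.

Profiles: each cytoband is split into 300 near-equal windows (remainder
spread over the leading windows) and per-window site counts are
normalized by the RPKM principle — count per kilobase of window per
million total sites — making profiles comparable across bands and
depths. The companion TA-density track counts TA occurrences per
window, normalizes by window length, min–max scales to [0, 1] (a
constant track maps to 0.5 by convention) and smooths with loess,
span 0.3 — the span is not published; 0.3 visibly smooths 300 windows
without flattening band-scale structure. The loess fit is deterministic.

## Sequence logo

Contexts are the + strand windows `[pos − flank, pos + 2 + flank)`
(flank 10 by default; the published motif is the central 8-mer, the
window width around it is an exposed choice). Strand-pooling is safe
because the AT-palindromic motif is strand-symmetric. The position
frequency matrix columns sum to 1 and the per-column information
content is $2 + \sum_b f_b \log_2 f_b$ bits, the standard logo height;
for genuine SB sites the two centre columns are invariant TA at 2 bits.

## Determinism and numerical choices

Every stochastic stage takes a seed and derives independent
sub-streams from it; `run_pipeline()` writes byte-identical outputs for
identical (config, seed), which an acceptance test asserts via file
checksums. Weighted site sampling uses inverse-CDF lookup
(`cumsum` + binary search) — distributionally identical to naive
weighted sampling but linear-time for the near-uniform weight vectors
over tens of thousands of TA sites that the null-calibration replicates
draw from. Random-mode mapping orders reads canonically (by id) before
drawing so call sets are invariant to input order.

## Problem sizes

The shipped analyses run at desk scale, chosen so the full test suite
and the acceptance script complete in minutes on one CPU while keeping
every statistical check well-powered: an 850 kb genome with ~42,000 TA
sites; 50,000 insertions per condition for bias recovery (published SB
integration studies of this design work with libraries of 10⁵-scale
site counts); 100,000 per condition per replicate for the 100-replicate null
calibration, which bounds the mean absolute null percent-increase near
2%; and a few hundred insertion events, expanded ~8-fold into
fragments, for the end-to-end read-level runs.

## What the simulation does and does not show

The generator reproduces the statistical structure the analysis relies
on: TA restriction, region-level bias, a TA-poor internally repetitive
NOR-like band, shear/size-selection geometry, PCR duplication,
backbone contamination and substitution noise. It does not model real
rDNA repeat sequence, nucleolar dominance, diploidy or copy-number
variation of rDNA arrays, indels, adapter read-through, optical
duplicates or quality-score error profiles. Tests passing on this
substrate therefore validate the pipeline's logic and statistics — not
mapping performance on true centromeric satellite, nor the biological
magnitude of nucleolar retargeting, which only real libraries can
measure.
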