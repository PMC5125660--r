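---
title: "Models and methods behind verisim"
author: "verisim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind verisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`verisim` simulates short-read sequencing data with exact, machine-checkable
ground truth, and learns the distributions it samples from out of real-format
inputs. This vignette is the package's own account of those models: what is
assumed, which knobs matter, which choices were genuinely open, and what the
validation suite does and does not demonstrate.

## The mutation model

A mutation model is a set of conditional distributions over a region:

* the overall rate `P(mutation | position)` (mutations per base, bounded to
  `[0, 0.3]`);
* the type split `P(sub | mutation)`, `P(ins | mutation)`,
  `P(del | mutation)`;
* sixteen context-conditioned substitution matrices: for flanking bases
  `X` and `Z`, a 4×4 row-stochastic matrix
  `P(alt base | context X_Z, ref base)` with zero diagonal;
* a 64-entry trinucleotide site bias, the relative probability that a
  mutation lands on a site with a given trinucleotide, normalized by the
  reference abundance of that trinucleotide;
* indel length distributions `P(L | ins)`, `P(L | del)` over `L >= 1`.

**Learning** (`learnMutationModel`) locates each VCF record on the
reference, verifies the REF allele, and tallies. A SNP's context is the
base before and after the site; its transition count is divided by the
reference census count of the source trinucleotide and each row is then
normalized into a conditional distribution. (Within one row the census
divisor is constant, so it cancels in the row normalization; it matters
for the site-bias vector, where hit counts per trinucleotide are divided
by abundance before normalizing.) Multi-allelic records contribute one
alternate allele picked at random. Records that contradict the reference,
use symbolic or non-ACGT alleles, or describe multi-nucleotide
replacements are skipped and counted in the `stats` attribute. Matrix rows
with no training data fall back to a uniform distribution over the three
alternates and are flagged in `unobservedRows`.

**Sampling** works through the reference in sliding windows (default
10,000 bases, 100-base overlap; see "Windows" below). Within each window
core the number of sites is the stochastically rounded product of callable
length and overall rate — floor plus a Bernoulli on the fraction, so small
windows are unbiased — or, when a mutation-rate BED is supplied, the sum
of per-position rates with sites drawn proportional to the local rate.
Site selection is otherwise uniform; drawing sites proportional to the
learned trinucleotide bias is available as an option
(`useTrinucBias`) but off by default, since what a mutation *becomes* is
modelled separately from *where* it lands and coupling the two changes the
meaning of a user-supplied rate track.

Deletions sampled at a site remove bases starting at that site and anchor
the VCF record one base to the left, as VCF convention expects; at a
window's first base, where no upstream anchor exists inside the window,
the site itself anchors and downstream bases are deleted. Inserted bases
are i.i.d. uniform over ACGT — insertion motifs are deliberately out of
scope. Genotypes are drawn per variant: with probability `hetFraction`
(default 2/3) a single uniformly chosen copy carries the alternate,
otherwise all copies do. Overlapping events are resolved by dropping the
later sampled event; variants from an input VCF always win conflicts and
are inserted verbatim.

## The sequencing model

### Quality scores

Quality strings are generated by a time-inhomogeneous Markov chain over
Phred values `0..qMax` (default `qMax = 41`, the ceiling of Phred+33
encoding): an initial distribution for cycle 1 and one transition matrix
per later cycle. Learning is a per-position frequency count of observed
transitions. Reads simulated at a length different from the model's map
target position `p` onto model position
`round(1 + (p-1)(L-1)/(T-1))`, so a 100-cycle profile stretches smoothly
to, say, 250-cycle reads. Transition rows never observed in training fall
back to uniform at sampling time. The built-in default chain
(`defaultQualityModel`) is a synthetic Illumina-like profile: scores start
near Q37, decay toward the 3' end, and regress toward the positional mean
with Gaussian spread.

### Sequencing errors

Each read base errs with probability `min(1, scale * 10^(-Q/10))`. The
Phred assumption — that the quality string honestly reports the error
probability — is taken as the base law, and a single learned or user-set
`scale` reconciles it with reality. This makes "simulate at error rate r"
well defined for any r: `scale = r / E[10^(-Q/10)]`, with the expectation
computed analytically from the quality chain's marginals
(`expectedPhredErrorProb`), not by Monte Carlo. A per-quality empirical
error table was considered and rejected as the primary representation
because it leaves rate rescaling ambiguous.

Given an error, its type, substituted base, indel length and inserted
bases follow learned discrete distributions. Indel likelihood is uniform
along the read — no homopolymer or positional dependence. Deletion errors
pull downstream template bases into the read (the simulator extracts a
margin beyond the read length for this); insertions push bases out; the
read is re-truncated to its length, and the sampled quality string stays
attached to machine cycles rather than bases. Golden CIGARs describe the
error-free alignment; the per-read error list (returned with
`returnReads = TRUE`) reconciles the emitted sequence against it.

Error learning from alignments classifies a read position as a sequencing
error iff it is a mismatch or an indel of at most `maxIndelLen` (default
4) bases, the site's variant allele frequency is below `vafThreshold`
(default 0.2), the base quality is below `qThreshold` (default 10), the
read's MAPQ is above `mapqThreshold` (default 10), and it is not adjacent
to another mismatch or indel in the same read (part of a larger event).
The thresholds are exposed as arguments; the defaults are conventional
working values for separating machine errors from real variation, not
fitted constants.

### Read sampling

Fragment starts are drawn per window core with per-position weights: the
target factor (98% of requested coverage inside target intervals, 2%
outside, both configurable — the two are depth fractions of the requested
coverage, not mixture weights), the GC multiplier of the enclosing
GC window, and an N mask. The expected fragment count is
`coverage / (readsPerFragment * readLength)` times the summed weights, and
the realized count is Poisson around it, so with unit weights the mean
depth equals the requested coverage exactly in expectation. Paired-end
fragments are FR-oriented with mate 1 always the 5' forward mate;
single-end reads are emitted forward-strand (which keeps the null-model
property that every read is a reference substring). Fragment lengths come
from an empirical template-length histogram learned from the TLEN field of
paired alignments (zero and implausibly large values skipped), or from a
discretized Gaussian fallback when no alignment is available — real insert
distributions are often non-Gaussian, which is why the empirical form is
primary.

GC bias is learned over non-overlapping 100-base windows (integer GC-count
bins): per-bin mean coverage divided by overall mean coverage, empty bins
interpolated from neighbors, multipliers capped (default 5) to avoid
degenerate amplification and renormalized so the abundance-weighted mean
is exactly 1, which conserves mean coverage when the bias is applied. The
weighted-mean-1 invariant makes an "all multipliers zero" model
unrepresentable by construction; the zero-weight sampling path is instead
exercised through N masking.

## Windows and coordinate bookkeeping

All internal coordinates are 0-based half-open; conversion to 1-based
happens only when writing VCF and SAM. Windows of 10,000 bases overlap by
100; each window owns a non-overlapping core (the window minus its tail
overlap) and the cores partition the contig. Mutations are sampled per
core in a first pass; in the second pass each window applies every
mutation anchored anywhere in its span, so the haplotypes of adjacent
windows agree base-for-base on the shared overlap and every read —
including one crossing a core boundary — reconstructs exactly from the
golden VCF applied to the reference. Sampled deletions are truncated so no
footprint crosses a window-span boundary. Fragments are sampled from
cores; a fragment whose length would overrun the window span has its start
redrawn from the feasible prefix of the same weight vector, conserving the
expected count while slightly redistributing starts near window ends. The
window size bounds the scale below which a mutation-rate BED can vary
meaningfully, and the overlap must exceed the largest indel the model can
emit.

Each haplotype copy carries a coordinate map — runs of reference-aligned
bases — from which golden CIGARs are built by a single walk (M/I/D against
the original reference, boundary insertions soft-clipped, boundary
deletions dropped). Read names encode the truth for both mates
(`prefix:serial:contig:pos1:strand1:cigar1:pos2:strand2:cigar2`), because
SAM requires mates to share a name; the same truth is duplicated into
local-use SAM tags (`zp`, `zs`, `zc`, `zh`) so it survives renaming.

## Evaluation

Alignment scoring decodes the truth from read names: position-correct
means same contig within a tolerance (default 0); CIGAR-correct
additionally requires equal normalized CIGARs (adjacent runs merged, hard
and soft clips equated) and implies position-correct. VCF comparison is
presence/absence on `(contig, pos, ref, alt)` after splitting
multi-allelic records; genotype concordance is reported separately and
deliberately does not affect TP/FP/FN. With equivalence detection on,
unmatched variants are clustered (gap ≤ 50 bases, configurable) and each
cluster's golden and test groups are applied to the reference window — if
they spell the same alternate sequence (per haplotype copy when both sides
carry genotypes of equal ploidy) the cluster counts as matched. False
negatives are diagnosed as `unmappable` when the read-length k-mer at the
position (counting both strands) is not unique in the reference,
`low-coverage` when golden depth is below the threshold (default 10), else
`other`; unmappability wins when both hold, as the root cause.

## The synthetic-data generators

`randomReference` emulates only base composition (i.i.d. bases at a chosen
GC fraction); it has none of the repeat structure, homopolymer runs or
compositional heterogeneity of real genomes. `randomMutationModel` draws
all conditional distributions from a Dirichlet so round trips exercise
asymmetric models. Consequently the passing round-trip suites show that
the learners invert the samplers at realistic sample sizes — they do not
show that the default models match any particular instrument or cohort,
nor how the tools behave on repeat-rich references, where mappability, not
model fidelity, dominates caller performance.

## Validation scales and numerical choices

The validation suite simulates at sizes chosen so that sampling noise sits
well inside each tolerance: the mutation round trip learns ~10^5 variants
from a 5 Mb reference (≈1,500 observations per matrix row, total-variation
tolerance 0.05); the quality-chain round trip compares transition rows
with expected occupancy ≥ 2,500 — rows below that are not learnable from
any finite FASTQ at the stated tolerance, and unvisited rows are uniform
fallbacks by construction; the fragment round trip uses ~3×10^4 pairs over
a 13-point support; golden consistency is checked read-by-read at 30×
over a megabase; the error-rate contract is measured over ≥2×10^6
sequenced bases with a substitution-only model, so the mismatch count is a
pure hamming distance and is not confounded by frameshifted tails that
indel errors would introduce into a naive comparison.

Other numerical choices: stochastic rounding wherever an expectation must
become a count; a single seeded RNG stream with fixed draw order
(mutations window-major, then fragments/qualities/errors window-major), so
a fixed seed reproduces outputs byte-identically; conflict ties broken
deterministically (input VCF beats sampled, earlier position beats later);
overlapping BED intervals merged with the maximum value winning;
distributions that would normalize a zero vector return an explicit
uniform fallback rather than NaN.

## Known limitations

Adapter contamination, duplicates, flowcell artifacts and variable-length
long reads are not emulated. Structural variation enters only verbatim
through an input VCF with explicit REF/ALT sequences; symbolic alleles are
skipped. Linkage disequilibrium and population haplotype structure are not
simulated. Germline-context normalization of somatic models (matched
normal trinucleotides) is out of scope; only reference-abundance
normalization is implemented. The targeted mode scales depth by a step
function at target boundaries — read pairs straddling a boundary smear it
by about a fragment length — with no probe-hybridization physics. Input
VCF deletions whose footprint crosses a window-core boundary are applied,
but reads from the neighboring window may then disagree with the global
haplotype over the crossed span; sampled deletions are constructed never
to do this.
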