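# verisim

Simulation of next-generation sequencing reads with verifiable ground
truth, for benchmarking aligners and variant callers.

Validating a variant-calling workflow needs datasets where the true
variants and the true read origins are known exactly — something real
sequencing data almost never provides. `verisim` addresses this in three
parts:

1. **Model learning.** Empirical models are learned from real-format
   inputs: a *mutation model* from variant calls (VCF) against a reference
   (FASTA), and a *sequencing model* from reads (FASTQ) and alignments
   (SAM).
2. **Simulation.** Reads are sampled from the reference under those models
   at arbitrary read length, coverage, ploidy and error/mutation rates,
   producing FASTQ files plus *golden* truth files: a SAM of true
   alignments (position, strand, CIGAR) and a VCF of inserted variants
   with phased genotypes.
3. **Evaluation.** Aligner output is scored against the truth embedded in
   the read names; caller VCFs are partitioned into TP/FP/FN against the
   golden VCF, with detection of equivalently represented variants and
   diagnosis of false negatives by coverage and mappability.

## The models

**Mutation model.** Mutations are placed and realized from learned
conditional distributions:

- P(mutation | genomic position) — the overall per-base rate, optionally
  modulated by a BED track of regional rates;
- P(substitution | mutation), P(insertion | mutation),
  P(deletion | mutation);
- P(substituted base = Y | trinucleotide context = X_Z) — sixteen 4×4
  substitution matrices indexed by the flanking bases, so e.g. row G,
  column C of the `A_A` matrix is the probability that AGA mutates to ACA;
- P(length = L | insertion), P(length = L | deletion).

Learned matrix entries are transition counts normalized by the reference
abundance of the source trinucleotide and then row-normalized. Variants
are inserted into a configurable fraction of the ploidy copies, so a
tetraploid heterozygous variant appears in the golden VCF as `0|1|0|0`.

**Sequencing model.** Three sub-models:

- *Quality scores*: a time-inhomogeneous Markov chain,
  P(Q at position p | Q at p−1), learned per position from FASTQ;
  profiles stretch to arbitrary simulated read lengths.
- *Sequencing errors*: per-base errors at
  `min(1, scale · 10^(−Q/10))` with learned type fractions, substitution
  matrix, indel lengths and inserted-base composition. Errors are learned
  from alignments by selecting low-VAF, low-quality mismatches and short
  indels on well-mapped reads.
- *Read sampling*: GC-content coverage multipliers over fixed windows and
  an empirical fragment-length (template-length) distribution; targeted
  runs deliver 98%/2% of the requested depth on/off target by default.

## Worked example

```r
library(verisim)

ref <- randomReference(1, 100000, gcFraction = 0.5, seed = 1)
out <- file.path(tempdir(), "demo")
res <- simulateReads(ref, out,
                     simConfig(coverage = 30, readLength = 100,
                               mutationRate = 0.002, errorRate = 0.005,
                               seed = 7))
print(res)
#> verisim simulation: 30066 reads (15033 fragments), 199 golden variants

## re-learn the mutation model from the golden VCF
model <- learnMutationModel(paste0(out, "_golden.vcf"), ref)
print(model)
#> MutationModel
#>   overall rate: 0.00199 per base
#>   type fractions: sub 0.889, ins 0.0452, del 0.0653
#>   unobserved matrix rows: 1

## score the golden alignment and VCF against themselves
show(compareAlignments(paste0(out, "_golden.sam")))
#> AlignmentReport: 30066 reads; position correct 30066 (100%); CIGAR correct 30066 (100%); unmapped 0; undecodable 0
show(compareVcfs(paste0(out, "_golden.vcf"), paste0(out, "_golden.vcf"), ref))
#> VcfComparisonReport: golden 199, test 199; TP 199, FP 0, FN 0 (0 equivalent-representation groups)
```

The simulation requested a mutation rate of 0.002 and realized
199 variants over 100 kb (0.00199 per base); 30066 reads of 100 bp over
100 kb is the requested 30× depth. Feeding the golden outputs back to the
evaluators gives perfect scores — the starting point for measuring how
far a real aligner or caller falls from them.

## Command line

A thin shell entry point wraps the same functions:

```sh
inst/cli/verisim make-ref --out ref.fa --length 100000 --seed 1
inst/cli/verisim gen-reads --ref ref.fa --read-len 100 --out sim --coverage 30 --seed 7
inst/cli/verisim compare-bam --test aligned.sam
inst/cli/verisim compare-vcf --golden sim_golden.vcf --test calls.vcf --ref ref.fa --equivalence
```

Every run writes a manifest JSON (parameters, seed, model checksums)
sufficient to reproduce its outputs byte-identically.

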