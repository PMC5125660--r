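#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## RegionTrack: BED-derived intervals carrying a scalar (mutation rate or
## target flag). Coordinates are held as GRanges (1-based closed internally,
## converted from/to 0-based half-open at the BED boundary).
## ---------------------------------------------------------------------------

#' Interval track with attached scalar values
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose `value` metadata column holds a
#' per-interval scalar: a positional mutation rate (semantics
#' `"mutation-rate"`) or a capture-target indicator (semantics `"target"`).
#' Overlapping input intervals are normalized at construction: they are
#' disjoined and the maximum value wins where they overlap.
#'
#' @slot regions GRanges with numeric metadata column `value`.
#' @slot semantics either `"mutation-rate"` or `"target"`.
#' @exportClass RegionTrack
setClass("RegionTrack",
  representation(regions = "GRanges", semantics = "character"))

setValidity("RegionTrack", function(object) {
  msg <- character(0)
  if (!object@semantics %in% c("mutation-rate", "target"))
    msg <- c(msg, "semantics must be 'mutation-rate' or 'target'")
  v <- object@regions$value
  if (is.null(v) || !is.numeric(v))
    msg <- c(msg, "regions must carry a numeric 'value' column")
  else if (any(v < 0)) msg <- c(msg, "values must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MutationModel
## ---------------------------------------------------------------------------

#' Region-level mutation model
#'
#' Holds the probabilities used to place and realize germline/somatic
#' mutations: the overall per-base mutation rate, the split between
#' substitutions, insertions and deletions, sixteen context-conditioned 4x4
#' substitution matrices (one per flanking-base pair `"X_Z"`, rows = reference
#' base, columns = substituted base, zero diagonal), a 64-entry trinucleotide
#' site bias (relative probability that a mutation lands on a site with that
#' trinucleotide, normalized by reference trinucleotide abundance), and the
#' indel length distributions.
#'
#' @slot overallRate numeric, P(mutation | position), in [0, 0.3].
#' @slot typeFractions named numeric: `sub`, `ins`, `del`; sums to 1.
#' @slot trinucMatrices named list of 16 4x4 row-stochastic matrices.
#' @slot trinucBias named numeric over the 64 trinucleotides; sums to 1.
#' @slot insLengths,delLengths named numeric distributions over lengths >= 1.
#' @slot unobservedRows character, `"X_Z:B"` labels of matrix rows that had no
#'   training data and fall back to a uniform distribution over the three
#'   alternate bases.
#' @exportClass MutationModel
setClass("MutationModel",
  representation(overallRate = "numeric", typeFractions = "numeric",
                 trinucMatrices = "list", trinucBias = "numeric",
                 insLengths = "numeric", delLengths = "numeric",
                 unobservedRows = "character"))

setValidity("MutationModel", function(object) {
  msg <- character(0)
  if (object@overallRate < 0 || object@overallRate > 0.3)
    msg <- c(msg, "overallRate must lie in [0, 0.3]")
  if (length(object@typeFractions) != 3L ||
      abs(sum(object@typeFractions) - 1) > 1e-6)
    msg <- c(msg, "typeFractions must be 3 values summing to 1")
  if (length(object@trinucMatrices) != 16L)
    msg <- c(msg, "expected 16 trinucleotide context matrices")
  for (m in object@trinucMatrices) {
    if (!all(dim(m) == c(4L, 4L)) || any(abs(rowSums(m) - 1) > 1e-6) ||
        any(diag(m) != 0))
      msg <- c(msg, "each context matrix must be 4x4 row-stochastic with zero diagonal")
  }
  if (abs(sum(object@trinucBias) - 1) > 1e-6)
    msg <- c(msg, "trinucBias must sum to 1")
  for (d in list(object@insLengths, object@delLengths))
    if (length(d) && abs(sum(d) - 1) > 1e-6)
      msg <- c(msg, "indel length distributions must sum to 1")
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## Sequencing sub-models
## ---------------------------------------------------------------------------

#' Position-dependent Markov model of quality scores
#'
#' A time-inhomogeneous Markov chain over Phred values 0..qMax: an initial
#' distribution for read position 1 and, for each later position, a
#' (qMax+1) x (qMax+1) transition matrix P(Q at p | Q at p-1). Rows never
#' observed in training are flagged and replaced by a uniform distribution at
#' sampling time. When reads of a different length are simulated, target
#' positions are mapped linearly onto model positions.
#'
#' @slot readLength model read length L.
#' @slot qMax highest quality score (41 for typical Phred+33 data).
#' @slot initDist numeric length qMax+1.
#' @slot transitions array `c(L, qMax+1, qMax+1)`; slice p is the transition
#'   matrix into position p (slice 1 unused).
#' @exportClass QualityModel
setClass("QualityModel",
  representation(readLength = "integer", qMax = "integer",
                 initDist = "numeric", transitions = "array"))

setValidity("QualityModel", function(object) {
  msg <- character(0)
  q1 <- object@qMax + 1L
  if (abs(sum(object@initDist) - 1) > 1e-6)
    msg <- c(msg, "initDist must sum to 1")
  if (!all(dim(object@transitions) == c(object@readLength, q1, q1)))
    msg <- c(msg, "transitions must be an (L, qMax+1, qMax+1) array")
  if (any(object@transitions < 0)) msg <- c(msg, "negative transition mass")
  if (length(msg)) msg else TRUE
})

#' Sequencing-error model
#'
#' Per-base errors occur with probability `errorScale * 10^(-Q/10)`; given an
#' error, its type (substitution/insertion/deletion), substituted base,
#' indel length and inserted bases follow the learned discrete distributions.
#'
#' @slot errorScale multiplier on the Phred-implied error probability.
#' @slot typeFractions named numeric `sub`/`ins`/`del`, sums to 1.
#' @slot subMatrix 4x4 row-stochastic, P(read base | true base), zero diagonal.
#' @slot indelLengths named numeric distribution over indel lengths.
#' @slot insBases named numeric over ACGT, distribution of inserted bases.
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(errorScale = "numeric", typeFractions = "numeric",
                 subMatrix = "matrix", indelLengths = "numeric",
                 insBases = "numeric"))

setValidity("ErrorModel", function(object) {
  msg <- character(0)
  if (object@errorScale < 0) msg <- c(msg, "errorScale must be >= 0")
  if (abs(sum(object@typeFractions) - 1) > 1e-6)
    msg <- c(msg, "typeFractions must sum to 1")
  if (any(abs(rowSums(object@subMatrix) - 1) > 1e-6) ||
      any(diag(object@subMatrix) != 0))
    msg <- c(msg, "subMatrix must be row-stochastic with zero diagonal")
  if (abs(sum(object@indelLengths) - 1) > 1e-6)
    msg <- c(msg, "indelLengths must sum to 1")
  if (abs(sum(object@insBases) - 1) > 1e-6)
    msg <- c(msg, "insBases must sum to 1")
  if (length(msg)) msg else TRUE
})

#' GC-content coverage bias
#'
#' Coverage multipliers per GC count over non-overlapping windows of
#' `windowSize` bases. The abundance-weighted mean multiplier is 1, so
#' applying the bias conserves mean coverage on the reference it was trained
#' on.
#'
#' @slot windowSize window size in bases.
#' @slot multipliers numeric length windowSize+1 (GC counts 0..windowSize).
#' @slot abundance number of training windows observed per GC bin.
#' @exportClass GcBiasModel
setClass("GcBiasModel",
  representation(windowSize = "integer", multipliers = "numeric",
                 abundance = "numeric"))

setValidity("GcBiasModel", function(object) {
  msg <- character(0)
  if (length(object@multipliers) != object@windowSize + 1L)
    msg <- c(msg, "need one multiplier per GC count 0..windowSize")
  if (any(object@multipliers < 0)) msg <- c(msg, "multipliers must be >= 0")
  if (sum(object@abundance) > 0) {
    wm <- weighted.mean(object@multipliers, object@abundance)
    if (abs(wm - 1) > 1e-6)
      msg <- c(msg, "abundance-weighted mean multiplier must be 1")
  }
  if (length(msg)) msg else TRUE
})

#' Fragment (insert) length model
#'
#' Either an empirical distribution of template lengths or a discretized
#' Gaussian fallback for when no alignment data are available.
#'
#' @slot kind `"empirical"` or `"gaussian"`.
#' @slot support,probs empirical support (template lengths) and probabilities.
#' @slot mean,sd Gaussian parameters (used when kind is `"gaussian"`).
#' @exportClass FragmentModel
setClass("FragmentModel",
  representation(kind = "character", support = "integer", probs = "numeric",
                 mean = "numeric", sd = "numeric"))

setValidity("FragmentModel", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("empirical", "gaussian"))
    msg <- c(msg, "kind must be 'empirical' or 'gaussian'")
  if (object@kind == "empirical") {
    if (length(object@support) == 0L || abs(sum(object@probs) - 1) > 1e-6)
      msg <- c(msg, "empirical model needs probs summing to 1")
    if (any(object@support <= 0L)) msg <- c(msg, "support must be positive")
  } else if (object@mean <= 0 || object@sd < 0)
    msg <- c(msg, "gaussian model needs mean > 0 and sd >= 0")
  if (length(msg)) msg else TRUE
})

#' Composite sequencing model
#'
#' Bundles the four sequencing sub-models: forward (and optionally reverse)
#' quality chain, the error model, an optional GC bias model and the fragment
#' length model.
#'
#' @slot qualityFwd,qualityRev QualityModel (qualityRev may be NULL, in which
#'   case the forward model is used for mate 2).
#' @slot error ErrorModel.
#' @slot gcBias GcBiasModel or NULL (no bias).
#' @slot fragment FragmentModel.
#' @exportClass SequencingModel
setClass("SequencingModel",
  representation(qualityFwd = "QualityModel", qualityRev = "ANY",
                 error = "ErrorModel", gcBias = "ANY",
                 fragment = "FragmentModel"))

setValidity("SequencingModel", function(object) {
  msg <- character(0)
  if (!is.null(object@qualityRev) && !is(object@qualityRev, "QualityModel"))
    msg <- c(msg, "qualityRev must be NULL or a QualityModel")
  if (!is.null(object@gcBias) && !is(object@gcBias, "GcBiasModel"))
    msg <- c(msg, "gcBias must be NULL or a GcBiasModel")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Simulation run configuration
#'
#' @slot readLength read length in bases (>= 20).
#' @slot coverage requested mean depth.
#' @slot paired logical; paired-end (FR) vs single-end.
#' @slot ploidy haplotype copies per window (default 2).
#' @slot mutationRate override of the mutation model's overall rate (NA keeps
#'   the model value).
#' @slot errorRate requested mean per-base sequencing error rate (NA keeps the
#'   error model's scale).
#' @slot onTargetFraction,offTargetFraction fractions of the requested
#'   coverage delivered on and off target when a target track is supplied
#'   (defaults 0.98 / 0.02).
#' @slot windowSize,windowOverlap sliding-window tiling of the reference.
#' @slot hetFraction probability that a sampled variant is heterozygous
#'   (single altered copy) rather than homozygous.
#' @slot writeFastq emit FASTQ (disable to produce truth files only; quality
#'   and error draws are skipped, so the random stream differs from a full
#'   run).
#' @slot keepHaplotypes retain the stitched mutated haplotype sequences in the
#'   returned object.
#' @slot returnReads retain a per-read table (name, truth, sequence) in the
#'   returned object.
#' @slot seed integer seed (NA = do not touch the RNG state).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(readLength = "integer", coverage = "numeric",
                 paired = "logical", ploidy = "integer",
                 mutationRate = "numeric", errorRate = "numeric",
                 onTargetFraction = "numeric", offTargetFraction = "numeric",
                 windowSize = "integer", windowOverlap = "integer",
                 hetFraction = "numeric", writeFastq = "logical",
                 keepHaplotypes = "logical", returnReads = "logical",
                 seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@readLength < 20L) msg <- c(msg, "readLength must be >= 20")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
  if (object@ploidy < 1L) msg <- c(msg, "ploidy must be >= 1")
  if (object@offTargetFraction < 0 || object@offTargetFraction > 1 ||
      object@onTargetFraction < 0 || object@onTargetFraction > 1)
    msg <- c(msg, "target fractions must lie in [0, 1]")
  if (object@windowSize <= 2L * object@windowOverlap ||
      object@windowOverlap <= 0L)
    msg <- c(msg, "need windowSize > 2*windowOverlap > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Reports
## ---------------------------------------------------------------------------

#' Aligner accuracy report
#'
#' @slot nReads,nCorrectPosition,nCorrectCigar,nUnmapped,nUnknown counts.
#' @slot mismatches data.frame of reads failing the position or CIGAR check.
#' @exportClass AlignmentReport
setClass("AlignmentReport",
  representation(nReads = "integer", nCorrectPosition = "integer",
                 nCorrectCigar = "integer", nUnmapped = "integer",
                 nUnknown = "integer", mismatches = "data.frame"))

#' Variant-call comparison report
#'
#' @slot nGolden,nTest,TP,FP,FN counts after equivalence grouping.
#' @slot nEquivalentGroups groups matched only through haplotype equivalence.
#' @slot fpRecords,fnRecords data.frames of the residual FP/FN variants.
#' @slot fnCategories named integer: low-coverage / unmappable / other split
#'   of the FN set (empty until diagnosis is run).
#' @slot genotypeConcordance fraction of exactly matched sites with equal
#'   genotype (NA when genotypes are absent).
#' @exportClass VcfComparisonReport
setClass("VcfComparisonReport",
  representation(nGolden = "integer", nTest = "integer", TP = "integer",
                 FP = "integer", FN = "integer",
                 nEquivalentGroups = "integer",
                 fpRecords = "data.frame", fnRecords = "data.frame",
                 fnCategories = "integer", genotypeConcordance = "numeric"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "RegionTrack", function(object) {
  cat("RegionTrack (", object@semantics, ") with ",
      length(object@regions), " intervals\n", sep = "")
})

setMethod("show", "MutationModel", function(object) {
  tf <- object@typeFractions
  cat("MutationModel\n",
      "  overall rate: ", signif(object@overallRate, 4), " per base\n",
      "  type fractions: sub ", signif(tf[["sub"]], 3),
      ", ins ", signif(tf[["ins"]], 3), ", del ", signif(tf[["del"]], 3), "\n",
      "  unobserved matrix rows: ", length(object@unobservedRows), "\n",
      sep = "")
})

setMethod("show", "QualityModel", function(object) {
  cat("QualityModel: L=", object@readLength, ", qMax=", object@qMax, "\n",
      sep = "")
})

setMethod("show", "ErrorModel", function(object) {
  cat("ErrorModel: scale ", signif(object@errorScale, 4),
      ", sub/ins/del = ", paste(signif(object@typeFractions, 3),
                                collapse = "/"), "\n", sep = "")
})

setMethod("show", "FragmentModel", function(object) {
  if (object@kind == "empirical")
    cat("FragmentModel (empirical), ", length(object@support),
        " lengths, mean ", round(sum(object@support * object@probs), 1),
        "\n", sep = "")
  else
    cat("FragmentModel (gaussian), mean ", object@mean, ", sd ", object@sd,
        "\n", sep = "")
})

setMethod("show", "SequencingModel", function(object) {
  cat("SequencingModel\n")
  show(object@qualityFwd)
  show(object@error)
  show(object@fragment)
  cat("  GC bias: ", if (is.null(object@gcBias)) "none" else "present",
      "; reverse-mate quality model: ",
      if (is.null(object@qualityRev)) "reuses forward" else "present",
      "\n", sep = "")
})

setMethod("show", "AlignmentReport", function(object) {
  n <- max(1L, object@nReads)
  cat("AlignmentReport: ", object@nReads, " reads; position correct ",
      object@nCorrectPosition, " (", round(100 * object@nCorrectPosition / n, 2),
      "%); CIGAR correct ", object@nCorrectCigar, " (",
      round(100 * object@nCorrectCigar / n, 2), "%); unmapped ",
      object@nUnmapped, "; undecodable ", object@nUnknown, "\n", sep = "")
})

setMethod("show", "VcfComparisonReport", function(object) {
  cat("VcfComparisonReport: golden ", object@nGolden, ", test ", object@nTest,
      "; TP ", object@TP, ", FP ", object@FP, ", FN ", object@FN,
      " (", object@nEquivalentGroups, " equivalent-representation groups)\n",
      sep = "")
  if (length(object@fnCategories))
    cat("  FN diagnosis: ",
        paste(names(object@fnCategories), object@fnCategories,
              sep = "=", collapse = ", "), "\n", sep = "")
})
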