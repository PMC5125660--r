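## Accessor generics: slot access stays behind these.

#' @rdname MutationModel-class
#' @param object a model or report object.
#' @export
setGeneric("overallRate", function(object) standardGeneric("overallRate"))
#' @rdname MutationModel-class
#' @export
setGeneric("typeFractions", function(object) standardGeneric("typeFractions"))
#' @rdname MutationModel-class
#' @export
setGeneric("trinucMatrices", function(object) standardGeneric("trinucMatrices"))
#' @rdname MutationModel-class
#' @export
setGeneric("trinucBias", function(object) standardGeneric("trinucBias"))
#' @rdname MutationModel-class
#' @export
setGeneric("indelLengths", function(object) standardGeneric("indelLengths"))

#' @rdname QualityModel-class
#' @export
setGeneric("qMax", function(object) standardGeneric("qMax"))
#' @rdname QualityModel-class
#' @export
setGeneric("modelReadLength", function(object) standardGeneric("modelReadLength"))

#' @rdname FragmentModel-class
#' @export
setGeneric("fragmentProbs", function(object) standardGeneric("fragmentProbs"))

#' @rdname RegionTrack-class
#' @export
setGeneric("trackRegions", function(object) standardGeneric("trackRegions"))
#' @rdname RegionTrack-class
#' @export
setGeneric("trackSemantics", function(object) standardGeneric("trackSemantics"))

#' @describeIn MutationModel-class overall per-base mutation rate.
setMethod("overallRate", "MutationModel", function(object) object@overallRate)
#' @describeIn MutationModel-class sub/ins/del split.
setMethod("typeFractions", "MutationModel", function(object) object@typeFractions)
#' @describeIn ErrorModel-class sub/ins/del split given an error.
setMethod("typeFractions", "ErrorModel", function(object) object@typeFractions)
#' @describeIn MutationModel-class the 16 context substitution matrices.
setMethod("trinucMatrices", "MutationModel", function(object) object@trinucMatrices)
#' @describeIn MutationModel-class 64-entry trinucleotide site bias.
setMethod("trinucBias", "MutationModel", function(object) object@trinucBias)
#' @describeIn MutationModel-class list with `ins` and `del` length distributions.
setMethod("indelLengths", "MutationModel",
          function(object) list(ins = object@insLengths, del = object@delLengths))
#' @describeIn ErrorModel-class indel-error length distribution.
setMethod("indelLengths", "ErrorModel", function(object) object@indelLengths)
#' @describeIn QualityModel-class highest representable quality score.
setMethod("qMax", "QualityModel", function(object) object@qMax)
#' @describeIn QualityModel-class model read length.
setMethod("modelReadLength", "QualityModel", function(object) object@readLength)
#' @describeIn FragmentModel-class data.frame of template length vs probability.
setMethod("fragmentProbs", "FragmentModel", function(object) {
  if (object@kind == "empirical")
    data.frame(length = object@support, prob = object@probs)
  else {
    s <- seq.int(max(1, floor(object@mean - 4 * object@sd)),
                 ceiling(object@mean + 4 * object@sd))
    p <- dnorm(s, object@mean, object@sd)
    data.frame(length = as.integer(s), prob = p / sum(p))
  }
})
#' @describeIn RegionTrack-class underlying GRanges.
setMethod("trackRegions", "RegionTrack", function(object) object@regions)
#' @describeIn RegionTrack-class the semantics tag.
setMethod("trackSemantics", "RegionTrack", function(object) object@semantics)
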