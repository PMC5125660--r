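## JSON serialization of sequencing models: one versioned document with
## mergeable quality / error / GC / fragment sub-documents.

qualityModelToDoc <- function(m) {
  if (is.null(m)) return(NULL)
  list(readLength = m@readLength, qMax = m@qMax,
       initDist = m@initDist,
       transitions = as.vector(m@transitions),
       dims = dim(m@transitions))
}

docToQualityModel <- function(d) {
  if (is.null(d)) return(NULL)
  tr <- array(d$transitions, dim = unlist(d$dims))
  QualityModel(initDist = unlist(d$initDist), transitions = tr,
               qMax = d$qMax)
}

errorModelToDoc <- function(m) {
  list(errorScale = m@errorScale, typeFractions = as.list(m@typeFractions),
       subMatrix = as.data.frame(m@subMatrix),
       indelLengths = as.list(m@indelLengths),
       insBases = as.list(m@insBases))
}

docToErrorModel <- function(d) {
  sm <- as.matrix(d$subMatrix)
  dimnames(sm) <- list(DNA_BASES, DNA_BASES)
  ErrorModel(errorScale = d$errorScale,
             typeFractions = unlist(d$typeFractions), subMatrix = sm,
             indelLengths = unlist(d$indelLengths),
             insBases = unlist(d$insBases))
}

fragmentModelToDoc <- function(m) {
  list(kind = m@kind, support = m@support, probs = m@probs,
       mean = m@mean, sd = m@sd)
}

docToFragmentModel <- function(d) {
  if (d$kind == "empirical")
    empiricalFragmentModel(unlist(d$support), unlist(d$probs))
  else gaussianFragmentModel(d$mean, d$sd)
}

gcBiasToDoc <- function(m) {
  if (is.null(m)) return(NULL)
  list(windowSize = m@windowSize, multipliers = m@multipliers,
       abundance = m@abundance)
}

docToGcBias <- function(d) {
  if (is.null(d)) return(NULL)
  methods::new("GcBiasModel", windowSize = as.integer(d$windowSize),
               multipliers = unlist(d$multipliers),
               abundance = unlist(d$abundance))
}

#' Write / read a sequencing model as JSON
#'
#' One versioned document holding the quality, error, GC-bias and
#' fragment sub-models; absent optional sub-models stay absent.
#'
#' @param model SequencingModel.
#' @param path output path.
#' @export
writeSequencingModel <- function(model, path) {
  doc <- list(format = "verisim-sequencing-model", version = 1L,
              qualityFwd = qualityModelToDoc(model@qualityFwd),
              qualityRev = qualityModelToDoc(model@qualityRev),
              error = errorModelToDoc(model@error),
              gcBias = gcBiasToDoc(model@gcBias),
              fragment = fragmentModelToDoc(model@fragment))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSequencingModel
#' @export
readSequencingModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "verisim-sequencing-model"))
    stop("not a sequencing model document: ", path)
  sequencingModel(qualityFwd = docToQualityModel(doc$qualityFwd),
                  qualityRev = docToQualityModel(doc$qualityRev),
                  error = docToErrorModel(doc$error),
                  gcBias = docToGcBias(doc$gcBias),
                  fragment = docToFragmentModel(doc$fragment))
}
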