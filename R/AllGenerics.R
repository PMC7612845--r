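## Accessor generics. Slots are never accessed with @ by user code.

#' @rdname BranchModel-class
#' @param object A `BranchModel`, `ExpansionResult` or other package object.
#' @export
setGeneric("branchName", function(object) standardGeneric("branchName"))

#' @rdname BranchModel-class
#' @export
setGeneric("branchStages", function(object) standardGeneric("branchStages"))

#' @rdname BranchModel-class
#' @export
setGeneric("branchData", function(object) standardGeneric("branchData"))

#' @rdname ExpansionResult-class
#' @param object An `ExpansionResult`.
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname ExpansionResult-class
#' @export
setGeneric("cumulativeOutput", function(object) standardGeneric("cumulativeOutput"))

#' @rdname ExpansionResult-class
#' @export
setGeneric("totalDivisions", function(object) standardGeneric("totalDivisions"))

#' @rdname IdentitySignature-class
#' @param object An `IdentitySignature`.
#' @export
setGeneric("medGenes", function(object) standardGeneric("medGenes"))

#' @rdname IdentitySignature-class
#' @export
setGeneric("extramedGenes", function(object) standardGeneric("extramedGenes"))

#' @rdname IdentityResult-class
#' @param object An `IdentityResult`.
#' @export
setGeneric("cellRatios", function(object) standardGeneric("cellRatios"))

#' @rdname IdentityResult-class
#' @export
setGeneric("sampleSummary", function(object) standardGeneric("sampleSummary"))

#' @rdname LdaResult-class
#' @param object An `LdaResult`.
#' @export
setGeneric("ldaEstimate", function(object) standardGeneric("ldaEstimate"))

#' @rdname LdaResult-class
#' @export
setGeneric("ldaConfint", function(object) standardGeneric("ldaConfint"))

#' @rdname LdaResult-class
#' @export
setGeneric("oneIn", function(object) standardGeneric("oneIn"))

#' @rdname LdaResult-class
#' @export
setGeneric("ldaFlags", function(object) standardGeneric("ldaFlags"))

#' @rdname BranchModel-class
#' @export
setMethod("branchName", "BranchModel", function(object) object@branchName)

#' @rdname ExpansionResult-class
#' @export
setMethod("branchName", "ExpansionResult", function(object) object@branchName)

#' @rdname BranchModel-class
#' @export
setMethod("branchStages", "BranchModel", function(object) object@stages)

#' @rdname ExpansionResult-class
#' @export
setMethod("branchStages", "ExpansionResult", function(object) object@stages)

#' @rdname BranchModel-class
#' @export
setMethod("branchData", "BranchModel", function(object) object@data)

#' @rdname ExpansionResult-class
#' @export
setMethod("transitions", "ExpansionResult", function(object) object@transitions)

#' @rdname ExpansionResult-class
#' @export
setMethod("cumulativeOutput", "ExpansionResult", function(object) object@output)

#' @rdname ExpansionResult-class
#' @export
setMethod("totalDivisions", "ExpansionResult", function(object) {
  setNames(object@totals$total_divisions,
           paste(object@totals$donor, object@totals$tissue, sep = "/"))
})

#' @rdname IdentitySignature-class
#' @export
setMethod("medGenes", "IdentitySignature", function(object) object@medGenes)

#' @rdname IdentitySignature-class
#' @export
setMethod("extramedGenes", "IdentitySignature", function(object) object@extramedGenes)

#' @rdname IdentityResult-class
#' @export
setMethod("cellRatios", "IdentityResult", function(object) object@cells)

#' @rdname IdentityResult-class
#' @export
setMethod("sampleSummary", "IdentityResult", function(object) object@samples)

#' @rdname LdaResult-class
#' @export
setMethod("ldaEstimate", "LdaResult", function(object) object@frequency)

#' @rdname LdaResult-class
#' @export
setMethod("ldaConfint", "LdaResult", function(object)
  c(lower = object@ciLow, upper = object@ciHigh))

#' @rdname LdaResult-class
#' @export
setMethod("oneIn", "LdaResult", function(object) {
  f <- object@frequency
  if (f <= 0) return(Inf)
  if (is.infinite(f)) return(1L)
  as.integer(ceiling(1 / f))
})

#' @rdname LdaResult-class
#' @export
setMethod("ldaFlags", "LdaResult", function(object) object@flags)
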