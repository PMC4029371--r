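#' @name accessors
#' @title Accessors for package classes
#' @param x an object of one of the package classes.
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
NULL

#' @rdname accessors
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))
#' @rdname accessors
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))
#' @rdname accessors
#' @export
setGeneric("atomLabels", function(x) standardGeneric("atomLabels"))
#' @rdname accessors
#' @export
setGeneric("ringInfo", function(x) standardGeneric("ringInfo"))
#' @rdname accessors
#' @export
setGeneric("substructures", function(x) standardGeneric("substructures"))
#' @rdname accessors
#' @export
setGeneric("descriptorCounts", function(x) standardGeneric("descriptorCounts"))
#' @rdname accessors
#' @export
setGeneric("descriptorLevel", function(x) standardGeneric("descriptorLevel"))
#' @rdname accessors
#' @export
setGeneric("spaceKeys", function(x) standardGeneric("spaceKeys"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

setMethod("molId", "MolGraph", function(x) x@id)
setMethod("molId", "KcfCompound", function(x) x@graph@id)
setMethod("atomTable", "MolGraph", function(x) x@atoms)
setMethod("atomTable", "KcfCompound", function(x) x@graph@atoms)
setMethod("bondTable", "MolGraph", function(x) x@bonds)
setMethod("bondTable", "KcfCompound", function(x) x@graph@bonds)
setMethod("atomCount", "MolGraph", function(x) nrow(x@atoms))
setMethod("atomCount", "KcfCompound", function(x) nrow(x@graph@atoms))
setMethod("bondCount", "MolGraph", function(x) nrow(x@bonds))
setMethod("bondCount", "KcfCompound", function(x) nrow(x@graph@bonds))
setMethod("atomLabels", "KcfCompound", function(x) x@labels)
setMethod("ringInfo", "KcfCompound", function(x) x@rings)

#' @describeIn accessors substructure instances as a data.frame with columns
#'   \code{attribute}, \code{canonical} and list-column \code{atoms}.
setMethod("substructures", "KcfCompound", function(x) {
  ins <- x@substructures
  data.frame(
    attribute = vapply(ins, `[[`, character(1), "attribute"),
    canonical = vapply(ins, `[[`, character(1), "canonical"),
    atoms = I(lapply(ins, `[[`, "atoms")),
    stringsAsFactors = FALSE)
})

setMethod("descriptorCounts", "KcfsDescriptor", function(x) x@counts)
setMethod("descriptorLevel", "KcfsDescriptor", function(x) x@level)
setMethod("spaceKeys", "FeatureSpace", function(x) x@keys)
setMethod("modelWeights", "SvmModel", function(x) x@w)
setMethod("modelBias", "SvmModel", function(x) x@bias)

#' Number of keys in a feature space
#' @param x a \code{FeatureSpace}.
#' @export
setMethod("length", "FeatureSpace", function(x) length(x@keys))
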