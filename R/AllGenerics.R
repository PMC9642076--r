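#' Accessors for solshift data classes
#'
#' Slot accessors for the S4 containers. Use these rather than `@` access.
#'
#' @param object a solshift data object.
#' @return The slot contents: a data.frame for the record accessors,
#'   character vectors for labels and identifier lists, a logical for
#'   `isBaitNormalized`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("quantRecords", function(object) standardGeneric("quantRecords"))
#' @rdname accessors
#' @export
setMethod("quantRecords", "QuantTable", function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("baitId", function(object) standardGeneric("baitId"))
#' @rdname accessors
#' @export
setMethod("baitId", "QuantTable", function(object) object@baitId)

#' @rdname accessors
#' @export
setGeneric("conditionLabels",
           function(object) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setMethod("conditionLabels", "QuantTable",
          function(object) object@conditionLabels)

#' @rdname accessors
#' @export
setGeneric("fractionMode", function(object) standardGeneric("fractionMode"))
#' @rdname accessors
#' @export
setMethod("fractionMode", "QuantTable", function(object) object@fractionMode)

#' @rdname accessors
#' @export
setGeneric("isBaitNormalized",
           function(object) standardGeneric("isBaitNormalized"))
#' @rdname accessors
#' @export
setMethod("isBaitNormalized", "QuantTable",
          function(object) object@baitNormalized)

#' @rdname accessors
#' @export
setGeneric("deData", function(object) standardGeneric("deData"))
#' @rdname accessors
#' @export
setMethod("deData", "DETable", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("datasetLabel", function(object) standardGeneric("datasetLabel"))
#' @rdname accessors
#' @export
setMethod("datasetLabel", "DETable", function(object) object@datasetLabel)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(object) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "GeneSetCollection",
          function(object) object@universe)

#' @rdname accessors
#' @export
setGeneric("flowEvents", function(object) standardGeneric("flowEvents"))
#' @rdname accessors
#' @export
setMethod("flowEvents", "EventTable", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "EventTable", function(object) object@groupLabel)

#' @rdname accessors
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setMethod("cellData", "CellTable", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("ctData", function(object) standardGeneric("ctData"))
#' @rdname accessors
#' @export
setMethod("ctData", "CtTable", function(object) object@ct)

#' @rdname accessors
#' @export
setGeneric("housekeepingIds",
           function(object) standardGeneric("housekeepingIds"))
#' @rdname accessors
#' @export
setMethod("housekeepingIds", "CtTable",
          function(object) object@housekeepingIds)
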