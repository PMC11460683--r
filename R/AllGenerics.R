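#' @import methods
NULL

#' @rdname MetabolicNetwork-class
#' @param object a \code{MetabolicNetwork}
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reversible", function(object) standardGeneric("reversible"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("boundaryReactions", function(object) standardGeneric("boundaryReactions"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("biomassId", function(object) standardGeneric("biomassId"))

#' @rdname StandardizedNetwork-class
#' @param object a \code{StandardizedNetwork}
#' @export
setGeneric("subnetworkItems", function(object) standardGeneric("subnetworkItems"))

#' @rdname PatternCollection-class
#' @param object a \code{PatternCollection}
#' @export
setGeneric("patternDefinition", function(object) standardGeneric("patternDefinition"))

#' @rdname PatternCollection-class
#' @export
setGeneric("patternCount", function(object) standardGeneric("patternCount"))

#' @rdname PatternCollection-class
#' @export
setGeneric("patternKeys", function(object) standardGeneric("patternKeys"))

#' @rdname RaySet-class
#' @param object a \code{RaySet}
#' @export
setGeneric("rayCount", function(object) standardGeneric("rayCount"))

#' @rdname RaySet-class
#' @export
setGeneric("rays", function(object) standardGeneric("rays"))
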