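#' @rdname MetabolicNetwork-class
#' @param x,object a `MetabolicNetwork`
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("objectiveId", function(x) standardGeneric("objectiveId"))

#' @rdname MetabolicNetwork-class
#' @param value replacement value
#' @export
setGeneric("objectiveId<-", function(x, value) standardGeneric("objectiveId<-"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname stoichiometricMatrix
#' @export
setGeneric("stoichiometricMatrix",
           function(x) standardGeneric("stoichiometricMatrix"))

#' @rdname FluxSolution-class
#' @param x a `FluxSolution`
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname FluxSolution-class
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))
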