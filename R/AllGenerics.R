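#' @include AllGenerics.R
NULL

#' Reduce a molecular graph to its degree-pair edge partition
#'
#' @param x a \linkS4class{MolecularGraph}
#' @return an \linkS4class{EdgePartition}
#' @export
setGeneric("edgePartition", function(x) standardGeneric("edgePartition"))

#' Evaluate a single degree-based topological index
#'
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{EdgePartition}
#' @param name index name, one of \code{indexNames()}
#' @return a single numeric value
#' @export
setGeneric("computeIndex", function(x, name) standardGeneric("computeIndex"))

#' Evaluate all nine degree-based topological indices
#'
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{EdgePartition}
#' @return named numeric vector with one entry per index in
#'   \code{indexNames()} order
#' @export
setGeneric("computeAllIndices", function(x) standardGeneric("computeAllIndices"))

#' @rdname idealPoints
#' @export
setGeneric("idealPoints", function(x, criteria, ...) standardGeneric("idealPoints"))

#' @rdname vikor
#' @export
setGeneric("vikor", function(x, criteria, ...) standardGeneric("vikor"))

#' @rdname saw
#' @export
setGeneric("saw", function(x, criteria, ...) standardGeneric("saw"))

#' Number of edges
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{EdgePartition}
#' @return integer edge count
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Vertex degrees
#' @param x a \linkS4class{MolecularGraph}
#' @return named integer vector of heavy-atom degrees
#' @export
setGeneric("graphDegrees", function(x) standardGeneric("graphDegrees"))

#' Alternatives (row labels) of a decision object
#' @param x a \linkS4class{DecisionMatrix}, \linkS4class{VikorResult} or
#'   \linkS4class{SawResult}
#' @return character vector
#' @export
setGeneric("alternatives", function(x) standardGeneric("alternatives"))

#' Criteria (column labels) of a decision object
#' @param x a \linkS4class{DecisionMatrix} or \linkS4class{CriterionSet}
#' @return character vector
#' @export
setGeneric("criteria", function(x) standardGeneric("criteria"))

#' Criterion weights
#' @param x a \linkS4class{CriterionSet}
#' @return named numeric vector summing to 1
#' @export
setGeneric("criterionWeights", function(x) standardGeneric("criterionWeights"))

#' Criterion orientations
#' @param x a \linkS4class{CriterionSet}
#' @return named character vector, \code{"beneficial"} or
#'   \code{"non_beneficial"} per criterion
#' @export
setGeneric("criterionOrientations", function(x) standardGeneric("criterionOrientations"))

#' Per-alternative scores of a ranking result
#'
#' For VIKOR: columns \code{S}, \code{R}, \code{Q} and the three rank
#' columns. For SAW: the total score and rank.
#'
#' @param x a \linkS4class{VikorResult} or \linkS4class{SawResult}
#' @return data.frame with one row per alternative
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
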