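#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- MolecularGraph

#' Hydrogen-suppressed molecular graph
#'
#' A simple connected graph whose vertices are heavy (non-hydrogen) atoms
#' and whose edges are covalent bonds, each bond counted once regardless of
#' bond order. Vertex identifiers are opaque labels; no atom typing or
#' geometry is stored — the class exists to supply vertex degrees, which are
#' the only structural input the topological indices need.
#'
#' @slot edges character matrix with two columns; one row per bond, vertex
#'   labels as entries. Rows are stored with the two endpoints in
#'   lexicographic order so that duplicate detection is canonical.
#'
#' @seealso [buildGraph()], [parseSmiles()], [edgePartition()]
#' @export
setClass("MolecularGraph", slots = c(edges = "matrix"))

setValidity("MolecularGraph", function(object) {
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a character matrix with two columns")
  if (nrow(e) < 1L)
    return("a molecular graph needs at least one bond")
  if (any(e[, 1L] == e[, 2L]))
    return("self-loops are not allowed")
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "\r")
  if (anyDuplicated(key))
    return("parallel (duplicate) edges are not allowed")
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (!igraph::is_connected(g))
    return("graph is disconnected; a molecular graph must be a single molecule")
  TRUE
})

# ---------------------------------------------------------------- EdgePartition

#' Degree-pair edge partition
#'
#' The multiset of unordered endpoint-degree pairs of a molecular graph:
#' for each canonical pair (a, b) with a <= b, the number of edges whose two
#' endpoints have degrees a and b. This is a sufficient statistic for every
#' degree-based topological index, and is the form in which worked
#' calculations are usually published.
#'
#' @slot pairs integer matrix with columns \code{a} and \code{b},
#'   \code{a <= b}, one row per distinct degree pair
#' @slot counts positive integer vector, one count per row of \code{pairs};
#'   counts sum to the number of edges of the source graph
#'
#' @seealso [edgePartition()], [makePartition()], [computeAllIndices()]
#' @export
setClass("EdgePartition", slots = c(pairs = "matrix", counts = "integer"))

setValidity("EdgePartition", function(object) {
  p <- object@pairs
  k <- object@counts
  if (!is.numeric(p) || ncol(p) != 2L)
    return("pairs must be a numeric matrix with two columns")
  if (nrow(p) != length(k))
    return("one count is required per degree pair")
  if (nrow(p) > 0L) {
    if (any(p < 1L) || any(p != round(p)))
      return("degrees must be positive integers")
    if (any(p[, 1L] > p[, 2L]))
      return("pairs must be canonical: a <= b")
    key <- paste(p[, 1L], p[, 2L])
    if (anyDuplicated(key))
      return("degree pairs must be distinct")
    if (any(k < 1L))
      return("counts must be positive")
  }
  TRUE
})

# ---------------------------------------------------------------- DecisionMatrix

#' Alternatives-by-criteria decision matrix
#'
#' Real-valued performance matrix for multi-criteria decision making: rows
#' are alternatives (here, drugs), columns are criteria (here, topological
#' indices). No missing cells are allowed.
#'
#' @slot values numeric matrix with complete dimnames
#' @seealso [decisionMatrix()], [vikor()], [saw()]
#' @export
setClass("DecisionMatrix", slots = c(values = "matrix"))

setValidity("DecisionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v))
    return("values must be numeric")
  if (nrow(v) < 2L)
    return("at least two alternatives are required")
  if (ncol(v) < 1L)
    return("at least one criterion is required")
  if (anyNA(v))
    return("missing cells are not allowed")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("alternative and criterion labels are required")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("alternative and criterion labels must be unique")
  TRUE
})

# ---------------------------------------------------------------- CriterionSet

#' Weights and orientations for a set of criteria
#'
#' Per-criterion weight (summing to 1) and orientation: a beneficial
#' criterion is one to maximize (its ideal is the column maximum), a
#' non-beneficial one is to minimize.
#'
#' @slot weights named numeric vector in (0, 1), summing to 1
#' @slot orientations named character vector over the same names; each entry
#'   \code{"beneficial"} or \code{"non_beneficial"}
#' @seealso [criterionSet()], [ratioWeights()], [classifyCriteria()]
#' @export
setClass("CriterionSet", slots = c(weights = "numeric", orientations = "character"))

setValidity("CriterionSet", function(object) {
  w <- object@weights
  o <- object@orientations
  if (is.null(names(w)) || anyDuplicated(names(w)))
    return("weights must carry unique criterion names")
  if (!identical(names(w), names(o)))
    return("weights and orientations must cover the same criteria, in order")
  if (any(w <= 0) || any(w > 1))
    return("weights must lie within (0, 1]")
  if (abs(sum(w) - 1) > 1e-8)
    return("weights must sum to 1")
  if (!all(o %in% c("beneficial", "non_beneficial")))
    return("orientations must be 'beneficial' or 'non_beneficial'")
  TRUE
})

# ---------------------------------------------------------------- VikorResult

#' VIKOR compromise-ranking result
#'
#' Per alternative: the group utility S (weighted normalized Manhattan
#' distance to the ideal point), the individual regret R (weighted
#' normalized Chebyshev distance) and the compromise index Q blending the
#' two with the weight v. Smaller is better for all three. Ranks are
#' competition ranks (ties share the smaller rank), ascending.
#'
#' @slot S,R,Q named numeric vectors, one entry per alternative
#' @slot ranks data.frame with integer columns \code{byS}, \code{byR},
#'   \code{byQ}
#' @slot v numeric in [0, 1]: weight of S in Q
#' @slot ideal data.frame with per-criterion columns \code{best} and
#'   \code{worst}
#' @slot criteria the \linkS4class{CriterionSet} used (after dropping any
#'   constant criteria)
#' @slot conditions logical vector reporting the classical compromise-set
#'   checks: acceptable advantage and acceptable stability of the Q-best
#'   alternative (informational; ranks are by Q alone)
#' @seealso [vikor()]
#' @export
setClass("VikorResult",
  slots = c(S = "numeric", R = "numeric", Q = "numeric",
            ranks = "data.frame", v = "numeric", ideal = "data.frame",
            criteria = "CriterionSet", conditions = "logical"))

# ---------------------------------------------------------------- SawResult

#' Simple-additive-weighting result
#'
#' @slot normalized numeric matrix of orientation-adjusted normalized
#'   performance values in [0, 1]
#' @slot weighted numeric matrix of weighted scores (normalized x weight)
#' @slot totals named numeric vector of per-alternative total scores
#' @slot rank named integer vector (competition ranks)
#' @slot normalization the normalization method used
#' @slot direction rank direction: \code{"desc"} ranks the largest total 1
#' @seealso [saw()]
#' @export
setClass("SawResult",
  slots = c(normalized = "matrix", weighted = "matrix", totals = "numeric",
            rank = "integer", normalization = "character",
            direction = "character"))

# ---------------------------------------------------------------- accessors

#' @describeIn MolecularGraph number of bonds
#' @export
setMethod("numEdges", "MolecularGraph", function(x) nrow(x@edges))

#' @describeIn EdgePartition total number of edges (sum of counts)
#' @export
setMethod("numEdges", "EdgePartition", function(x) sum(x@counts))

#' @describeIn MolecularGraph named vector of vertex degrees
#' @export
setMethod("graphDegrees", "MolecularGraph", function(x) {
  d <- table(c(x@edges[, 1L], x@edges[, 2L]))
  ret <- as.integer(d)
  names(ret) <- names(d)
  ret
})

#' Edge list of a molecular graph
#' @param x a \linkS4class{MolecularGraph}
#' @return two-column character matrix, one row per bond
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "MolecularGraph"))
  x@edges
}

#' Degree pairs and counts of an edge partition
#'
#' @param x an \linkS4class{EdgePartition}
#' @return `partitionPairs`: integer matrix with columns `a`, `b`;
#'   `partitionCounts`: integer vector of per-pair edge counts.
#' @export
partitionPairs <- function(x) {
  stopifnot(is(x, "EdgePartition"))
  x@pairs
}

#' @rdname partitionPairs
#' @export
partitionCounts <- function(x) {
  stopifnot(is(x, "EdgePartition"))
  x@counts
}

#' @describeIn DecisionMatrix row labels
#' @export
setMethod("alternatives", "DecisionMatrix", function(x) rownames(x@values))

#' @describeIn DecisionMatrix column labels
#' @export
setMethod("criteria", "DecisionMatrix", function(x) colnames(x@values))

#' @describeIn CriterionSet criterion names
#' @export
setMethod("criteria", "CriterionSet", function(x) names(x@weights))

#' @describeIn CriterionSet weights
#' @export
setMethod("criterionWeights", "CriterionSet", function(x) x@weights)

#' @describeIn CriterionSet orientations
#' @export
setMethod("criterionOrientations", "CriterionSet", function(x) x@orientations)

#' Underlying matrix of a DecisionMatrix
#' @param x a \linkS4class{DecisionMatrix}
#' @return numeric matrix with dimnames
#' @export
decisionValues <- function(x) {
  stopifnot(is(x, "DecisionMatrix"))
  x@values
}

#' @describeIn VikorResult alternative labels
#' @export
setMethod("alternatives", "VikorResult", function(x) names(x@S))

#' @describeIn VikorResult S, R, Q and ranks as a data.frame
#' @export
setMethod("scores", "VikorResult", function(x) {
  data.frame(S = x@S, R = x@R, Q = x@Q,
             rankS = x@ranks$byS, rankR = x@ranks$byR, rank = x@ranks$byQ,
             row.names = names(x@S))
})

#' @describeIn SawResult alternative labels
#' @export
setMethod("alternatives", "SawResult", function(x) names(x@totals))

#' @describeIn SawResult totals and ranks as a data.frame
#' @export
setMethod("scores", "SawResult", function(x) {
  data.frame(total = x@totals, rank = x@rank, row.names = names(x@totals))
})

# ---------------------------------------------------------------- show

setMethod("show", "MolecularGraph", function(object) {
  d <- graphDegrees(object)
  cat("MolecularGraph:", length(d), "heavy atoms,", numEdges(object),
      "bonds; degree range", min(d), "-", max(d), "\n")
})

setMethod("show", "EdgePartition", function(object) {
  cat("EdgePartition over", numEdges(object), "edges\n")
  p <- object@pairs
  lab <- sprintf("|E(%d,%d)| = %d", p[, 1L], p[, 2L], object@counts)
  cat(" ", paste(lab, collapse = ", "), "\n")
})

setMethod("show", "DecisionMatrix", function(object) {
  v <- object@values
  cat("DecisionMatrix:", nrow(v), "alternatives x", ncol(v), "criteria\n")
  cat("  criteria:", paste(colnames(v), collapse = ", "), "\n")
  print(utils::head(v, 4L))
  if (nrow(v) > 4L) cat("  ...", nrow(v) - 4L, "more alternatives\n")
})

setMethod("show", "CriterionSet", function(object) {
  cat("CriterionSet over", length(object@weights), "criteria\n")
  df <- data.frame(weight = round(object@weights, 6),
                   orientation = object@orientations)
  print(df)
})

setMethod("show", "VikorResult", function(object) {
  cat("VikorResult (v =", object@v, ")\n")
  df <- scores(object)
  print(df[order(df$rank), ])
  cat("compromise checks on the Q-best alternative:",
      "acceptable advantage =", object@conditions[["advantage"]],
      "; acceptable stability =", object@conditions[["stability"]], "\n")
})

setMethod("show", "SawResult", function(object) {
  cat("SawResult (", object@normalization, "normalization, rank",
      object@direction, ")\n")
  df <- scores(object)
  print(df[order(df$rank), ])
})
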