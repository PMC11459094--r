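#' @include molgraph.R
NULL

.INDEX_NAMES <- c("RA", "ABC", "M1", "M2", "SCI", "F", "GA", "H", "HM")

#' Names of the supported degree-based topological indices
#'
#' @return character vector: Randic (RA), atom-bond connectivity (ABC),
#'   first Zagreb (M1), second Zagreb (M2), sum-connectivity (SCI),
#'   forgotten (F), geometric-arithmetic (GA), harmonic (H) and
#'   hyper-Zagreb (HM)
#' @export
indexNames <- function() .INDEX_NAMES

#' Per-edge contribution of a degree-based index
#'
#' Every supported index is a sum over edges of a symmetric function of the
#' endpoint degrees (a, b):
#' \deqn{RA: 1/\sqrt{ab};\ ABC: \sqrt{(a+b-2)/(ab)};\ M_1: a+b;\ M_2: ab;}
#' \deqn{SCI: 1/\sqrt{a+b};\ F: a^2+b^2;\ GA: 2\sqrt{ab}/(a+b);\ H: 2/(a+b);\ HM: (a+b)^2.}
#' The ABC contribution of a (1,1) edge is 0 (the radicand vanishes); this
#' is a defined value, not an error.
#'
#' @param name one of [indexNames()]
#' @param a,b endpoint degrees, positive integers (vectorized)
#' @return numeric vector of per-edge terms
#' @examples
#' indexContribution("M1", 2, 3)   # 5
#' indexContribution("GA", 1, 1)   # 1: regular pairs contribute exactly 1
#' @export
indexContribution <- function(name, a, b) {
  name <- match.arg(name, .INDEX_NAMES)
  if (any(a < 1) || any(b < 1) || any(a != round(a)) || any(b != round(b)))
    stop("degrees must be positive integers")
  switch(name,
    RA  = 1 / sqrt(a * b),
    ABC = sqrt((a + b - 2) / (a * b)),
    M1  = a + b,
    M2  = a * b,
    SCI = 1 / sqrt(a + b),
    F   = a^2 + b^2,
    GA  = 2 * sqrt(a * b) / (a + b),
    H   = 2 / (a + b),
    HM  = (a + b)^2)
}

.index_from_partition <- function(partition, name) {
  p <- partition@pairs
  if (nrow(p) == 0L) return(0)
  as.numeric(sum(partition@counts *
                   indexContribution(name, p[, 1L], p[, 2L])))
}

#' @describeIn computeIndex count-weighted sum of per-edge contributions
#'   over the partition
#' @examples
#' ep <- makePartition(rbind(c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)),
#'                     c(1, 3, 2, 5, 2))
#' computeIndex(ep, "M1")  # 60
#' computeIndex(ep, "M2")  # 67
#' @export
setMethod("computeIndex", "EdgePartition", function(x, name)
  .index_from_partition(x, name))

#' @describeIn computeIndex computed via the graph's edge partition
#' @export
setMethod("computeIndex", "MolecularGraph", function(x, name)
  .index_from_partition(edgePartition(x), name))

#' @describeIn computeAllIndices all nine indices from one partition pass
#' @export
setMethod("computeAllIndices", "EdgePartition", function(x) {
  vapply(.INDEX_NAMES, function(nm) .index_from_partition(x, nm),
         numeric(1L))
})

#' @describeIn computeAllIndices all nine indices of a graph
#' @export
setMethod("computeAllIndices", "MolecularGraph", function(x)
  computeAllIndices(edgePartition(x)))

#' Tabulate all indices for a collection of molecules
#'
#' @param graphs named list of \linkS4class{MolecularGraph} or
#'   \linkS4class{EdgePartition} objects
#' @return numeric matrix, one row per molecule, columns [indexNames()]
#' @export
indexTable <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  out <- t(vapply(graphs, computeAllIndices, numeric(length(.INDEX_NAMES))))
  if (!is.null(names(graphs))) rownames(out) <- names(graphs)
  out
}
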