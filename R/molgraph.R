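#' @include AllClasses.R
NULL

#' Build a molecular graph from an explicit edge list
#'
#' Validates and canonicalizes a bond list into a
#' \linkS4class{MolecularGraph}. Self-loops and duplicate bonds are
#' rejected. Disconnected input (a salt or mixture, or a typo) is an error
#' by default; with `largestComponent = TRUE` the largest connected
#' component is kept and a warning names how many vertices were dropped.
#'
#' @param edges a two-column matrix or data.frame of vertex labels, or a
#'   list of length-2 vectors; anything coercible to character
#' @param largestComponent keep the largest component of disconnected input
#'   instead of erroring
#' @return a \linkS4class{MolecularGraph}
#' @examples
#' g <- buildGraph(rbind(c("a", "b"), c("b", "c")))
#' graphDegrees(g)
#' @export
buildGraph <- function(edges, largestComponent = FALSE) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, as.character))
  edges <- as.matrix(edges)
  if (length(edges) == 0L || nrow(edges) == 0L)
    stop("empty edge list: a molecular graph needs at least one bond")
  if (ncol(edges) != 2L)
    stop("edges must have exactly two columns")
  mode(edges) <- "character"
  if (anyNA(edges) || any(!nzchar(edges)))
    stop("vertex labels must be non-missing, non-empty strings")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop detected: an atom cannot bond to itself")
  key <- paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge detected: each bond may be listed only once")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!igraph::is_connected(g)) {
    if (!largestComponent)
      stop("graph is disconnected; pass largestComponent = TRUE to keep ",
           "the largest component")
    comp <- igraph::components(g)
    keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    dropped <- sum(comp$csize) - max(comp$csize)
    warning("disconnected input: dropped ", dropped,
            " vertex(es) outside the largest component")
    sel <- edges[, 1L] %in% keep & edges[, 2L] %in% keep
    edges <- edges[sel, , drop = FALSE]
  }
  canon <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  dimnames(canon) <- NULL
  methods::new("MolecularGraph", edges = canon)
}

#' Construct an edge partition directly from degree-pair counts
#'
#' Convenience constructor for published partitions of the form
#' |E(a,b)| = count. Pairs are canonicalized to a <= b and repeated pairs
#' are summed.
#'
#' @param pairs two-column matrix (or data.frame) of degree pairs
#' @param counts positive integer vector, one per row of `pairs`
#' @return an \linkS4class{EdgePartition}
#' @examples
#' # a published partition: one (1,2) edge, three (1,3), two (2,2), ...
#' makePartition(rbind(c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)),
#'               c(1, 3, 2, 5, 2))
#' @export
makePartition <- function(pairs, counts) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("pairs must have two columns")
  if (nrow(pairs) != length(counts))
    stop("one count is required per degree pair")
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers")
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  key <- paste(a, b)
  agg <- rowsum(as.integer(counts), key)
  ord <- order(as.integer(sub(" .*", "", rownames(agg))),
               as.integer(sub(".* ", "", rownames(agg))))
  parts <- do.call(rbind, strsplit(rownames(agg)[ord], " ", fixed = TRUE))
  m <- matrix(as.integer(parts), ncol = 2L,
              dimnames = list(NULL, c("a", "b")))
  methods::new("EdgePartition", pairs = m, counts = as.integer(agg[ord]))
}

#' @describeIn edgePartition count, for every edge (u, v), the canonical
#'   degree pair (min(d_u, d_v), max(d_u, d_v))
#' @examples
#' edgePartition(buildGraph(rbind(c("a", "b"), c("a", "c"), c("a", "d"))))
#' @export
setMethod("edgePartition", "MolecularGraph", function(x) {
  d <- graphDegrees(x)
  du <- d[x@edges[, 1L]]
  dv <- d[x@edges[, 2L]]
  makePartition(cbind(pmin(du, dv), pmax(du, dv)),
                rep(1L, nrow(x@edges)))
})

#' Parse SMILES into hydrogen-suppressed molecular graphs
#'
#' Heavy atoms become vertices; every bond (single, double, triple or
#' aromatic) becomes one simple edge, so the resulting degree is the count
#' of heavy-atom neighbours. Parsing is delegated to
#' \pkg{ChemmineR}/\pkg{ChemmineOB}; stereochemistry, charges and isotopes
#' are ignored by construction.
#'
#' @param smiles a single SMILES string
#' @return a \linkS4class{MolecularGraph} whose vertex labels are
#'   element_position (e.g. \code{"C_1"})
#' @examples
#' \donttest{
#' edgePartition(parseSmiles("C1CCCCC1"))  # cyclohexane: six (2,2) edges
#' }
#' @export
parseSmiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("parseSmiles requires the ChemmineR package")
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("SMILES parse error: ", conditionMessage(e)))
  sdf1 <- sdf[[1L]]
  atoms <- rownames(ChemmineR::atomblock(sdf1))
  bonds <- ChemmineR::bondblock(sdf1)
  if (is.null(bonds) || nrow(bonds) == 0L)
    stop("SMILES parse error: molecule has no bonds between heavy atoms")
  heavy <- !grepl("^H_", atoms)
  idx <- bonds[, 1L]
  jdx <- bonds[, 2L]
  keep <- heavy[idx] & heavy[jdx]
  buildGraph(cbind(atoms[idx[keep]], atoms[jdx[keep]]))
}

#' Read an edge list file
#'
#' Accepts two-column CSV/TSV (header optional: a header row is assumed when
#' neither field of the first line appears again as a vertex of the second)
#' or a JSON array of two-element arrays.
#'
#' @param path file path; format chosen by extension (.json vs delimited)
#' @param largestComponent passed to [buildGraph()]
#' @return a \linkS4class{MolecularGraph}
#' @export
readEdgeList <- function(path, largestComponent = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON edge lists requires the jsonlite package")
    e <- jsonlite::fromJSON(path)
    return(buildGraph(as.matrix(e), largestComponent = largestComponent))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) != 2L)
    stop("edge list files must have exactly two columns")
  # drop a header row when its fields never recur as vertex labels
  if (nrow(raw) > 1L &&
      !any(unlist(raw[1L, ]) %in% unlist(raw[-1L, ]))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  buildGraph(as.matrix(raw), largestComponent = largestComponent)
}
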