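#' @include saw.R
NULL

#' Random chemical-like molecular graph
#'
#' Generates a connected simple graph with bounded degrees, emulating a
#' hydrogen-suppressed organic skeleton: a random tree grown by attaching
#' each new vertex to a uniformly chosen non-saturated existing vertex,
#' plus a number of extra degree-respecting edges (rings). The default
#' degree cap of 4 is the usual heavy-atom valence heuristic; the default
#' ring count of about 15% of the atom count is in the range of small
#' drug-like molecules.
#'
#' @param nAtoms number of vertices, >= 2
#' @param maxDegree degree cap, >= 1
#' @param nExtraEdges number of additional (cycle-forming) edges to attempt
#'   beyond the spanning tree; defaults to \code{round(0.15 * nAtoms)}.
#'   Fewer are added when the degree cap leaves no room.
#' @param seed optional integer; when given, results are reproducible and
#'   the caller's RNG state is untouched
#' @return a \linkS4class{MolecularGraph} with vertex labels
#'   \code{"v1"}, \code{"v2"}, ...
#' @examples
#' g <- randomMolecularGraph(20, seed = 7)
#' max(graphDegrees(g)) <= 4
#' @export
randomMolecularGraph <- function(nAtoms, maxDegree = 4L,
                                 nExtraEdges = NULL, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed,
      randomMolecularGraph(nAtoms, maxDegree, nExtraEdges, seed = NULL)))
  nAtoms <- as.integer(nAtoms)
  maxDegree <- as.integer(maxDegree)
  if (nAtoms < 2L)
    stop("infeasible configuration: at least 2 atoms are required")
  if (maxDegree < 1L || (nAtoms > 2L && maxDegree < 2L))
    stop("infeasible configuration: the degree cap leaves no room ",
         "for a connected graph on ", nAtoms, " atoms")
  if (is.null(nExtraEdges)) nExtraEdges <- round(0.15 * nAtoms)
  deg <- integer(nAtoms)
  edges <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nAtoms)[-1L]) {
    open <- which(deg[seq_len(k - 1L)] < maxDegree)
    if (length(open) == 0L)
      stop("infeasible configuration: all placed atoms are saturated")
    parent <- open[sample.int(length(open), 1L)]
    edges <- rbind(edges, c(parent, k))
    deg[parent] <- deg[parent] + 1L
    deg[k] <- deg[k] + 1L
  }
  adj <- matrix(FALSE, nAtoms, nAtoms)
  adj[edges] <- TRUE
  adj[edges[, c(2L, 1L)]] <- TRUE
  added <- 0L
  while (added < nExtraEdges) {
    open <- which(deg < maxDegree)
    if (length(open) < 2L) break
    cand <- which(!adj[open, open, drop = FALSE] &
                    upper.tri(matrix(TRUE, length(open), length(open))),
                  arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    pick <- cand[sample.int(nrow(cand), 1L), ]
    u <- open[pick[1L]]
    w <- open[pick[2L]]
    edges <- rbind(edges, c(u, w))
    adj[u, w] <- adj[w, u] <- TRUE
    deg[u] <- deg[u] + 1L
    deg[w] <- deg[w] + 1L
    added <- added + 1L
  }
  buildGraph(cbind(paste0("v", edges[, 1L]), paste0("v", edges[, 2L])))
}

#' A set of random molecular graphs
#'
#' @param nMolecules number of graphs
#' @param nAtoms integer vector (recycled) of atom counts
#' @param maxDegree degree cap shared by all graphs
#' @param seed optional integer master seed; per-molecule seeds are derived
#'   from it so each graph is individually reproducible
#' @return named list of \linkS4class{MolecularGraph} objects
#' @export
randomMoleculeSet <- function(nMolecules, nAtoms = 20L, maxDegree = 4L,
                              seed = NULL) {
  stopifnot(nMolecules >= 1L)
  nAtoms <- rep_len(as.integer(nAtoms), nMolecules)
  seeds <- if (is.null(seed)) rep(list(NULL), nMolecules)
           else as.list(seed + seq_len(nMolecules))
  out <- lapply(seq_len(nMolecules), function(i)
    randomMolecularGraph(nAtoms[i], maxDegree, seed = seeds[[i]]))
  names(out) <- paste0("mol", seq_len(nMolecules))
  out
}

#' Property vector with an exact target correlation
#'
#' Constructs y with sample Pearson correlation against x equal to
#' `targetR` exactly (to numerical precision): random noise is projected
#' orthogonal to the centered x, both parts are standardized, and combined
#' as \eqn{\rho z_x + \sqrt{1-\rho^2} z_e}. The construction makes
#' correlation round-trips deterministic, which is what the package's own
#' tests rely on; set \code{exact = FALSE} for a conventional noisy draw
#' \eqn{y = x + \sigma e} whose sample correlation only approaches the
#' implied value at large n.
#'
#' @param x non-constant numeric vector, length >= 3
#' @param targetR target sample correlation, |targetR| < 1 (exact mode)
#' @param seed optional integer for reproducibility
#' @param exact build the exact-correlation construction (default)
#' @param noiseSd noise standard deviation for \code{exact = FALSE}
#' @return numeric vector the same length as `x`
#' @examples
#' x <- rnorm(25)
#' cor(x, correlatedProperty(x, 0.7, seed = 1))  # 0.7 to ~1e-15
#' @export
correlatedProperty <- function(x, targetR, seed = NULL, exact = TRUE,
                               noiseSd = 1) {
  if (!is.null(seed))
    return(withr::with_seed(seed,
      correlatedProperty(x, targetR, seed = NULL, exact = exact,
                         noiseSd = noiseSd)))
  if (length(x) < 3L)
    stop("at least 3 observations are required")
  if (stats::sd(x) == 0)
    stop("constant vector: cannot target a correlation against it")
  if (!exact)
    return(x + stats::rnorm(length(x), sd = noiseSd))
  if (abs(targetR) >= 1)
    stop("|targetR| must be < 1 for the exact construction")
  zx <- as.numeric(scale(x))
  repeat {
    e <- stats::rnorm(length(x))
    e <- e - mean(e)
    e <- e - zx * sum(e * zx) / sum(zx * zx)
    if (stats::sd(e) > 0) break
  }
  ze <- e / stats::sd(e)
  targetR * zx + sqrt(1 - targetR^2) * ze
}
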