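#' @include qspr.R
NULL

#' Construct a decision matrix
#'
#' @param values numeric matrix or data.frame, alternatives in rows,
#'   criteria in columns, complete dimnames (a data.frame's first character
#'   column is promoted to row names when row names are absent)
#' @return a \linkS4class{DecisionMatrix}
#' @export
decisionMatrix <- function(values) {
  if (is.data.frame(values)) {
    if (is.character(values[[1L]]) &&
        identical(rownames(values), as.character(seq_len(nrow(values))))) {
      rn <- values[[1L]]
      values <- values[, -1L, drop = FALSE]
      rownames(values) <- rn
    }
    values <- as.matrix(values)
  }
  methods::new("DecisionMatrix", values = values)
}

#' Read a decision matrix from CSV
#'
#' First column = alternative labels, header row = criterion names.
#'
#' @param path CSV file path
#' @return a \linkS4class{DecisionMatrix}
#' @export
readDecisionMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  decisionMatrix(df)
}

# Align a CriterionSet to a matrix's columns; drop constant criteria.
.align_criteria <- function(vals, criteria, onConstant = c("drop", "error")) {
  onConstant <- match.arg(onConstant)
  cn <- colnames(vals)
  if (!all(cn %in% criteria(criteria)))
    stop("criteria must cover every column of the decision matrix")
  w <- criterionWeights(criteria)[cn]
  o <- criterionOrientations(criteria)[cn]
  spread <- apply(vals, 2L, function(col) diff(range(col)))
  if (any(spread == 0)) {
    bad <- cn[spread == 0]
    if (onConstant == "error")
      stop("constant criterion (ideal best equals ideal worst): ",
           paste(bad, collapse = ", "))
    warning("dropping constant criterion: ", paste(bad, collapse = ", "))
    keep <- spread > 0
    vals <- vals[, keep, drop = FALSE]
    w <- w[keep] / sum(w[keep])  # renormalize over the retained criteria
    o <- o[keep]
  }
  if (ncol(vals) == 0L)
    stop("no non-constant criteria remain")
  list(vals = vals, weights = w, orientations = o)
}

#' Ideal best and worst points of a decision matrix
#'
#' For a beneficial criterion the ideal best is the column maximum and the
#' ideal worst the minimum; for a non-beneficial criterion the roles swap.
#'
#' @param x a \linkS4class{DecisionMatrix}
#' @param criteria a \linkS4class{CriterionSet} covering every column
#' @param onConstant what to do with a criterion whose best equals its
#'   worst: \code{"drop"} (with a warning) or \code{"error"}
#' @param ... unused
#' @return data.frame with columns \code{orientation}, \code{best},
#'   \code{worst}, one row per retained criterion
#' @export
setMethod("idealPoints", "DecisionMatrix",
  function(x, criteria, onConstant = c("drop", "error"), ...) {
    al <- .align_criteria(x@values, criteria, onConstant)
    ben <- al$orientations == "beneficial"
    best <- ifelse(ben, apply(al$vals, 2L, max), apply(al$vals, 2L, min))
    worst <- ifelse(ben, apply(al$vals, 2L, min), apply(al$vals, 2L, max))
    data.frame(orientation = al$orientations, best = best, worst = worst,
               row.names = colnames(al$vals))
  })

#' Competition ranks of a score vector
#'
#' Rank 1 is the best score under the stated direction; ties share the
#' smaller rank and the following rank is skipped ("1224" style).
#'
#' @param x numeric scores
#' @param direction \code{"asc"}: smaller is better (rank 1 = minimum);
#'   \code{"desc"}: larger is better
#' @return integer ranks, same length and names as `x`
#' @examples
#' rankScores(c(0.3, 0.1, 0.2))          # 3 1 2
#' rankScores(c(5, 5, 1))                # 2 2 1
#' @export
rankScores <- function(x, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  stopifnot(length(x) >= 1L, !anyNA(x))
  s <- if (direction == "asc") x else -x
  as.integer(rank(s, ties.method = "min"))
}

#' VIKOR compromise ranking
#'
#' For each alternative j, with weights w_i and ideal best/worst f_i^+ and
#' f_i^- per criterion i:
#' \deqn{S_j = \sum_i w_i (f_i^+ - f_{ij})/(f_i^+ - f_i^-)}
#' (group utility: the weighted normalized Manhattan distance to the ideal),
#' \deqn{R_j = \max_i w_i (f_i^+ - f_{ij})/(f_i^+ - f_i^-)}
#' (individual regret: the weighted normalized Chebyshev distance), and
#' \deqn{Q_j = v (S_j - S^+)/(S^- - S^+) + (1 - v)(R_j - R^+)/(R^- - R^+)}
#' with S^+ = min S, S^- = max S, R^+ = min R, R^- = max R. Alternatives
#' are ranked ascending by each of S, R and Q; the Q ranking is the
#' headline ordering. The classical compromise-set conditions (acceptable
#' advantage Q(2nd) - Q(1st) >= 1/(m - 1), and acceptable stability: the
#' Q-best alternative is also best by S or by R) are reported but not used
#' to modify ranks.
#'
#' @param x a \linkS4class{DecisionMatrix}
#' @param criteria a \linkS4class{CriterionSet} covering every column
#' @param v weight of group utility S in Q, in [0, 1]; 0.5 balances group
#'   utility and individual regret
#' @param onConstant see [idealPoints()]
#' @param ... unused
#' @return a \linkS4class{VikorResult}
#' @export
setMethod("vikor", "DecisionMatrix",
  function(x, criteria, v = 0.5, onConstant = c("drop", "error"), ...) {
    stopifnot(length(v) == 1L, v >= 0, v <= 1)
    al <- .align_criteria(x@values, criteria, onConstant)
    vals <- al$vals
    ben <- al$orientations == "beneficial"
    best <- ifelse(ben, apply(vals, 2L, max), apply(vals, 2L, min))
    worst <- ifelse(ben, apply(vals, 2L, min), apply(vals, 2L, max))
    # weighted normalized deviation from the ideal, per cell
    dev <- sweep(sweep(vals, 2L, best, function(f, fp) fp - f),
                 2L, best - worst, "/")
    terms <- sweep(dev, 2L, al$weights, "*")
    S <- rowSums(terms)
    R <- apply(terms, 1L, max)
    if (diff(range(S)) == 0 || diff(range(R)) == 0)
      stop("degenerate spread: all alternatives share the same S or R; ",
           "Q is undefined")
    Q <- v * (S - min(S)) / (max(S) - min(S)) +
      (1 - v) * (R - min(R)) / (max(R) - min(R))
    ranks <- data.frame(byS = rankScores(S), byR = rankScores(R),
                        byQ = rankScores(Q),
                        row.names = rownames(vals))
    bestQ <- which.min(Q)
    qs <- sort(Q)
    advantage <- length(Q) > 1L &&
      (qs[2L] - qs[1L]) >= 1 / (length(Q) - 1L)
    stability <- ranks$byS[bestQ] == 1L || ranks$byR[bestQ] == 1L
    ideal <- data.frame(orientation = al$orientations, best = best,
                        worst = worst, row.names = colnames(vals))
    methods::new("VikorResult", S = S, R = R, Q = Q, ranks = ranks, v = v,
                 ideal = ideal,
                 criteria = criterionSet(al$weights, al$orientations),
                 conditions = c(advantage = advantage,
                                stability = stability))
  })
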