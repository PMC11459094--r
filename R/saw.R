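#' @include mcdm.R
NULL

#' Simple additive weighting (SAW)
#'
#' Normalizes the decision matrix per criterion, multiplies by the
#' criterion weights, and sums across criteria into a total score per
#' alternative. Two normalizations are offered:
#' \describe{
#'   \item{\code{"linearMax"} (default)}{beneficial: f / max(f);
#'     non-beneficial: min(f) / f. Requires strictly positive columns for
#'     the inverted form.}
#'   \item{\code{"minMax"}}{beneficial: (f - min) / (max - min);
#'     non-beneficial: (max - f) / (max - min).}
#' }
#' Both map every column into [0, 1] with 1 = best, so larger totals are
#' better and the default rank direction is descending; an ascending
#' direction is exposed because published SAW tables occasionally rank the
#' other way.
#'
#' @param x a \linkS4class{DecisionMatrix}
#' @param criteria a \linkS4class{CriterionSet} covering every column
#' @param normalization \code{"linearMax"} or \code{"minMax"}
#' @param direction rank direction for the totals: \code{"desc"} (larger
#'   total = rank 1, default) or \code{"asc"}
#' @param onConstant see [idealPoints()]; only consulted for
#'   \code{"minMax"}, which cannot normalize a constant column
#' @param ... unused
#' @return a \linkS4class{SawResult}
#' @export
setMethod("saw", "DecisionMatrix",
  function(x, criteria, normalization = c("linearMax", "minMax"),
           direction = c("desc", "asc"),
           onConstant = c("drop", "error"), ...) {
    normalization <- match.arg(normalization)
    direction <- match.arg(direction)
    if (normalization == "minMax") {
      al <- .align_criteria(x@values, criteria, onConstant)
    } else {
      cn <- colnames(x@values)
      if (!all(cn %in% criteria(criteria)))
        stop("criteria must cover every column of the decision matrix")
      al <- list(vals = x@values,
                 weights = criterionWeights(criteria)[cn],
                 orientations = criterionOrientations(criteria)[cn])
    }
    vals <- al$vals
    ben <- al$orientations == "beneficial"
    norm <- vals
    if (normalization == "linearMax") {
      for (j in seq_len(ncol(vals))) {
        col <- vals[, j]
        if (ben[j]) {
          cmax <- max(col)
          if (cmax == 0)
            stop("zero division: column maximum of ", colnames(vals)[j],
                 " is 0 under linear-max normalization")
          norm[, j] <- col / cmax
        } else {
          if (any(col == 0))
            stop("zero division: column ", colnames(vals)[j],
                 " contains 0; the inverted linear-max form divides by it")
          norm[, j] <- min(col) / col
        }
      }
    } else {
      best <- ifelse(ben, apply(vals, 2L, max), apply(vals, 2L, min))
      worst <- ifelse(ben, apply(vals, 2L, min), apply(vals, 2L, max))
      norm <- sweep(sweep(vals, 2L, worst), 2L, best - worst, "/")
    }
    weighted <- sweep(norm, 2L, al$weights, "*")
    totals <- rowSums(weighted)
    methods::new("SawResult", normalized = norm, weighted = weighted,
                 totals = totals,
                 rank = rankScores(totals, direction),
                 normalization = normalization, direction = direction)
  })
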