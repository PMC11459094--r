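# Independent brute-force oracles and frozen published values.

# Per-edge index sum computed directly over the edge list, without the
# partition machinery: the oracle for the partition route.
brute_index <- function(graph, name) {
  e <- graphEdges(graph)
  d <- graphDegrees(graph)
  total <- 0
  for (i in seq_len(nrow(e))) {
    a <- d[[e[i, 1L]]]
    b <- d[[e[i, 2L]]]
    term <- switch(name,
      RA  = 1 / sqrt(a * b),
      ABC = sqrt((a + b - 2) / (a * b)),
      M1  = a + b,
      M2  = a * b,
      SCI = 1 / sqrt(a + b),
      F   = a^2 + b^2,
      GA  = 2 * sqrt(a * b) / (a + b),
      H   = 2 / (a + b),
      HM  = (a + b)^2)
    total <- total + term
  }
  total
}

# Plain-loop VIKOR, written directly from the S/R/Q definitions.
brute_vikor <- function(values, weights, beneficial, v = 0.5) {
  m <- nrow(values)
  n <- ncol(values)
  S <- numeric(m)
  R <- numeric(m)
  for (j in seq_len(m)) {
    terms <- numeric(n)
    for (i in seq_len(n)) {
      col <- values[, i]
      fp <- if (beneficial[i]) max(col) else min(col)
      fm <- if (beneficial[i]) min(col) else max(col)
      terms[i] <- weights[i] * (fp - values[j, i]) / (fp - fm)
    }
    S[j] <- sum(terms)
    R[j] <- max(terms)
  }
  Q <- numeric(m)
  for (j in seq_len(m)) {
    Q[j] <- v * (S[j] - min(S)) / (max(S) - min(S)) +
      (1 - v) * (R[j] - min(R)) / (max(R) - min(R))
  }
  list(S = S, R = R, Q = Q)
}

# Published per-drug index values for the worked-example molecule
# (epinephrine row of the case study's index table).
EPI_INDICES <- c(RA = 6.147066, ABC = 9.439677, M1 = 60, M2 = 67,
                 SCI = 6.129915, F = 152, GA = 12.43986, H = 5.833333,
                 HM = 286)

# Worked-example degree-pair partition: {(1,2):1,(1,3):3,(2,2):2,(2,3):5,(3,3):2}
EPI_PARTITION_PAIRS <- rbind(c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
EPI_PARTITION_COUNTS <- c(1L, 3L, 2L, 5L, 2L)

# Published VIKOR tables of the case study: S, R, Q and rank per drug,
# boiling-point (bp) and enthalpy-of-vaporization (ev) weighting.
published_vikor <- function(property) {
  txt_bp <- "drug S R Q rank
Prednisone 0.527392105 0.071511068 0.397714246 10
Methyleprednisolone 0.520804376 0.067757243 0.362124907 7
Prednisolone 0.54296303 0.068162602 0.404753247 11
Epinephrine 0.638243902 0.135219512 1 16
Salbutamole 0.601727818 0.119077899 0.832156082 13
Levosalbutamole 0.618575117 0.127336402 0.914710696 15
Fluticasone 0.509280745 0.072783795 0.372989036 8
Salmeterol 0.361888448 0.05594497 0.000239342 1
Flunisolide 0.464835707 0.060075513 0.212461108 3
Ciclesonide 0.361756098 0.102243902 0.292016399 4
Mometasone 0.450132572 0.090690919 0.378969321 9
Vilanterol 0.394635128 0.069542256 0.145219109 2
Formoterol 0.464735555 0.073336968 0.295922571 5
Beclometasone 0.423257793 0.092423867 0.341299062 6
Montelukast 0.519858807 0.093927028 0.52547288 12
Zileutone 0.605031291 0.119453293 0.840497758 14"
  txt_ev <- "drug S R Q rank
Prednisone 0.528974263 0.064658425 0.426815195 6
Methyleprednisolone 0.524923022 0.061264316 0.393204055 5
Prednisolone 0.554421627 0.07495934 0.556502937 11
Epinephrine 0.599036818 0.122261923 1 16
Salbutamole 0.571980933 0.107667101 0.835191937 13
Levosalbutamole 0.584089984 0.115134223 0.915864042 15
Fluticasone 0.524607346 0.078010011 0.516302268 9
Salmeterol 0.361462583 0.054609429 0 1
Flunisolide 0.472049044 0.063165896 0.295979225 3
Ciclesonide 0.400963182 0.107503495 0.474057902 7
Mometasone 0.479851685 0.097621467 0.567051853 12
Vilanterol 0.384906253 0.067882115 0.147434254 2
Formoterol 0.454388706 0.071586238 0.321043495 4
Beclometasone 0.455272446 0.097178301 0.512046946 8
Montelukast 0.498069192 0.08745275 0.530238473 10
Zileutone 0.575119521 0.108659305 0.849130515 14"
  df <- read.table(text = if (property == "bp") txt_bp else txt_ev,
                   header = TRUE)
  rownames(df) <- df$drug
  df$drug <- NULL
  df
}

# Small random connected graph built independently of the synthetic module
# (random tree by uniform parent attachment, no degree cap).
random_tree_graph <- function(n) {
  edges <- t(vapply(2:n, function(k)
    c(paste0("t", sample.int(k - 1L, 1L)), paste0("t", k)), character(2)))
  buildGraph(edges)
}
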