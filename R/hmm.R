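#' HMM parameters for duplicon decoding
#'
#' The decoder is a three-state hidden Markov model over matrix columns with
#' states D1 and D2 (two interchangeable duplicon states, so that adjacent
#' duplicons can be told apart) and N (non-duplicon).  The self-transition
#' base probability `p = 1 - 1/L` encodes a geometric length prior with mean
#' `L`, the average length of known duplicons.  `P_o` is the probability
#' that a given SD carries a given duplicon (average duplicon copy number
#' divided by the number of SDs in the reference library); it parameterises
#' the cumulative-binomial emission model.
#'
#' @param L Mean known-duplicon length in bases (> 1).  Default 4651, the
#'   mean length of duplicons in the reference library.
#' @param P_o Per-SD duplicon occurrence probability in (0, 1).
#' @param min_len Minimum number of consecutive duplicon states for a
#'   segment to be reported as a candidate duplicon (default 100).
#' @param prob_floor Positive floor applied to transition and emission
#'   probabilities before taking logs, so that structurally possible paths
#'   never score `-Inf`.
#' @return An object of class `hmm_params` with elements `L`, `p`, `P_o`,
#'   `min_len`, `prob_floor`.
#' @export
hmm_params <- function(L = 4651, P_o = 0.05, min_len = 100L,
                       prob_floor = 1e-300) {
  if (L <= 1) stop("`L` must exceed 1")
  if (P_o <= 0 || P_o >= 1) stop("`P_o` must lie in (0, 1)")
  if (min_len < 1L) stop("`min_len` must be >= 1")
  if (prob_floor <= 0 || prob_floor >= 1) stop("`prob_floor` must be in (0,1)")
  structure(list(L = L, p = 1 - 1 / L, P_o = P_o,
                 min_len = as.integer(min_len), prob_floor = prob_floor),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: L = %g (p = %.6f), P_o = %g, min_len = %d\n",
              x$L, x$p, x$P_o, x$min_len))
  invisible(x)
}

#' Duplicon-state transition probabilities from adjacent-column patterns
#'
#' For a pair of adjacent columns with pattern counts `f11`, `f01`, `f10`,
#' the continuation weight is `omega = f11 / (f11 + f01 + f10)` and the
#' switch weight is `gamma = f01 / (f01 + f10)`.  From either duplicon
#' state the transition probabilities are `p * omega` to the same duplicon
#' state, `(1 - p * omega) * gamma` to the other duplicon state and
#' `(1 - p * omega) * (1 - gamma)` to the non-duplicon state.  Degenerate
#' denominators yield `omega = 0` (no coverage evidence) and `gamma = 0`
#' (no switching evidence: all non-stay mass goes to N).
#'
#' @param f11,f01,f10 Non-negative pattern counts (vectorised).
#' @param p Self-transition base probability in (0, 1).
#' @return A data.frame with columns `omega`, `gamma`, `stay`, `switch`,
#'   `to_non`; each row sums to 1 across the last three columns.
#' @examples
#' transition_row(1, 2, 3, p = 0.9)   # omega = 1/6, gamma = 2/5
#' @export
transition_row <- function(f11, f01, f10, p) {
  if (any(f11 < 0) || any(f01 < 0) || any(f10 < 0))
    stop("pattern counts must be non-negative")
  if (any(p <= 0) || any(p >= 1)) stop("`p` must lie in (0, 1)")
  tot <- f11 + f01 + f10
  omega <- ifelse(tot > 0, f11 / tot, 0)
  sw_tot <- f01 + f10
  gamma <- ifelse(sw_tot > 0, f01 / sw_tot, 0)
  stay <- p * omega
  data.frame(omega = omega, gamma = gamma, stay = stay,
             switch = (1 - stay) * gamma, to_non = (1 - stay) * (1 - gamma))
}

#' Duplicon-state emission probability (cumulative binomial)
#'
#' A column covered by `k` of the `m` SD rows emits, in a duplicon state,
#' `P_d = P(X <= k)` for `X ~ Binomial(m, P_o)` — the probability of seeing
#' at most the observed coverage if every SD carried the duplicon
#' independently with probability `P_o`.  The non-duplicon state emits
#' `1 - P_d`.
#'
#' @param k Number of 1s in the column, `0 <= k <= m` (vectorised).
#' @param m Number of SD rows in the matrix.
#' @param P_o Per-SD duplicon occurrence probability.
#' @param log.p Return the log probability.
#' @return `P_d` as a probability (or its log).
#' @export
emission_prob <- function(k, m, P_o, log.p = FALSE) {
  if (m < 0) stop("`m` must be non-negative")
  if (any(k < 0) || any(k > m)) stop("`k` must satisfy 0 <= k <= m")
  stats::pbinom(k, size = m, prob = P_o, log.p = log.p)
}

#' Decode the maximum-probability duplicon state path
#'
#' Runs the Viterbi algorithm in log space over the columns of an alignment
#' matrix.  The model is non-homogeneous: the transition matrix used
#' between columns j and j+1 is built from that pair's pattern counts via
#' [transition_row()].  The initial distribution puts probability 1/2 on D1
#' and 1/2 on N (D2 is reachable only by switching out of D1); the
#' non-duplicon state moves to each of D1, D2, N with probability 1/3.
#' Ties are broken deterministically, preferring N over D1 over D2.
#'
#' @param mat An [alignment_matrix()].
#' @param params An [hmm_params()] object.
#' @param stats Optional precomputed [column_stats()] for `mat`.
#' @return An object of class `state_path`: list with `states` (character
#'   vector over `"D1"`, `"D2"`, `"N"` of length `n_cols`) and `log_score`
#'   (log-probability of the decoded path).  A matrix with zero rows
#'   decodes to the all-N path.
#' @export
viterbi <- function(mat, params, stats = NULL) {
  stopifnot(inherits(mat, "alignment_matrix"), inherits(params, "hmm_params"))
  if (is.null(stats)) stats <- column_stats(mat)
  n <- mat$n_cols
  lfloor <- log(params$prob_floor)
  if (mat$m == 0L) {
    # no alignment evidence at all: P_d = 1 everywhere, N emissions floored
    score <- log(0.5) + n * lfloor + (n - 1L) * log(1 / 3)
    return(structure(list(states = rep("N", n), log_score = score),
                     class = "state_path"))
  }
  le_d <- pmax(stats::pbinom(stats$o, mat$m, params$P_o, log.p = TRUE), lfloor)
  le_n <- pmax(stats::pbinom(stats$o, mat$m, params$P_o, lower.tail = FALSE,
                             log.p = TRUE), lfloor)
  lthird <- log(1 / 3)
  if (n >= 2L) {
    tr <- transition_row(stats$f11, stats$f01, stats$f10, params$p)
    lstay <- pmax(log(tr$stay), lfloor)
    lsw <- pmax(log(tr$switch), lfloor)
    ltn <- pmax(log(tr$to_non), lfloor)
  }
  # state order: 1 = D1, 2 = D2, 3 = N; tie preference N > D1 > D2
  pref <- c(3L, 1L, 2L)
  pick <- function(v) pref[which.max(v[pref])]
  delta <- matrix(-Inf, nrow = 3L, ncol = n)
  psi <- matrix(0L, nrow = 3L, ncol = n)
  delta[, 1L] <- c(log(0.5) + le_d[1L], -Inf, log(0.5) + le_n[1L])
  if (n >= 2L) {
    for (j in 2:n) {
      i <- j - 1L
      prev <- delta[, i]
      c1 <- prev + c(lstay[i], lsw[i], lthird)
      c2 <- prev + c(lsw[i], lstay[i], lthird)
      c3 <- prev + c(ltn[i], ltn[i], lthird)
      b1 <- pick(c1); b2 <- pick(c2); b3 <- pick(c3)
      delta[1L, j] <- c1[b1] + le_d[j]
      delta[2L, j] <- c2[b2] + le_d[j]
      delta[3L, j] <- c3[b3] + le_n[j]
      psi[1L, j] <- b1; psi[2L, j] <- b2; psi[3L, j] <- b3
    }
  }
  states <- integer(n)
  states[n] <- pick(delta[, n])
  if (n >= 2L) for (j in n:2) states[j - 1L] <- psi[states[j], j]
  structure(list(states = c("D1", "D2", "N")[states],
                 log_score = delta[states[n], n]),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  r <- rle(x$states)
  cat(sprintf("state_path: %d columns, log score %.3f\n",
              length(x$states), x$log_score))
  cat("  segments:", paste(sprintf("%s x %d", r$values, r$lengths),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Extract candidate duplicons from a decoded state path
#'
#' Candidate duplicons are maximal runs of a single duplicon label (D1 or
#' D2) of length at least `min_len` states.  Adjacent runs with different
#' labels are distinct candidates.
#'
#' @param path A `state_path` from [viterbi()] (or a bare character vector
#'   of states).
#' @param min_len Minimum run length in states (default 100).
#' @param cnv_id Optional CNV identifier carried into the output.
#' @return A data.frame with columns `cnv_id`, `start`, `end` (0-based
#'   half-open column interval), `state_label` and `length`.
#' @export
extract_candidates <- function(path, min_len = 100L, cnv_id = NA_character_) {
  states <- if (inherits(path, "state_path")) path$states else path
  if (length(states) < 1L) stop("state path must have length >= 1")
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% c("D1", "D2") & r$lengths >= min_len
  data.frame(cnv_id = rep(as.character(cnv_id), sum(keep)),
             start = starts[keep], end = ends[keep],
             state_label = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}
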