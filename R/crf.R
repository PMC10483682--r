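# Linear-chain CRF: path scoring, log-partition via the forward
# recursion in log space, Viterbi decoding, forward-backward marginals
# and the negative log-likelihood training objective.
#
# Tag paths are passed as character vectors over the schema's tags;
# -Inf entries in the transition/start scores remove illegal paths
# from both the normalizer and the decoder.

#' @noRd
tags_to_idx <- function(tags, schema) {
  check_tags_known(tags, schema)
  match(tags, schema$tags)
}

#' Score one tag path under the CRF
#'
#' `score = start[y1] + sum_t E[t, y_t] + sum_{t>=2} T[y_{t-1}, y_t] +
#' end[y_T]`.
#'
#' @param emissions Numeric (seq_len x |tags|) matrix.
#' @param params An `nmu_ner_params` (only `trans`, `start`, `end` used).
#' @param path Character tag vector of length seq_len.
#' @return The path score (may be `-Inf` under constrained
#'   transitions).
#' @export
crf_score <- function(emissions, params, path) {
  if (length(path) != nrow(emissions)) {
    stop_nmu("path length must equal sequence length",
             class = "nmutext_contract_error")
  }
  y <- tags_to_idx(path, params$schema)
  s <- params$start[y[1]] + sum(emissions[cbind(seq_along(y), y)]) +
    params$end[y[length(y)]]
  if (length(y) > 1) {
    s <- s + sum(params$trans[cbind(y[-length(y)], y[-1])])
  }
  unname(s)
}

#' Log-partition function of the CRF
#'
#' `log` of the sum over all tag paths of `exp(crf_score)`, computed by
#' the forward recursion with log-sum-exp so long sequences stay
#' numerically stable.  Paths through `-Inf` transition sentinels
#' contribute nothing, so under constrained transitions the sum runs
#' over legal paths only.
#'
#' @inheritParams crf_score
#' @return A finite scalar (or `-Inf` if no path is admissible).
#' @export
crf_log_partition <- function(emissions, params) {
  if (anyNA(emissions)) {
    stop_nmu("NaN in emissions", class = "nmutext_contract_error")
  }
  alpha <- crf_forward(emissions, params)
  logsumexp(alpha[nrow(alpha), ] + params$end)
}

# Forward log-messages: alpha[t, j] = log sum over prefixes ending in
# tag j at position t (end scores not yet added).
#' @noRd
crf_forward <- function(emissions, params) {
  T_len <- nrow(emissions); K <- ncol(emissions)
  alpha <- matrix(-Inf, T_len, K)
  alpha[1, ] <- params$start + emissions[1, ]
  if (T_len > 1) {
    for (t in 2:T_len) {
      for (j in seq_len(K)) {
        alpha[t, j] <- logsumexp(alpha[t - 1, ] + params$trans[, j]) +
          emissions[t, j]
      }
    }
  }
  alpha
}

# Backward log-messages: beta[t, i] = log sum over suffixes from tag i
# at position t (including the end score).
#' @noRd
crf_backward <- function(emissions, params) {
  T_len <- nrow(emissions); K <- ncol(emissions)
  beta <- matrix(-Inf, T_len, K)
  beta[T_len, ] <- params$end
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      for (i in seq_len(K)) {
        beta[t, i] <- logsumexp(params$trans[i, ] + emissions[t + 1, ] +
                                  beta[t + 1, ])
      }
    }
  }
  beta
}

#' Maximum-scoring tag path (Viterbi decoding)
#'
#' Dynamic-programming argmax with deterministic tie-breaking toward
#' the lowest tag index at every backtrack step.  Under constrained
#' transitions the decoded path is always IOB2-legal.
#'
#' @inheritParams crf_score
#' @return List with `path` (character tags) and `score`.
#' @export
viterbi_decode <- function(emissions, params) {
  if (anyNA(emissions)) {
    stop_nmu("NaN in emissions", class = "nmutext_contract_error")
  }
  T_len <- nrow(emissions); K <- ncol(emissions)
  delta <- matrix(-Inf, T_len, K)
  back <- matrix(0L, T_len, K)
  delta[1, ] <- params$start + emissions[1, ]
  if (T_len > 1) {
    for (t in 2:T_len) {
      for (j in seq_len(K)) {
        cand <- delta[t - 1, ] + params$trans[, j]
        best <- which.max(cand)  # first maximum = lowest tag index
        back[t, j] <- best
        delta[t, j] <- cand[best] + emissions[t, j]
      }
    }
  }
  final <- delta[T_len, ] + params$end
  if (!any(is.finite(final))) {
    stop_nmu("no admissible tag path (over-constrained transitions)",
             class = "nmutext_decode_error")
  }
  y <- integer(T_len)
  y[T_len] <- which.max(final)
  if (T_len > 1) {
    for (t in (T_len - 1):1) y[t] <- back[t + 1, y[t + 1]]
  }
  list(path = params$schema$tags[y], score = unname(max(final)))
}

# Forward-backward expectations needed for the NLL gradient:
# node marginals P(y_t = k) and, summed over positions, pairwise
# transition expectations P(y_{t-1} = i, y_t = j).
#' @noRd
crf_marginals <- function(emissions, params) {
  T_len <- nrow(emissions); K <- ncol(emissions)
  alpha <- crf_forward(emissions, params)
  beta <- crf_backward(emissions, params)
  logZ <- logsumexp(alpha[T_len, ] + params$end)
  node <- exp(alpha + beta - logZ)
  node[is.na(node)] <- 0  # -Inf + Inf cannot occur; guard exp(-Inf - -Inf)
  pair <- matrix(0, K, K)
  if (T_len > 1) {
    for (t in 2:T_len) {
      lp <- outer(alpha[t - 1, ], emissions[t, ] + beta[t, ], `+`) +
        params$trans - logZ
      p <- exp(lp)
      p[!is.finite(lp)] <- 0
      pair <- pair + p
    }
  }
  list(node = node, pair = pair, logZ = logZ)
}

#' CRF negative log-likelihood of gold tag paths
#'
#' Mean over the batch of `log Z - crf_score(gold)`; non-negative by
#' construction.  Gold sequences that are impossible under constrained
#' transitions (score `-Inf`) are a contract violation.
#'
#' @param params An `nmu_ner_params`.
#' @param batch List of elements, each with `tokens` and `tags`
#'   (character vectors of equal length); alternatively `emissions`
#'   may be supplied directly in place of `tokens`.
#' @param provider Embedding provider (needed when batch elements
#'   carry `tokens`).
#' @return Mean negative log-likelihood (scalar, >= 0 up to rounding).
#' @export
crf_nll <- function(params, batch, provider = NULL) {
  losses <- vapply(batch, function(item) {
    E <- item$emissions
    if (is.null(E)) E <- emissions(item$tokens, params, provider)
    s <- crf_score(E, params, item$tags)
    if (!is.finite(s)) {
      stop_nmu("gold path impossible under constrained transitions",
               class = "nmutext_contract_error")
    }
    crf_log_partition(E, params) - s
  }, numeric(1))
  mean(losses)
}
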