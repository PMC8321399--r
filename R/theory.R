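# ---- probability model of weight-lightest edge detection -------------------

#' Single-round co-blocking probability
#'
#' Under the uniform-minimizer hypothesis (every k-mer of an L-long read is
#' equally likely to be the minimizer), two reads whose best alignment has
#' `s` shifting bases and `t` differing k-mers in the overlap share the same
#' k-minimizer — and therefore land in the same block of one indexing round —
#' with probability
#' \deqn{p(k) = \left(\frac{L - k + 1 - (s + t)}{L - k + 1}\right)^2.}
#'
#' @param L read length (bases).
#' @param k k-mer size of the round.
#' @param s shifting bases of the best alignment.
#' @param t number of differing k-mers in the overlap substring.
#' @return probability in `[0, 1]` (vectorized over the arguments).
#' @export
p_single <- function(L, k, s, t) {
  nk <- L - k + 1
  if (any(k > L)) stop("k exceeds the read length", call. = FALSE)
  if (any(s + t > nk) || any(s < 0) || any(t < 0)) {
    stop("domain error: need 0 <= s + t <= L - k + 1", call. = FALSE)
  }
  ((nk - (s + t)) / nk)^2
}

#' Multi-round detection probability
#'
#' Probability that two reads are clustered into the same block in at least
#' one of `n` independent indexing rounds with per-round probabilities
#' `p_i`: `p = 1 - prod(1 - p_i)`, together with the lower bound
#' `1 - (1 - min(p_i))^n`.
#'
#' @param p_values per-round co-blocking probabilities, each in `[0, 1]`.
#' @return list with `probability` and `lower_bound`.
#' @export
p_multi <- function(p_values) {
  if (!length(p_values)) stop("domain error: empty probability list", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("domain error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  list(probability = 1 - prod(1 - p_values),
       lower_bound = 1 - (1 - min(p_values))^length(p_values))
}

#' Monte-Carlo check of the co-blocking probability
#'
#' Simulates read pairs sharing an overlap (`shift` offset bases, point
#' substitutions at `error_rate` applied independently to each read) and
#' measures how often the two reads share a k-minimizer. The hashed k-mer
#' ordering approximates the uniform-minimizer hypothesis; the model
#' prediction uses [p_single()] with `t` set to the realized count of
#' differing k-mers of each simulated pair.
#'
#' @param L read length.
#' @param k k-mer size.
#' @param error_rate per-base substitution probability.
#' @param shift offset bases between the two reads.
#' @param n_pairs number of simulated pairs.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param ordering k-mer ordering (default hashed; see [round_config()]).
#' @return list with `p_hat` (empirical sharing rate), `se` (Monte-Carlo
#'   standard error), `p_model` (mean squared-form prediction over realized
#'   `t`, a slight underestimate because it treats the two reads' minimizer
#'   draws as independent), `p_exact` (the dependent-ordering probability
#'   `c / (2(L-k+1) - c)` averaged over pairs) and `n_pairs`.
#' @export
monte_carlo_coblocking <- function(L, k, error_rate, shift, n_pairs = 10000L,
                                   seed, ordering = c("hashed", "lexicographic")) {
  ordering <- match.arg(ordering)
  stopifnot(L >= k, shift >= 0, shift < L, n_pairs > 0)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  tpl_len <- L + shift
  tpl <- matrix(sample(bases, n_pairs * tpl_len, replace = TRUE),
                nrow = n_pairs)
  mutate <- function(mat) {
    hit <- which(runif(length(mat)) < error_rate)
    if (length(hit)) {
      old_codes <- match(mat[hit], bases)
      mat[hit] <- bases[(old_codes - 1L + sample(1:3, length(hit),
                                                 replace = TRUE)) %% 4L + 1L]
    }
    mat
  }
  u_mat <- mutate(tpl[, seq_len(L), drop = FALSE])
  v_mat <- mutate(tpl[, shift + seq_len(L), drop = FALSE])
  u <- apply(u_mat, 1L, paste0, collapse = "")
  v <- apply(v_mat, 1L, paste0, collapse = "")
  hu <- .scan_hits(u, u, k, FALSE, ordering, 17L, both_strands = FALSE)
  hv <- .scan_hits(v, v, k, FALSE, ordering, 17L, both_strands = FALSE)
  share <- !is.na(hu$kmer) & !is.na(hv$kmer) & hu$kmer == hv$kmer
  p_hat <- mean(share)
  # realized t: differing aligned k-mer windows within the overlap
  n_ov <- L - shift - k + 1L
  diff_ct <- integer(n_pairs)
  for (w in seq_len(max(n_ov, 0L)) - 1L) {
    uw <- substr(u, shift + w + 1L, shift + w + k)
    vw <- substr(v, w + 1L, w + k)
    diff_ct <- diff_ct + (uw != vw)
  }
  nk <- L - k + 1L
  st <- pmin(shift + diff_ct, nk)
  cm <- nk - st                        # common aligned k-mers
  p_model <- mean((cm / nk)^2)
  # the squared form treats the two minimizer draws as independent; under a
  # shared random ordering both minimizers equal the minimum over the union
  # of windows, giving exactly c / (2*nk - c) -- a slightly larger value
  p_exact <- mean(ifelse(cm > 0, cm / (2 * nk - cm), 0))
  list(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_pairs),
       p_model = p_model, p_exact = p_exact, n_pairs = n_pairs)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
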