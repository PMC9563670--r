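# run code with a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permute condition labels for the permutation null
#'
#' Builds the label permutations used to form the empirical null of the
#' impact factor. In paired mode each patient's pre/post labels are swapped
#' independently with probability 1/2 (a within-pair sign-flip scheme), so the
#' pair structure is preserved. In unpaired mode the condition labels are
#' shuffled across all samples, preserving the label counts.
#'
#' @param samples Sample metadata data frame (`sample_id`, `condition`, and
#'   `pair_id` in paired mode).
#' @param paired Use the within-pair swap scheme?
#' @param n_permutations Number of permuted label tables (default 10).
#' @param seed Integer seed; the stream is reproducible and does not disturb
#'   the caller's RNG state.
#' @return List of `n_permutations` sample data frames.
#' @export
permute_labels <- function(samples, paired = TRUE, n_permutations = 10L,
                           seed = 1L) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (paired && (!"pair_id" %in% names(samples) || anyNA(samples$pair_id))) {
    stop("paired permutation requires complete pair_id metadata", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_permutations), function(i) {
      out <- samples
      if (paired) {
        for (pid in unique(samples$pair_id)) {
          if (stats::runif(1) < 0.5) {
            j <- which(samples$pair_id == pid)
            out$condition[j] <- c(pre = "post", post = "pre")[samples$condition[j]]
          }
        }
      } else {
        out$condition <- sample(samples$condition)
      }
      out
    })
  })
}

#' Empirical tail p-value against a permutation null
#'
#' The p-value is the upper-tail proportion of null scores at least as large
#' as the observed score, with an add-one pseudo-count so that a score beyond
#' every null draw gets `1 / (M + 1)` rather than zero. Null scores must come
#' from subpathways of the same length as the observed one (length-stratified
#' null).
#'
#' @param observed Observed impact factor(s); vectorized.
#' @param null_scores Numeric vector of impact factors from permuted datasets,
#'   pooled over subpathways of the same length.
#' @return Empirical p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_scores) {
  if (!length(null_scores)) stop("empty permutation null", call. = FALSE)
  vapply(observed, function(x) (1 + sum(null_scores >= x)) / (1 + length(null_scores)),
         numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values (rank-preserving).
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
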