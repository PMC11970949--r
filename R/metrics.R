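# Diversity figures of merit: Hamming distance curves and Shannon entropies.

#' Hamming distance between two solution vectors
#'
#' Counts the positions at which the two vectors differ; the magnitude of a
#' difference is ignored (each differing integer variable contributes exactly
#' 1). For example `hamming(c(1,2,3,4), c(1,0,3,5))` is 2.
#'
#' @param x,y Numeric (or character key) vectors of equal length; character
#'   scalars are decoded as solution keys.
#' @return Nonnegative integer.
#' @export
hamming <- function(x, y) {
  if (is.character(x) && length(x) == 1) x <- key_values(x)
  if (is.character(y) && length(y) == 1) y <- key_values(y)
  if (length(x) != length(y)) {
    stop_morseopt("hamming distance needs vectors of equal length",
                  "morseopt_contract_error")
  }
  sum(x != y)
}

#' Average pairwise Hamming distance curve
#'
#' Entry `i` (for `i >= 2`) is the mean Hamming distance over all unordered
#' pairs among the first `i` keys in the given order, divided by
#' `normalizer`; entry 1 is defined as 0. With `normalizer` equal to the
#' number of binary/integer objective variables (the total binary solution
#' size), values lie in `[0, 1]`.
#'
#' @param keys Character vector of solution keys (an ordering of a batch's
#'   solution list, duplicates included), or a numeric key matrix.
#' @param normalizer Positive number to divide the mean distance by.
#' @return Numeric vector of length `length(keys)`.
#' @export
avg_pairwise_hamming_curve <- function(keys, normalizer) {
  stopifnot(normalizer > 0)
  km <- if (is.matrix(keys)) keys else keys_to_matrix(keys)
  k <- nrow(km)
  if (k == 0) return(numeric(0))
  curve <- numeric(k)
  total <- 0
  for (i in seq_len(k)[-1]) {
    total <- total + sum(hamming_to_row(km[seq_len(i - 1), , drop = FALSE],
                                        km[i, , drop = TRUE]))
    curve[i] <- total / choose(i, 2) / normalizer
  }
  curve
}

#' Solution multiset with empirical probabilities
#'
#' @param keys Character vector of solution keys, repetitions allowed, in
#'   sampling order.
#' @return An object of class `solution_multiset` with `keys` (as given),
#'   `counts` and `probabilities` over the distinct keys (first-seen order).
#' @export
solution_multiset <- function(keys) {
  keys <- keys[!is.na(keys)]
  if (!length(keys)) {
    stop_morseopt("empty solution multiset", "morseopt_contract_error")
  }
  distinct <- unique(keys)
  counts <- vapply(distinct, function(k) sum(keys == k), numeric(1))
  structure(
    list(keys = keys, counts = counts, probabilities = counts / sum(counts)),
    class = "solution_multiset"
  )
}

#' @export
print.solution_multiset <- function(x, ...) {
  cat(sprintf("<solution_multiset> %d draws, %d distinct\n",
              length(x$keys), length(x$counts)))
  invisible(x)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a solution multiset
#'
#' `-sum(p * log2(p))` over the empirical probabilities of the distinct
#' solutions in the sampled list (no deduplication, no normalization by the
#' number of distinct solutions). Higher entropy means less sampling bias
#' among the optima; the maximum, `log2(k)` for `k` distinct solutions, is
#' attained exactly at uniform multiplicities.
#'
#' @param x A `solution_multiset`, a character vector of keys, or a numeric
#'   vector of probabilities/counts.
#' @return Nonnegative numeric scalar (bits).
#' @examples
#' entropy_multiset(c(1, 2) / 3)            # ~0.918
#' entropy_multiset(rep(1, 3) / 3)          # ~1.585
#' entropy_multiset(c("a", "a", "a", "b", "b", "c"))  # counts 3,2,1 -> ~1.459
#' @export
entropy_multiset <- function(x) {
  if (inherits(x, "solution_multiset")) return(shannon_entropy(x$probabilities))
  if (is.character(x)) return(shannon_entropy(solution_multiset(x)$probabilities))
  if (!length(x)) stop_morseopt("empty solution multiset", "morseopt_contract_error")
  stopifnot(is.numeric(x), all(x >= 0), sum(x) > 0)
  shannon_entropy(x / sum(x))
}

#' Average per-variable Shannon entropy
#'
#' For each objective-function variable, the Shannon entropy of its empirical
#' value distribution across the sampled solution list; returned is the
#' unweighted mean over those variables. A variable constant across all
#' solutions contributes 0.
#'
#' @param keys Character vector of solution keys (with repetitions) or a
#'   numeric key matrix.
#' @param instance Optional [mip_instance()] (labels columns; the key itself
#'   fixes the variable set).
#' @return Nonnegative numeric scalar (bits).
#' @export
avg_variable_entropy <- function(keys, instance = NULL) {
  km <- if (is.matrix(keys)) keys else keys_to_matrix(keys, instance)
  if (!nrow(km)) stop_morseopt("no solutions", "morseopt_contract_error")
  ent <- apply(km, 2, function(col) {
    shannon_entropy(as.numeric(table(col)) / length(col))
  })
  mean(ent)
}

#' Assemble the full diversity report for a pair of orderings
#'
#' Computes, for each requested ordering of a batch's solution list, the
#' average pairwise Hamming distance curve, plus the distinct-optima curve,
#' the solution-multiset entropy and the averaged per-variable entropy.
#'
#' @param batch A `batch_result`.
#' @param orderings Subset of `c("seed_based", "random_shuffle",
#'   "greedy_diversity")`.
#' @param order_seed Seed for the randomized orderings.
#' @param normalizer `"auto"` (count of binary/integer objective variables)
#'   or a positive number.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(batch,
                           orderings = c("seed_based", "random_shuffle", "greedy_diversity"),
                           order_seed = 0L, normalizer = "auto") {
  stopifnot(inherits(batch, "batch_result"))
  orderings <- match.arg(orderings, several.ok = TRUE)
  if (identical(normalizer, "auto")) {
    normalizer <- length(integral_objective_variables(batch$instance))
  }
  stopifnot(is.numeric(normalizer), normalizer > 0)
  keys <- batch$keys[!is.na(batch$keys)]
  curves <- lapply(orderings, function(m) {
    avg_pairwise_hamming_curve(ordered_keys(batch, m, order_seed), normalizer)
  })
  names(curves) <- orderings
  structure(
    list(instance_name = batch$instance_name, mode = batch$mode,
         hamming_curves = curves,
         distinct_curve = distinct_curve(batch),
         multiset_entropy = entropy_multiset(keys),
         avg_variable_entropy = avg_variable_entropy(keys),
         normalizer = normalizer),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (%s): %d distinct optima, multiset entropy %.3f bits, avg variable entropy %.3f bits\n",
              x$instance_name, x$mode, max(x$distinct_curve$distinct),
              x$multiset_entropy, x$avg_variable_entropy))
  invisible(x)
}
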