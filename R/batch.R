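# Batches of independent runs and orderings of the collected solutions.

#' Run a batch of independent perturb-and-solve runs
#'
#' Executes one run per seed (seeds must be distinct), mutually independent:
#' the result is identical whether the runs execute serially or concurrently,
#' because each run's randomness derives only from its own seed. The
#' reference optimal value and epsilon are computed once and shared.
#'
#' @param instance A [mip_instance()]; must pass [screen_instance()].
#' @param seeds Integer vector of distinct seeds (default `0:(runs-1)`).
#' @param runs Number of runs when `seeds` is not given.
#' @param mode `"morse"` or `"uniform"` (identity-perturbation baseline).
#' @param epsilon Optional radius or `epsilon_report`; derived if `NULL`.
#' @param backend Solver backend.
#' @param tolerance Verification tolerance, see [morse_single_run()].
#' @return An object of class `batch_result`: `instance_name`, `mode`,
#'   `records` (sorted by seed), `keys` (one per record, `NA` for failed
#'   runs), `distinct_keys` (first-seen order), `reference_value`,
#'   `epsilon_report`.
#' @examples
#' toy <- toy_fixtures()$toy_2var
#' b <- run_batch(toy, runs = 10, mode = "morse")
#' b$distinct_keys
#' @export
run_batch <- function(instance, seeds = NULL, runs = NULL,
                      mode = c("morse", "uniform"), epsilon = NULL,
                      backend = "bnb", tolerance = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(instance, "mip_instance"))
  if (is.null(seeds)) {
    if (is.null(runs)) stop("provide `seeds` or `runs`")
    seeds <- seq_len(runs) - 1L
  }
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  seeds <- sort(seeds)

  eps_rep <- if (mode == "morse") resolve_epsilon(instance, epsilon, backend) else NULL
  ref <- solve_to_optimality(instance, seed = 0L, backend = backend)
  reference_value <- if (ref$status == "optimal") ref$objective_value else NULL

  records <- lapply(seeds, function(s) {
    tryCatch(
      morse_single_run(instance, seed = s, mode = mode, epsilon = eps_rep,
                       backend = backend, reference_value = reference_value,
                       tolerance = tolerance),
      error = function(e) {
        new_run_record(s, mode, NULL,
                       structure(list(values = NULL, objective_value = NA_real_,
                                      status = "error",
                                      detail = conditionMessage(e)),
                                 class = "mip_solution"),
                       NA_real_, NA_real_, FALSE, backend, eps_rep)
      }
    )
  })
  keys <- vapply(records, function(r) {
    if (r$solution$status == "optimal") solution_key(instance, r$solution) else NA_character_
  }, character(1))
  ok <- !is.na(keys)
  structure(
    list(instance_name = instance$name, mode = mode, records = records,
         keys = keys, distinct_keys = unique(keys[ok]),
         reference_value = reference_value, epsilon_report = eps_rep,
         instance = instance),
    class = "batch_result"
  )
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %s, mode=%s: %d runs, %d distinct optima\n",
              x$instance_name, x$mode, length(x$records),
              length(x$distinct_keys)))
  invisible(x)
}

#' Cumulative distinct-optima curve
#'
#' Entry `i` is the number of distinct solution keys among the first `i`
#' records (in seed order); the curve is nondecreasing and bounded by `i`.
#' Failed runs contribute no key and leave the count unchanged.
#'
#' @param batch A `batch_result`.
#' @return A `data.frame` with columns `run_index` and `distinct`.
#' @export
distinct_curve <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  keys <- batch$keys
  seen <- !is.na(keys) & !duplicated(keys)
  data.frame(run_index = seq_along(keys), distinct = cumsum(seen))
}

#' Order the solutions of a batch
#'
#' Three orderings of the collected solution list (duplicates participate as
#' separate entries):
#' * `seed_based` — the identity: records are already sorted by seed;
#' * `random_shuffle` — a uniform random permutation drawn from `order_seed`;
#' * `greedy_diversity` — first element drawn uniformly at random from
#'   `order_seed`; each subsequent element is the remaining solution that
#'   maximizes the average pairwise Hamming distance to all previously
#'   selected solutions, ties broken by earliest seed order.
#'
#' @param batch A `batch_result`.
#' @param method Ordering method.
#' @param order_seed Seed for the random choices of `random_shuffle` and
#'   `greedy_diversity`.
#' @return An integer permutation of `seq_along(batch$records)`.
#' @export
order_solutions <- function(batch,
                            method = c("seed_based", "random_shuffle", "greedy_diversity"),
                            order_seed = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(batch, "batch_result"))
  idx <- which(!is.na(batch$keys))
  if (!length(idx)) stop_morseopt("batch has no successful runs", "morseopt_contract_error")
  n <- length(batch$records)
  if (method == "seed_based") return(seq_len(n))
  if (method == "random_shuffle") {
    return(with_seed(order_seed, sample.int(n)))
  }
  # greedy for diversity, over successful records; failed runs appended last
  km <- keys_to_matrix(batch$keys[idx])
  k <- length(idx)
  first <- with_seed(order_seed, sample.int(k, 1))
  selected <- first
  remaining <- setdiff(seq_len(k), first)
  # running sum of Hamming distances from each remaining row to the selection
  dsum <- hamming_to_row(km, km[first, , drop = TRUE])
  while (length(remaining)) {
    best <- remaining[which.max(dsum[remaining])]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      dsum <- dsum + hamming_to_row(km, km[best, , drop = TRUE])
    }
  }
  c(idx[selected], setdiff(seq_len(n), idx))
}

# Hamming distance from every row of a key matrix to one key row.
hamming_to_row <- function(km, row) {
  rowSums(km != matrix(row, nrow(km), length(row), byrow = TRUE))
}

#' Keys of a batch in a chosen ordering
#'
#' Convenience wrapper around [order_solutions()] that returns the reordered
#' solution keys (failed runs dropped).
#'
#' @inheritParams order_solutions
#' @return Character vector of keys.
#' @export
ordered_keys <- function(batch,
                         method = c("seed_based", "random_shuffle", "greedy_diversity"),
                         order_seed = 0L) {
  perm <- order_solutions(batch, method, order_seed)
  keys <- batch$keys[perm]
  keys[!is.na(keys)]
}
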