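# Random multiplicative perturbation of objective coefficients, the core
# randomized step: one multiplier per binary/integer objective variable,
# drawn i.i.d. from the uniform distribution on [1 - eps, 1 + eps).

#' Sample a perturbation vector
#'
#' Draws one multiplier per binary/integer objective variable, i.i.d. uniform
#' on `[1 - epsilon, 1 + epsilon)`; continuous objective variables are never
#' perturbed. `epsilon = 0` is allowed as the degenerate identity draw.
#' Reproducible for a fixed seed.
#'
#' @param instance A [mip_instance()].
#' @param epsilon Nonnegative perturbation radius.
#' @param seed Integer seed for the draw.
#' @return An object of class `perturbation_vector`: `multipliers` (named),
#'   `epsilon`, `seed`.
#' @examples
#' toy <- toy_fixtures()$toy_2var
#' sample_perturbation(toy, epsilon = 0.01, seed = 1)
#' @export
sample_perturbation <- function(instance, epsilon, seed) {
  stopifnot(inherits(instance, "mip_instance"), epsilon >= 0)
  iv <- integral_objective_variables(instance)
  mult <- if (epsilon == 0) {
    rep(1, length(iv))
  } else {
    with_seed(seed, stats::runif(length(iv), 1 - epsilon, 1 + epsilon))
  }
  names(mult) <- iv
  structure(list(multipliers = mult, epsilon = epsilon, seed = as.integer(seed)),
            class = "perturbation_vector")
}

#' Identity perturbation (the homogeneous/uniform-weights baseline)
#'
#' All multipliers exactly 1; applying it leaves the objective unchanged.
#'
#' @param instance A [mip_instance()].
#' @return A `perturbation_vector` with all multipliers 1 and `epsilon = 0`.
#' @export
identity_perturbation <- function(instance) {
  iv <- integral_objective_variables(instance)
  structure(list(multipliers = stats::setNames(rep(1, length(iv)), iv),
                 epsilon = 0, seed = NA_integer_, identity = TRUE),
            class = "perturbation_vector")
}

is_identity_perturbation <- function(v) {
  isTRUE(v$identity) || all(v$multipliers == 1)
}

#' @export
print.perturbation_vector <- function(x, ...) {
  cat(sprintf("<perturbation_vector> %d multipliers, epsilon=%g%s\n",
              length(x$multipliers), x$epsilon,
              if (is_identity_perturbation(x)) " (identity)" else ""))
  invisible(x)
}

#' Apply a perturbation vector to an instance
#'
#' Returns an instance with identical variables, bounds, constraints and
#' sense, and objective coefficient `c * v` for each binary/integer objective
#' variable; coefficients of continuous variables are untouched. Zero
#' coefficients stay zero, and each perturbed coefficient keeps the sign of
#' the original.
#'
#' @param instance A [mip_instance()].
#' @param v A `perturbation_vector` whose multiplier domain matches the
#'   instance's binary/integer objective variables.
#' @return A perturbed [mip_instance()].
#' @examples
#' toy <- toy_fixtures()$toy_2var
#' v1 <- structure(list(multipliers = c(x1 = 0.99864, x2 = 1.00142),
#'                      epsilon = 0.01, seed = NA_integer_),
#'                 class = "perturbation_vector")
#' apply_perturbation(toy, v1)$objective
#' @export
apply_perturbation <- function(instance, v) {
  stopifnot(inherits(instance, "mip_instance"),
            inherits(v, "perturbation_vector"))
  iv <- integral_objective_variables(instance)
  if (!setequal(names(v$multipliers), iv)) {
    stop_morseopt(
      "perturbation domain does not match the instance's integral objective variables",
      "morseopt_contract_error"
    )
  }
  out <- instance
  out$objective[iv] <- instance$objective[iv] * v$multipliers[iv]
  attr(out, "perturbation") <- v
  out
}

#' Verify a candidate solution against the original instance
#'
#' A perturbed-instance optimum is accepted as an optimum of the original
#' instance iff it is feasible for the original and its original-objective
#' value matches the reference optimal value to within a relative tolerance.
#'
#' @param original The unperturbed [mip_instance()].
#' @param candidate A solver solution (list with `values`) or named vector.
#' @param reference_value True optimal value of the original instance.
#' @param tolerance Relative tolerance (default `1e-6`).
#' @return Logical scalar.
#' @export
verify_optimal_in_original <- function(original, candidate, reference_value,
                                       tolerance = 1e-6) {
  values <- if (is.list(candidate)) candidate$values else candidate
  if (is.null(values)) return(FALSE)
  if (!is_feasible(original, values, tol = tolerance)) return(FALSE)
  obj <- objective_value(original, values)
  abs(obj - reference_value) <= tolerance * max(1, abs(reference_value))
}

new_run_record <- function(seed, mode, perturbation, solution, original_value,
                           perturbed_value, verified, backend, epsilon_report) {
  structure(
    list(seed = as.integer(seed), mode = mode, perturbation = perturbation,
         solution = solution, original_objective_value = original_value,
         perturbed_objective_value = perturbed_value,
         verified_optimal = verified, backend = backend,
         epsilon_report = epsilon_report),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> seed=%d mode=%s status=%s original_objective=%s verified=%s\n",
              x$seed, x$mode, x$solution$status,
              format(x$original_objective_value),
              format(x$verified_optimal)))
  invisible(x)
}

#' One perturb-and-solve run
#'
#' The unit of work: choose (or accept) epsilon, sample a perturbation vector
#' from `seed` (or the identity for the uniform-weights baseline), solve the
#' perturbed instance to optimality, evaluate the solution under the original
#' objective, and verify optimality against the original instance.
#' Verification is mandatory when the instance has continuous variables
#' (preservation cannot be guaranteed there) and is performed as an audit
#' otherwise whenever a reference value is available or computable.
#'
#' @param instance A [mip_instance()]; must pass [screen_instance()].
#' @param seed Integer seed; drives the perturbation draw and the backend's
#'   tie-breaking randomness (both recorded).
#' @param mode `"morse"` (random perturbation) or `"uniform"` (identity
#'   perturbation, backend seed variation only).
#' @param epsilon Radius, an `epsilon_report`, or `NULL` to derive it via
#'   [choose_epsilon()] with fallback to a reference solve.
#' @param backend Solver backend, see [solve_to_optimality()].
#' @param reference_value Optimal value of the original instance, if already
#'   known (avoids one extra solve per run in batches).
#' @param verify Logical; `NULL` (default) verifies always.
#' @param resample Number of times to retry with a fresh derived seed when
#'   verification fails (relevant only for instances with continuous
#'   variables); `0` records the failed run with
#'   `verified_optimal = FALSE`.
#' @param tolerance Relative optimality tolerance for verification.
#' @return A `run_record`.
#' @examples
#' toy <- toy_fixtures()$toy_2var
#' morse_single_run(toy, seed = 3)
#' @export
morse_single_run <- function(instance, seed, mode = c("morse", "uniform"),
                             epsilon = NULL, backend = "bnb",
                             reference_value = NULL, verify = NULL,
                             resample = 0, tolerance = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(instance, "mip_instance"))
  if (screen_instance(instance) != "accept") {
    stop_morseopt("instance rejected by screening: no integral objective variable",
                  "morseopt_contract_error")
  }
  eps_rep <- if (mode == "morse") resolve_epsilon(instance, epsilon, backend) else NULL

  do_verify <- verify %||% TRUE
  if (do_verify && is.null(reference_value)) {
    ref <- solve_to_optimality(instance, seed = 0L, backend = backend)
    if (ref$status != "optimal") {
      # infeasible/unbounded original: report through the run record
      sol <- ref
      return(new_run_record(seed, mode, NULL, sol, NA_real_, NA_real_, FALSE,
                            backend, eps_rep))
    }
    reference_value <- ref$objective_value
  }

  attempt_seed <- as.integer(seed)
  for (attempt in seq_len(resample + 1)) {
    v <- if (mode == "morse") {
      sample_perturbation(instance, eps_rep$epsilon, attempt_seed)
    } else {
      identity_perturbation(instance)
    }
    perturbed <- apply_perturbation(instance, v)
    sol <- solve_to_optimality(perturbed, seed = attempt_seed, backend = backend)
    if (sol$status != "optimal") {
      return(new_run_record(attempt_seed, mode, v, sol, NA_real_, NA_real_,
                            FALSE, backend, eps_rep))
    }
    orig_val <- objective_value(instance, sol$values)
    pert_val <- sol$objective_value
    verified <- if (do_verify) {
      verify_optimal_in_original(instance, sol, reference_value, tolerance)
    } else {
      NA
    }
    if (!do_verify || isTRUE(verified) || attempt > resample) {
      if (isFALSE(verified) && attempt > resample && resample > 0) {
        warning("verification failed after ", resample, " resamples; run recorded as unverified")
      }
      return(new_run_record(attempt_seed, mode, v, sol, orig_val, pert_val,
                            verified, backend, eps_rep))
    }
    # fresh derived seed, kept within 32-bit integer range
    attempt_seed <- as.integer((attempt_seed + 104729 * attempt) %% .Machine$integer.max)
  }
}
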