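# Instance-adaptive choice of the perturbation radius epsilon.
#
# The radius must be small enough that multiplying each binary/integer
# objective coefficient by a factor in [1 - eps, 1 + eps] can reorder only
# solutions that are exactly tied in the original objective. With integer
# coefficients and integer variables, distinct objective values differ by at
# least 1, while the perturbation moves any feasible value by at most
# eps * S, where S bounds sum(|c_i x_i|); eps = 1/(2 S) keeps the movement
# under 1/2 on both solutions being compared.

f_weight <- function(coef, lb, ub, vtype) {
  ifelse(vtype == "Continuous", 0, abs(coef) * pmax(abs(lb), abs(ub)))
}

#' Bound-weighted sum of absolute objective coefficients
#'
#' Computes `S = sum(|c| * max(|lb|, |ub|))` over the binary/integer objective
#' variables (continuous variables contribute 0). `S` bounds the absolute
#' objective contribution of the perturbable terms at any feasible point.
#'
#' @param instance A [mip_instance()].
#' @return Nonnegative numeric scalar.
#' @details Every counted variable (nonzero coefficient, integral type) must
#'   have finite bounds; otherwise an error of class
#'   `morseopt_bounds_unavailable` is signalled, and the caller should fall
#'   back to [epsilon_from_reference_solution()].
#' @examples
#' weight_sum_S(toy_fixtures()$eps_example)  # 20
#' @export
weight_sum_S <- function(instance) {
  stopifnot(inherits(instance, "mip_instance"))
  vars <- instance$variables
  obj <- instance$objective
  idx <- match(names(obj), vars$name)
  counted <- obj != 0 & vars$vtype[idx] != "Continuous"
  if (any(counted & (!is.finite(vars$lb[idx]) | !is.finite(vars$ub[idx])))) {
    stop_morseopt(
      "bounds unavailable: an integral objective variable has an infinite bound",
      "morseopt_bounds_unavailable"
    )
  }
  sum(f_weight(obj, vars$lb[idx], vars$ub[idx], vars$vtype[idx]))
}

#' Least integralizing scale factor for a coefficient vector
#'
#' Returns the least positive integer `L` such that `L * c` is integral for
#' every coefficient, after approximating each coefficient by the best
#' rational with denominator at most `max_denominator` (continued-fraction
#' convergents; exact for coefficients that are ratios of small integers).
#' `L` is the least common multiple of the denominators.
#'
#' @param coefficients Numeric vector.
#' @param max_denominator Cap on the rational approximation denominator.
#' @return Positive integer-valued numeric scalar.
#' @examples
#' integer_scaling_factor(c(1.3, 3.2, 2.1))  # 10
#' integer_scaling_factor(c(0.5, 0.25))      # 4
#' @export
integer_scaling_factor <- function(coefficients, max_denominator = 1e6) {
  stopifnot(all(is.finite(coefficients)), max_denominator >= 1)
  L <- 1
  for (x in coefficients) {
    if (x == 0) next
    den <- rational_approx(x, max_denominator)[2]
    L <- lcm2(L, den)
    if (L > 2^52) {
      warning("integralizing scale factor exceeds exact double range; capped")
      return(L)
    }
  }
  L
}

epsilon_report <- function(S, L, epsilon, method, notes = character()) {
  structure(
    list(S = S, scaling_factor_L = L, epsilon = epsilon, method = method,
         notes = notes),
    class = "epsilon_report"
  )
}

#' @export
print.epsilon_report <- function(x, ...) {
  cat(sprintf("<epsilon_report> epsilon=%g (method=%s, S=%g, L=%g)\n",
              x$epsilon, x$method, x$S, x$scaling_factor_L))
  for (nt in x$notes) cat(" note:", nt, "\n")
  invisible(x)
}

finalize_epsilon <- function(S, L, method, safety = 1) {
  notes <- character()
  if (S <= 0) {
    return(epsilon_report(S, L, 0.01, "default",
                          "S = 0; fell back to the default radius 0.01"))
  }
  eps <- safety / (2 * S)
  if (L > 1) {
    notes <- c(notes, sprintf(
      "fractional coefficients (integralizing factor L = %g): the tie-gap guarantee formally holds for the x L rescaled objective, i.e. for the conservative radius epsilon / L = %g",
      L, eps / L))
  }
  if (eps < 1e-12) {
    warning("epsilon < 1e-12: solver numerics may swallow the perturbation; consider rescaling the objective coefficients")
    notes <- c(notes, "epsilon below 1e-12; coefficient rescaling recommended")
  }
  epsilon_report(S, L, eps, method, notes)
}

#' Choose the perturbation radius from variable bounds
#'
#' Applies the bound-based rule `epsilon = 1 / (2 S)` with `S` from
#' [weight_sum_S()]. The rule is scale-covariant: multiplying all objective
#' coefficients by `k > 0` divides epsilon by `k`. The integralizing factor
#' `L` from [integer_scaling_factor()] is reported alongside; when `L > 1`
#' the report notes the conservative radius `epsilon / L` under which the
#' tie-gap argument applies verbatim to the rescaled integral objective
#' (the multiplicative perturbation itself is invariant under that rescale).
#'
#' @param instance A [mip_instance()]; must pass [screen_instance()].
#' @param max_denominator Passed to [integer_scaling_factor()].
#' @return An `epsilon_report` with fields `S`, `scaling_factor_L`, `epsilon`,
#'   `method` (`"bounds"`, or `"default"` when `S = 0`), `notes`.
#' @examples
#' choose_epsilon(toy_fixtures()$eps_example)$epsilon       # 0.025
#' choose_epsilon(toy_fixtures()$eps_example_div5)$epsilon  # 0.125
#' @export
choose_epsilon <- function(instance, max_denominator = 1e6) {
  stopifnot(inherits(instance, "mip_instance"))
  if (screen_instance(instance) != "accept") {
    stop_morseopt("instance rejected by screening: no integral objective variable",
                  "morseopt_contract_error")
  }
  S <- weight_sum_S(instance)  # may signal morseopt_bounds_unavailable
  iv <- integral_objective_variables(instance)
  L <- integer_scaling_factor(instance$objective[iv], max_denominator)
  finalize_epsilon(S, L, "bounds")
}

#' Choose the perturbation radius from a reference solution
#'
#' Fallback for instances with unbounded variables: substitutes the absolute
#' values of a known optimal solution for `max(|lb|, |ub|)` in the weight sum,
#' giving `S' = sum(|c_i| * |x_i|)`, and returns
#' `epsilon = 0.999 / (2 S')`. The 0.999 safety factor enforces the strict
#' inequality the preservation argument requires (the reference solution
#' attains `S'` rather than merely bounding it).
#'
#' @param instance A [mip_instance()].
#' @param reference Named numeric vector: a feasible optimal solution.
#' @param max_denominator Passed to [integer_scaling_factor()].
#' @return An `epsilon_report` with `method = "reference_solution"` (or
#'   `"default"` when `S' = 0`).
#' @export
epsilon_from_reference_solution <- function(instance, reference,
                                            max_denominator = 1e6) {
  stopifnot(inherits(instance, "mip_instance"))
  vars <- instance$variables
  obj <- instance$objective
  idx <- match(names(obj), vars$name)
  missing_vars <- setdiff(names(obj), names(reference))
  if (length(missing_vars)) {
    stop_morseopt(paste("reference is missing objective variables:",
                        paste(missing_vars, collapse = ", ")),
                  "morseopt_contract_error")
  }
  xs <- abs(as.numeric(reference[names(obj)]))
  counted <- vars$vtype[idx] != "Continuous"
  Sp <- sum(abs(obj[counted]) * xs[counted])
  iv <- integral_objective_variables(instance)
  L <- integer_scaling_factor(instance$objective[iv], max_denominator)
  finalize_epsilon(Sp, L, "reference_solution", safety = 0.999)
}

# Full fallback chain: bounds -> reference solution (solving once) -> default.
resolve_epsilon <- function(instance, epsilon = NULL, backend = "bnb") {
  if (!is.null(epsilon)) {
    if (inherits(epsilon, "epsilon_report")) return(epsilon)
    return(epsilon_report(NA_real_, NA_real_, epsilon, "user"))
  }
  tryCatch(
    choose_epsilon(instance),
    morseopt_bounds_unavailable = function(e) {
      sol <- solve_to_optimality(instance, seed = 0L, backend = backend)
      if (sol$status != "optimal") {
        stop_morseopt(
          paste0("cannot derive epsilon: bounds unavailable and reference solve returned ",
                 sol$status),
          "morseopt_environment_error"
        )
      }
      epsilon_from_reference_solution(instance, sol$values)
    }
  )
}
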