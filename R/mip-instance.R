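#' Construct a mixed integer program instance
#'
#' The central data container of the package: a linear objective over named
#' variables, a sense, simple bounds with types per variable, and a system of
#' linear constraints. Binary variables are normalized internally to integer
#' variables with bounds clipped into `[0, 1]`; the declared type is retained
#' for reporting.
#'
#' @param name Instance identifier.
#' @param variables A `data.frame` with columns `name` (character), `vtype`
#'   (one of `"Binary"`, `"Integer"`, `"Continuous"`), `lb` and `ub` (numeric,
#'   may be `-Inf` / `Inf`).
#' @param objective Named numeric vector of objective coefficients; names must
#'   be declared variables. Variables absent from `objective` are
#'   constraint-only.
#' @param sense `"minimize"` or `"maximize"`.
#' @param constraints Either a list of objects built by [linear_constraint()],
#'   or a list with elements `A` (numeric matrix with column names matching
#'   variables), `sense` (character vector of `"<="`, `"="`, `">="`) and `rhs`
#'   (numeric vector).
#' @param constant Objective constant term, carried through evaluation but
#'   excluded from perturbation and from the epsilon rule (a constant cannot
#'   break ties).
#'
#' @return An object of class `mip_instance`.
#' @examples
#' toy <- mip_instance(
#'   name = "toy",
#'   variables = data.frame(
#'     name = c("x1", "x2"), vtype = "Integer", lb = 0, ub = 2
#'   ),
#'   objective = c(x1 = 1, x2 = 1),
#'   sense = "maximize",
#'   constraints = list(linear_constraint(c(x1 = 1, x2 = 1), "<=", 3.5))
#' )
#' screen_instance(toy)
#' @export
mip_instance <- function(name, variables, objective, sense = c("minimize", "maximize"),
                         constraints = list(), constant = 0) {
  sense <- match.arg(sense)
  stopifnot(is.data.frame(variables), nrow(variables) >= 1)
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  req <- c("name", "vtype", "lb", "ub")
  if (!all(req %in% names(variables))) {
    stop("`variables` must have columns name, vtype, lb, ub")
  }
  variables <- variables[, req]
  variables$name <- as.character(variables$name)
  variables$vtype <- as.character(variables$vtype)
  if (anyDuplicated(variables$name)) stop("duplicate variable names")
  if (!all(variables$vtype %in% c("Binary", "Integer", "Continuous"))) {
    stop("vtype must be Binary, Integer or Continuous")
  }
  # Binary normalization: integer behaviour on [0, 1]
  bin <- variables$vtype == "Binary"
  variables$lb[bin] <- pmax(variables$lb[bin], 0)
  variables$ub[bin] <- pmin(variables$ub[bin], 1)
  if (any(variables$lb > variables$ub)) {
    stop("variable with lb > ub: ",
         paste(variables$name[variables$lb > variables$ub], collapse = ", "))
  }

  objective <- unlist(objective)
  if (length(objective) && is.null(names(objective))) {
    stop("`objective` must be a named vector")
  }
  unknown <- setdiff(names(objective), variables$name)
  if (length(unknown)) {
    stop("objective references undeclared variables: ", paste(unknown, collapse = ", "))
  }

  cons <- canonicalize_constraints(constraints, variables$name)

  structure(
    list(
      name = as.character(name),
      variables = variables,
      objective = objective,
      sense = sense,
      constraints = cons,
      constant = constant
    ),
    class = "mip_instance"
  )
}

#' Build a single linear constraint
#'
#' @param coefficients Named numeric vector mapping variable names to
#'   coefficients.
#' @param sense One of `"<="`, `"="`, `">="`.
#' @param rhs Right-hand side value.
#' @param name Optional row name.
#' @return An object of class `linear_constraint`.
#' @export
linear_constraint <- function(coefficients, sense = c("<=", "=", ">="), rhs, name = NULL) {
  sense <- match.arg(sense)
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients))) stop("constraint coefficients must be named")
  structure(
    list(coefficients = coefficients, sense = sense, rhs = as.numeric(rhs),
         name = name),
    class = "linear_constraint"
  )
}

# Internal: accept either a list of linear_constraint objects or an
# A/sense/rhs triple and return the dense canonical form.
canonicalize_constraints <- function(constraints, var_names) {
  n <- length(var_names)
  if (is.list(constraints) && !is.null(constraints$A)) {
    A <- as.matrix(constraints$A)
    if (is.null(colnames(A))) {
      if (ncol(A) != n) stop("constraint matrix has wrong number of columns")
      colnames(A) <- var_names
    }
    unknown <- setdiff(colnames(A), var_names)
    if (length(unknown)) stop("constraints reference undeclared variables: ",
                              paste(unknown, collapse = ", "))
    full <- matrix(0, nrow(A), n, dimnames = list(rownames(A), var_names))
    full[, colnames(A)] <- A
    sense <- as.character(constraints$sense)
    rhs <- as.numeric(constraints$rhs)
    if (length(sense) != nrow(A) || length(rhs) != nrow(A)) {
      stop("constraint sense/rhs length mismatch")
    }
    if (!all(sense %in% c("<=", "=", ">="))) stop("constraint sense must be <=, = or >=")
    nm <- rownames(full) %||% paste0("c", seq_len(nrow(full)))
    return(list(A = unname(full), sense = sense, rhs = rhs, names = nm,
                var_names = var_names))
  }
  if (length(constraints) && !all(vapply(constraints, inherits, TRUE, "linear_constraint"))) {
    stop("`constraints` must be linear_constraint objects or an A/sense/rhs list")
  }
  m <- length(constraints)
  A <- matrix(0, m, n, dimnames = list(NULL, var_names))
  sense <- character(m)
  rhs <- numeric(m)
  nm <- character(m)
  for (i in seq_len(m)) {
    ci <- constraints[[i]]
    unknown <- setdiff(names(ci$coefficients), var_names)
    if (length(unknown)) stop("constraint references undeclared variables: ",
                              paste(unknown, collapse = ", "))
    A[i, names(ci$coefficients)] <- ci$coefficients
    sense[i] <- ci$sense
    rhs[i] <- ci$rhs
    nm[i] <- ci$name %||% paste0("c", i)
  }
  list(A = unname(A), sense = sense, rhs = rhs, names = nm, var_names = var_names)
}

#' @export
print.mip_instance <- function(x, ...) {
  nint <- sum(x$variables$vtype != "Continuous")
  cat(sprintf("<mip_instance> %s: %s, %d variables (%d integral), %d constraints\n",
              x$name, x$sense, nrow(x$variables), nint, length(x$constraints$rhs)))
  invisible(x)
}

# Variables appearing in the objective function with a nonzero coefficient.
# These are the variables over which solutions are compared and keys formed.
objective_variables <- function(instance) {
  obj <- instance$objective
  names(obj)[obj != 0]
}

# Objective variables that are Binary/Integer (the perturbation domain).
integral_objective_variables <- function(instance) {
  ov <- objective_variables(instance)
  vt <- instance$variables$vtype[match(ov, instance$variables$name)]
  ov[vt != "Continuous"]
}

has_continuous_variables <- function(instance) {
  any(instance$variables$vtype == "Continuous")
}

#' Screen an instance for applicability of objective perturbation
#'
#' The perturbation method only applies when the objective involves at least
#' one binary or integer variable (with a nonzero coefficient): perturbing a
#' purely continuous objective cannot break ties among lattice solutions, and
#' the preservation guarantee does not hold.
#'
#' @param instance A [mip_instance()].
#' @return `"accept"` or `"reject"`.
#' @export
screen_instance <- function(instance) {
  stopifnot(inherits(instance, "mip_instance"))
  if (length(integral_objective_variables(instance)) >= 1) "accept" else "reject"
}

#' Evaluate the objective function at an assignment
#'
#' @param instance A [mip_instance()].
#' @param assignment Named numeric vector covering at least all objective
#'   variables.
#' @param coefficients Optional alternative coefficient vector (e.g. a
#'   perturbed objective); defaults to the instance's own.
#' @return The objective value, including the instance's constant term.
#' @export
objective_value <- function(instance, assignment, coefficients = NULL) {
  stopifnot(inherits(instance, "mip_instance"))
  obj <- coefficients %||% instance$objective
  missing_vars <- setdiff(names(obj), names(assignment))
  if (length(missing_vars)) {
    stop_morseopt(
      paste("assignment is missing objective variables:",
            paste(missing_vars, collapse = ", ")),
      "morseopt_contract_error"
    )
  }
  sum(obj * assignment[names(obj)]) + instance$constant
}

#' Canonical solution key over objective-function variables
#'
#' Two solutions are distinct if and only if they differ, after rounding, in
#' at least one variable appearing in the objective function; constraint-only
#' variables are ignored. Binary/integer values are rounded to the nearest
#' integer, continuous objective variables to six decimals.
#'
#' @param instance A [mip_instance()].
#' @param solution A solver solution (list with `values`) or a named numeric
#'   vector of variable values.
#' @return A character scalar key; the corresponding numeric values are
#'   recoverable with [key_values()].
#' @export
solution_key <- function(instance, solution) {
  values <- if (is.list(solution)) solution$values else solution
  ov <- objective_variables(instance)
  missing_vars <- setdiff(ov, names(values))
  if (length(missing_vars)) {
    stop_morseopt(paste("solution is missing objective variables:",
                        paste(missing_vars, collapse = ", ")),
                  "morseopt_contract_error")
  }
  vt <- instance$variables$vtype[match(ov, instance$variables$name)]
  v <- as.numeric(values[ov])
  v[vt != "Continuous"] <- round(v[vt != "Continuous"])
  v[vt == "Continuous"] <- round(v[vt == "Continuous"], 6)
  paste(format(v, trim = TRUE, scientific = FALSE, digits = 15), collapse = ",")
}

#' Decode a solution key back to numeric values
#'
#' @param key Character key produced by [solution_key()].
#' @param instance The instance the key was formed on (fixes variable order).
#' @return Named numeric vector over the objective variables.
#' @export
key_values <- function(key, instance = NULL) {
  v <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
  if (!is.null(instance)) names(v) <- objective_variables(instance)
  v
}

# Rows of a key matrix: one row per key, columns = objective variables.
keys_to_matrix <- function(keys, instance = NULL) {
  if (!length(keys)) return(matrix(numeric(0), 0, 0))
  rows <- lapply(keys, function(k) as.numeric(strsplit(k, ",", fixed = TRUE)[[1]]))
  len <- unique(lengths(rows))
  if (length(len) != 1) {
    stop_morseopt("keys have differing lengths", "morseopt_contract_error")
  }
  m <- do.call(rbind, rows)
  if (!is.null(instance)) colnames(m) <- objective_variables(instance)
  m
}

#' Check feasibility of an assignment
#'
#' Verifies bounds, integrality of Binary/Integer variables, and every linear
#' constraint, each within `tol` scaled by the row magnitude.
#'
#' @param instance A [mip_instance()].
#' @param values Named numeric vector covering all variables.
#' @param tol Absolute feasibility tolerance (scaled by row magnitude).
#' @return Logical scalar.
#' @export
is_feasible <- function(instance, values, tol = 1e-6) {
  vars <- instance$variables
  if (!all(vars$name %in% names(values))) return(FALSE)
  v <- as.numeric(values[vars$name])
  if (any(v < vars$lb - tol) || any(v > vars$ub + tol)) return(FALSE)
  intmask <- vars$vtype != "Continuous"
  if (any(abs(v[intmask] - round(v[intmask])) > tol)) return(FALSE)
  cons <- instance$constraints
  if (length(cons$rhs)) {
    lhs <- as.numeric(cons$A %*% v)
    scale <- pmax(1, abs(cons$rhs))
    ok <- rep(TRUE, length(lhs))
    le <- cons$sense == "<="
    ge <- cons$sense == ">="
    eq <- cons$sense == "="
    ok[le] <- lhs[le] <= cons$rhs[le] + tol * scale[le]
    ok[ge] <- lhs[ge] >= cons$rhs[ge] - tol * scale[ge]
    ok[eq] <- abs(lhs[eq] - cons$rhs[eq]) <= tol * scale[eq]
    if (!all(ok)) return(FALSE)
  }
  TRUE
}
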