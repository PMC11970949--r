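# Ground truth: enumeration of *all* optima of an instance, by exhaustive
# lattice scan or by sequential no-good cuts, plus a goodness-of-fit test for
# the equal-probability property on selection problems.

new_optima_census <- function(optimal_value, keys, complete, feasible, strategy,
                              n_enumerated = NA_integer_) {
  structure(
    list(optimal_value = optimal_value, keys = keys, complete = complete,
         feasible = feasible, strategy = strategy, n_enumerated = n_enumerated),
    class = "optima_census"
  )
}

#' @export
print.optima_census <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<optima_census> infeasible (%s)\n", x$strategy))
  } else {
    cat(sprintf("<optima_census> optimal value %s, %d distinct optima (%s%s)\n",
                format(x$optimal_value), length(x$keys), x$strategy,
                if (x$complete) "" else ", INCOMPLETE"))
  }
  invisible(x)
}

#' Enumerate all optimal solutions of an instance
#'
#' Two strategies, which agree wherever both apply:
#' * `"exhaustive"` — scans every integer point of the bound box (all
#'   variables must be integral with finite bounds; the lattice size must not
#'   exceed `limit`), filters the feasible points and collects the full
#'   argmin/argmax set. Distinct optima are distinct keys over the
#'   objective-function variables.
#' * `"cuts"` — repeatedly solves the instance, records the optimum's key,
#'   and adds a no-good cut excluding exactly that key: the classical
#'   exclusion row for binary variables, and an exclusion via auxiliary
#'   deviation indicators for bounded general-integer variables. Stops when
#'   the augmented instance becomes infeasible or its optimal value degrades;
#'   if `limit` keys are found first, the census is flagged incomplete.
#'
#' @param instance A [mip_instance()] whose objective variables are all
#'   Binary/Integer.
#' @param limit For `"exhaustive"`: maximum lattice size; for `"cuts"`:
#'   maximum number of optima to enumerate.
#' @param strategy `"exhaustive"` or `"cuts"`.
#' @param tol Relative tolerance for identifying ties with the optimal value.
#' @return An object of class `optima_census`: `optimal_value`, `keys`
#'   (character, each a [solution_key()]), `complete`, `feasible`,
#'   `strategy`.
#' @examples
#' census <- enumerate_all_optima(toy_fixtures()$toy_2var)
#' census$optimal_value  # 3
#' census$keys           # the two tied optima
#' @export
enumerate_all_optima <- function(instance, limit = NULL,
                                 strategy = c("exhaustive", "cuts"),
                                 tol = 1e-9) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(instance, "mip_instance"))
  vars <- instance$variables
  ov <- objective_variables(instance)
  if (any(vars$vtype[match(ov, vars$name)] == "Continuous")) {
    stop_morseopt("enumeration requires all objective variables to be Binary/Integer",
                  "morseopt_unsupported_error")
  }
  if (strategy == "exhaustive") {
    enumerate_exhaustive(instance, limit %||% 1e7, tol)
  } else {
    enumerate_cuts(instance, limit %||% 10000L, tol)
  }
}

enumerate_exhaustive <- function(instance, limit, tol) {
  vars <- instance$variables
  if (any(vars$vtype == "Continuous")) {
    stop_morseopt("exhaustive enumeration requires a pure-integer instance",
                  "morseopt_unsupported_error")
  }
  if (any(!is.finite(vars$lb)) || any(!is.finite(vars$ub))) {
    stop_morseopt("exhaustive enumeration requires finite bounds",
                  "morseopt_unsupported_error")
  }
  lb <- round(vars$lb); ub <- round(vars$ub)
  sizes <- ub - lb + 1
  total <- prod(sizes)
  if (total > limit) {
    stop_morseopt(sprintf("lattice size %g exceeds limit %g", total, limit),
                  "morseopt_unsupported_error")
  }
  n <- nrow(vars)
  stride <- cumprod(c(1, sizes[-n]))
  mat <- instance_matrices(instance)
  minimize <- !mat$maximize

  best <- Inf
  best_rows <- list()
  chunk <- 65536L
  start <- 0
  while (start < total) {
    idx <- start + seq_len(min(chunk, total - start)) - 1
    X <- vapply(seq_len(n), function(j) lb[j] + (idx %/% stride[j]) %% sizes[j],
                numeric(length(idx)))
    if (!is.matrix(X)) X <- matrix(X, nrow = 1)
    feas <- rep(TRUE, nrow(X))
    if (length(mat$rhs)) {
      lhs <- X %*% t(mat$A)
      scale <- pmax(1, abs(mat$rhs))
      for (i in seq_along(mat$rhs)) {
        feas <- feas & switch(mat$sense[i],
          "<=" = lhs[, i] <= mat$rhs[i] + tol * scale[i],
          ">=" = lhs[, i] >= mat$rhs[i] - tol * scale[i],
          "="  = abs(lhs[, i] - mat$rhs[i]) <= tol * scale[i])
      }
    }
    if (any(feas)) {
      Xf <- X[feas, , drop = FALSE]
      val <- as.numeric(Xf %*% mat$c)
      if (!minimize) val <- -val
      vmin <- min(val)
      gap <- tol * max(1, abs(vmin))
      if (vmin < best - gap) {
        best <- vmin
        best_rows <- list(Xf[val <= vmin + gap, , drop = FALSE])
      } else if (vmin <= best + gap) {
        best_rows <- c(best_rows, list(Xf[val <= best + gap, , drop = FALSE]))
      }
    }
    start <- start + chunk
  }
  if (!is.finite(best)) {
    return(new_optima_census(NA_real_, character(0), TRUE, FALSE, "exhaustive",
                             as.integer(total)))
  }
  rows <- do.call(rbind, best_rows)
  colnames(rows) <- vars$name
  keys <- unique(apply(rows, 1, function(r) solution_key(instance, r)))
  value <- (if (!minimize) -best else best) + instance$constant
  new_optima_census(value, keys, TRUE, TRUE, "exhaustive", as.integer(total))
}

# One no-good cut system excluding exactly the assignments whose objective
# variables equal `vals`. Binary variables enter the exclusion row directly;
# general integers via auxiliary "deviate up"/"deviate down" binaries.
nogood_augment <- function(work, instance, vals, cut_id) {
  vars <- work$variables
  ov <- names(vals)
  idx <- match(ov, vars$name)
  main_coefs <- numeric(0); main_nm <- character(0)
  rhs_main <- 1
  extra_vars <- list()
  side <- list()  # each: list(coefs (named), sense, rhs)
  for (k in seq_along(ov)) {
    v <- vals[k]
    lbk <- vars$lb[idx[k]]; ubk <- vars$ub[idx[k]]
    if (lbk == 0 && ubk == 1) {
      if (v >= 0.5) {
        main_coefs <- c(main_coefs, -1); main_nm <- c(main_nm, ov[k])
        rhs_main <- rhs_main - 1
      } else {
        main_coefs <- c(main_coefs, 1); main_nm <- c(main_nm, ov[k])
      }
    } else {
      if (v < ubk) {  # deviation upward possible
        d <- sprintf(".ng%d_%s_up", cut_id, ov[k])
        extra_vars[[length(extra_vars) + 1]] <-
          data.frame(name = d, vtype = "Binary", lb = 0, ub = 1)
        side[[length(side) + 1]] <- list(
          coefs = stats::setNames(c(1, -(v + 1 - lbk)), c(ov[k], d)),
          sense = ">=", rhs = lbk)
        main_coefs <- c(main_coefs, 1); main_nm <- c(main_nm, d)
      }
      if (v > lbk) {  # deviation downward possible
        d <- sprintf(".ng%d_%s_dn", cut_id, ov[k])
        extra_vars[[length(extra_vars) + 1]] <-
          data.frame(name = d, vtype = "Binary", lb = 0, ub = 1)
        side[[length(side) + 1]] <- list(
          coefs = stats::setNames(c(1, ubk - v + 1), c(ov[k], d)),
          sense = "<=", rhs = ubk)
        main_coefs <- c(main_coefs, 1); main_nm <- c(main_nm, d)
      }
    }
  }
  new_vars <- rbind(work$variables, do.call(rbind, extra_vars))
  nvar <- nrow(new_vars)
  cons <- work$constraints
  m_old <- length(cons$rhs)
  m_new <- m_old + length(side) + 1L
  A <- matrix(0, m_new, nvar, dimnames = list(NULL, new_vars$name))
  if (m_old) A[seq_len(m_old), cons$var_names] <- cons$A
  sense <- c(cons$sense, vapply(side, `[[`, character(1), "sense"), ">=")
  rhs <- c(cons$rhs, vapply(side, function(s) s$rhs, numeric(1)), rhs_main)
  for (i in seq_along(side)) {
    A[m_old + i, names(side[[i]]$coefs)] <- side[[i]]$coefs
  }
  if (length(main_coefs)) A[m_new, main_nm] <- main_coefs
  # (a key with no possible deviation yields the infeasible row 0 >= 1)
  mip_instance(work$name, new_vars, work$objective, work$sense,
               list(A = A, sense = sense, rhs = rhs), work$constant)
}

enumerate_cuts <- function(instance, limit, tol) {
  work <- instance
  keys <- character(0)
  zstar <- NA_real_
  for (i in seq_len(limit)) {
    sol <- solve_to_optimality(work, seed = 0L)
    if (sol$status == "infeasible") {
      return(new_optima_census(zstar, keys, TRUE, length(keys) > 0, "cuts",
                               length(keys)))
    }
    if (sol$status != "optimal") {
      stop_morseopt(paste0("cut enumeration: solver returned ", sol$status),
                    "morseopt_environment_error")
    }
    val <- objective_value(instance, sol$values)
    if (is.na(zstar)) {
      zstar <- val
    } else {
      degraded <- if (instance$sense == "minimize") {
        val > zstar + tol * max(1, abs(zstar)) + 1e-7
      } else {
        val < zstar - tol * max(1, abs(zstar)) - 1e-7
      }
      if (degraded) {
        return(new_optima_census(zstar, keys, TRUE, TRUE, "cuts", length(keys)))
      }
    }
    key <- solution_key(instance, sol$values)
    if (key %in% keys) {
      warning("cut enumeration revisited a key; stopping (numerical issue)")
      return(new_optima_census(zstar, keys, FALSE, TRUE, "cuts", length(keys)))
    }
    keys <- c(keys, key)
    vals <- key_values(key, instance)
    work <- nogood_augment(work, instance, vals, i)
  }
  new_optima_census(zstar, keys, FALSE, length(keys) > 0, "cuts", length(keys))
}

#' Chi-squared test of uniformity over observed optima
#'
#' Pearson goodness-of-fit statistic of observed optimum counts against the
#' uniform distribution over the given keys (the equal-probability property
#' that holds for unit-coefficient selection problems). Wraps
#' [stats::chisq.test()]; degrees of freedom are one less than the number of
#' keys.
#'
#' @param counts Nonnegative integer vector (optionally named by key), one
#'   entry per distinct optimum, length at least 2.
#' @return List with `statistic`, `dof` and `p_value`.
#' @examples
#' uniformity_chisq(c(30, 10))  # statistic 10, dof 1
#' @export
uniformity_chisq <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) < 2) {
    stop_morseopt("uniformity test needs at least 2 keys", "morseopt_contract_error")
  }
  stopifnot(all(counts >= 0), sum(counts) > 0)
  if (sum(counts) / length(counts) < 5) {
    warning("expected count per cell below 5; chi-squared approximation is unreliable")
  }
  ht <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
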