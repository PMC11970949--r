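# Linear and mixed-integer solving.
#
# No LP/MIP solver backend ships with this package's dependency set, so the
# package carries its own: a dense two-phase tableau simplex with general
# variable bounds, and a depth-first branch-and-bound on top of it. Both are
# written for the moderate instance sizes this package targets (tens of
# variables and rows); correctness over speed, with anti-cycling via a Bland
# rule fallback. The solver adapter surface (`backend` argument, recorded in
# every run record) leaves room for external solvers to be plugged in.

# Solve min/max obj'x  s.t.  A x (sense) rhs,  lb <= x <= ub.
# Returns list(status, x, value) with status one of
# "optimal", "infeasible", "unbounded", "iteration_limit".
lp_simplex <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE,
                       tol = 1e-9, max_iter = NULL) {
  n0 <- length(obj)
  if (is.null(A)) A <- matrix(0, 0, n0)
  if (!is.matrix(A)) A <- matrix(A, ncol = n0)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  cmin <- if (maximize) -obj else obj

  # --- transform every variable to y >= 0 ---------------------------------
  # shift  (finite lb):        x = lb + y,  y in [0, ub - lb]
  # mirror (lb = -Inf, ub fin): x = ub - y,  y in [0, Inf)
  # split  (free):              x = y1 - y2
  Acols <- vector("list", 2L * n0)
  cvec <- numeric(2L * n0)
  ubp <- numeric(2L * n0)
  map_var <- integer(2L * n0)
  map_sign <- numeric(2L * n0)
  map_off <- numeric(2L * n0)
  k <- 0L
  b2 <- rhs
  for (j in seq_len(n0)) {
    aj <- A[, j]
    if (is.finite(lb[j])) {
      k <- k + 1L
      b2 <- b2 - aj * lb[j]
      Acols[[k]] <- aj; cvec[k] <- cmin[j]
      ubp[k] <- ub[j] - lb[j]
      map_var[k] <- j; map_sign[k] <- 1; map_off[k] <- lb[j]
    } else if (is.finite(ub[j])) {
      k <- k + 1L
      b2 <- b2 - aj * ub[j]
      Acols[[k]] <- -aj; cvec[k] <- -cmin[j]
      ubp[k] <- Inf
      map_var[k] <- j; map_sign[k] <- -1; map_off[k] <- ub[j]
    } else {
      k <- k + 1L
      Acols[[k]] <- aj; cvec[k] <- cmin[j]; ubp[k] <- Inf
      map_var[k] <- j; map_sign[k] <- 1; map_off[k] <- 0
      k <- k + 1L
      Acols[[k]] <- -aj; cvec[k] <- -cmin[j]; ubp[k] <- Inf
      map_var[k] <- j; map_sign[k] <- -1; map_off[k] <- 0
    }
  }
  n <- k
  Acols <- Acols[seq_len(n)]
  cvec <- cvec[seq_len(n)]; ubp <- ubp[seq_len(n)]
  map_var <- map_var[seq_len(n)]; map_sign <- map_sign[seq_len(n)]
  map_off <- map_off[seq_len(n)]

  A2 <- if (nrow(A)) do.call(cbind, Acols) else matrix(0, 0, n)
  s2 <- sense
  # upper bounds as explicit rows
  for (q in which(is.finite(ubp))) {
    row <- numeric(n); row[q] <- 1
    A2 <- rbind(A2, row, deparse.level = 0)
    b2 <- c(b2, ubp[q])
    s2 <- c(s2, "<=")
  }
  m <- nrow(A2)

  finish <- function(y) {
    x <- numeric(n0)
    for (q in seq_len(n)) x[map_var[q]] <- x[map_var[q]] + map_sign[q] * y[q]
    x <- x + {
      off <- numeric(n0)
      first <- !duplicated(map_var)
      off[map_var[first]] <- map_off[first]
      off
    }
    list(status = "optimal", x = x, value = sum(obj * x))
  }

  if (m == 0L) {
    # unconstrained over y >= 0
    if (any(cvec < -tol)) return(list(status = "unbounded", x = NULL, value = NA_real_))
    return(finish(numeric(n)))
  }

  # --- equality form with slack/surplus ------------------------------------
  ns <- sum(s2 != "=")
  S <- matrix(0, m, ns)
  si <- 0L
  for (i in seq_len(m)) {
    if (s2[i] == "<=") { si <- si + 1L; S[i, si] <- 1 }
    else if (s2[i] == ">=") { si <- si + 1L; S[i, si] <- -1 }
  }
  Aeq <- cbind(A2, S)
  beq <- b2
  neg <- beq < 0
  if (any(neg)) {
    Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
  }
  ntot <- ncol(Aeq)

  # --- tableau with artificial basis ---------------------------------------
  Tm <- cbind(Aeq, diag(m), beq)
  basis <- ntot + seq_len(m)
  last <- ntot + m + 1L
  if (is.null(max_iter)) max_iter <- 200L * (m + ntot) + 500L
  bland_after <- 20L * (m + ntot) + 50L

  pivot <- function(i, j) {
    Tm[i, ] <<- Tm[i, ] / Tm[i, j]
    fac <- Tm[, j]
    fac[i] <- 0
    nz <- which(abs(fac) > 0)
    if (length(nz)) Tm[nz, ] <<- Tm[nz, ] - outer(fac[nz], Tm[i, ])
    Tm[abs(Tm) < 1e-11] <<- 0
    basis[i] <<- j
  }

  run_phase <- function(cost, eligible) {
    # cost: length last vector (reduced-cost row, priced out by caller)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(code = "iteration_limit", cost = cost))
      rc <- cost[seq_len(ntot + m)]
      rc[!eligible] <- Inf
      if (iter <= bland_after) {
        j <- which.min(rc)
        if (rc[j] >= -tol) return(list(code = "optimal", cost = cost))
      } else {
        cand <- which(rc < -tol)
        if (!length(cand)) return(list(code = "optimal", cost = cost))
        j <- cand[1L]
      }
      colj <- Tm[, j]
      pos <- which(colj > tol)
      if (!length(pos)) return(list(code = "unbounded", cost = cost))
      theta <- Tm[pos, last] / colj[pos]
      tmin <- min(theta)
      tie <- pos[theta <= tmin + 1e-12]
      i <- tie[which.min(basis[tie])]
      pivot(i, j)
      cost <- cost - cost[j] * Tm[i, ]
    }
  }

  # phase 1: minimize sum of artificials
  cost1 <- c(numeric(ntot), rep(1, m), 0)
  cost1 <- cost1 - colSums(Tm)
  elig1 <- rep(TRUE, ntot + m)
  ph1 <- run_phase(cost1, elig1)
  if (ph1$code == "iteration_limit") {
    return(list(status = "iteration_limit", x = NULL, value = NA_real_))
  }
  feas_tol <- 1e-7 * max(1, max(abs(beq)))
  phase1_obj <- -ph1$cost[last]
  if (phase1_obj > feas_tol) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # drive artificials out of the basis where possible
  for (i in which(basis > ntot)) {
    jj <- which(abs(Tm[i, seq_len(ntot)]) > 1e-7)
    if (length(jj)) pivot(i, jj[1L])
  }

  # phase 2
  cext <- c(cvec, numeric(ns + m))
  cost2 <- c(cext, 0)
  for (i in seq_len(m)) {
    cb <- cext[basis[i]]
    if (cb != 0) cost2 <- cost2 - cb * Tm[i, ]
  }
  elig2 <- c(rep(TRUE, ntot), rep(FALSE, m))
  ph2 <- run_phase(cost2, elig2)
  if (ph2$code == "iteration_limit") {
    return(list(status = "iteration_limit", x = NULL, value = NA_real_))
  }
  if (ph2$code == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  y <- numeric(ntot + m)
  y[basis] <- Tm[, last]
  finish(y[seq_len(n)])
}

# Dense matrix view of an instance for the solver.
instance_matrices <- function(instance) {
  vars <- instance$variables
  n <- nrow(vars)
  cfull <- numeric(n)
  names(cfull) <- vars$name
  cfull[names(instance$objective)] <- instance$objective
  list(
    c = unname(cfull),
    A = instance$constraints$A,
    sense = instance$constraints$sense,
    rhs = instance$constraints$rhs,
    lb = vars$lb,
    ub = vars$ub,
    int = vars$vtype != "Continuous",
    names = vars$name,
    maximize = instance$sense == "maximize"
  )
}

# Branch-and-bound over the LP relaxation. The seed randomizes branching
# tie-breaks and child exploration order; with tied integer optima this is
# what lets repeated solves with different seeds surface different optima
# (the role the random generator seed plays in commercial solvers).
bnb_solve <- function(instance, seed = 0L, node_limit = 100000L, int_tol = 1e-6) {
  mat <- instance_matrices(instance)
  n <- length(mat$c)
  cmin <- if (mat$maximize) -mat$c else mat$c
  intmask <- mat$int

  result <- with_seed(seed, {
    priority <- stats::runif(n)
    stack <- list(list(lb = mat$lb, ub = mat$ub))
    best <- NULL
    bestval <- Inf
    nodes <- 0L
    status <- NULL
    while (length(stack)) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nodes <- nodes + 1L
      if (nodes > node_limit) { status <- "node_limit"; break }
      res <- lp_simplex(cmin, mat$A, mat$sense, mat$rhs, node$lb, node$ub)
      if (res$status == "infeasible") next
      if (res$status == "unbounded") { status <- "unbounded"; break }
      if (res$status != "optimal") { status <- res$status; break }
      if (is.finite(bestval) &&
          res$value >= bestval - 1e-9 * max(1, abs(bestval))) next
      xi <- res$x
      frac <- abs(xi - round(xi))
      frac[!intmask] <- 0
      if (max(frac) <= int_tol) {
        xr <- xi
        xr[intmask] <- round(xr[intmask])
        val <- sum(cmin * xr)
        if (val < bestval - 1e-12) { best <- xr; bestval <- val }
        next
      }
      cand <- which(frac > int_tol)
      j <- cand[which.max(frac[cand] + 1e-6 * priority[cand])]
      down <- node; down$ub[j] <- floor(xi[j])
      up <- node; up$lb[j] <- floor(xi[j]) + 1
      if (stats::runif(1) < 0.5) {
        stack[c(length(stack) + 1L, length(stack) + 2L)] <- list(down, up)
      } else {
        stack[c(length(stack) + 1L, length(stack) + 2L)] <- list(up, down)
      }
    }
    list(best = best, bestval = bestval, status = status, nodes = nodes)
  })

  if (!is.null(result$status)) {
    return(structure(list(values = NULL, objective_value = NA_real_,
                          status = if (result$status == "unbounded") "unbounded" else "error",
                          detail = result$status, nodes = result$nodes),
                     class = "mip_solution"))
  }
  if (is.null(result$best)) {
    return(structure(list(values = NULL, objective_value = NA_real_,
                          status = "infeasible", nodes = result$nodes),
                     class = "mip_solution"))
  }
  values <- result$best
  names(values) <- mat$names
  obj <- sum(mat$c * result$best) + instance$constant
  structure(list(values = values, objective_value = obj, status = "optimal",
                 nodes = result$nodes),
            class = "mip_solution")
}

#' Solve an instance to proven optimality
#'
#' Dispatches to a solver backend. The built-in backend, `"bnb"`, is a
#' depth-first branch-and-bound over a two-phase simplex relaxation; it proves
#' optimality by exhausting the search tree. For a fixed backend, seed and
#' instance the returned solution is reproducible; the seed only influences
#' which of several tied optimal solutions is returned.
#'
#' @param instance A [mip_instance()].
#' @param seed Integer backend seed (tie-breaking randomness).
#' @param backend Backend identifier; `"bnb"` is the only built-in backend.
#' @param node_limit Maximum number of branch-and-bound nodes.
#' @return An object of class `mip_solution`: `values` (named vector over all
#'   variables), `objective_value` (in the instance's own sense, including any
#'   constant term), and `status` (`"optimal"`, `"infeasible"`, `"unbounded"`
#'   or `"error"`).
#' @examples
#' toy <- toy_fixtures()$toy_2var
#' solve_to_optimality(toy, seed = 1)
#' @export
solve_to_optimality <- function(instance, seed = 0L, backend = "bnb",
                                node_limit = 100000L) {
  stopifnot(inherits(instance, "mip_instance"))
  if (backend != "bnb") {
    stop_morseopt(paste0("unknown solver backend: ", backend),
                  "morseopt_environment_error")
  }
  sol <- bnb_solve(instance, seed = seed, node_limit = node_limit)
  sol$backend <- backend
  sol$seed <- as.integer(seed)
  sol
}

#' @export
print.mip_solution <- function(x, ...) {
  cat(sprintf("<mip_solution> status=%s objective=%s (%d nodes)\n",
              x$status,
              if (is.na(x$objective_value)) "NA" else format(x$objective_value),
              x$nodes %||% NA_integer_))
  invisible(x)
}
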