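# The LP simplex and branch-and-bound engine, cross-validated against
# independent references: boot's textbook simplex on configurations where it
# is sound, exhaustive lattice enumeration, and (in one batched call) the
# HiGHS solver behind scipy.optimize.milp.

lp <- function(...) morseopt:::lp_simplex(...)

test_that("the LP engine handles bound transforms, equalities and statuses", {
  # box with negative lower bounds, no rows
  r <- lp(c(2, 3, 1), NULL, character(0), numeric(0),
          lb = c(-2, 1, -4), ub = c(1, 4, 2))
  expect_identical(r$status, "optimal")
  expect_equal(r$x, c(-2, 1, -4))
  expect_equal(r$value, -5)

  # fractional vertex
  r <- lp(c(1, 1), matrix(c(1, 1), 1, 2), "<=", 3.5, c(0, 0), c(2, 2),
          maximize = TRUE)
  expect_equal(r$value, 3.5)

  # equality-only system
  r <- lp(c(1, 2), matrix(c(1, 1), 1, 2), "=", 2, c(0, 0), c(Inf, Inf))
  expect_equal(r$value, 2)
  expect_equal(r$x, c(2, 0))

  # free variable
  r <- lp(c(1, 0), rbind(c(1, 1)), "=", 3, c(-Inf, 0), c(Inf, 1))
  expect_equal(r$x, c(2, 1))

  # infeasible and unbounded
  expect_identical(lp(c(1), matrix(1, 1, 1), ">=", 2, 0, 1)$status, "infeasible")
  expect_identical(lp(c(1), matrix(1, 1, 1), ">=", 0, 0, Inf, maximize = TRUE)$status,
                   "unbounded")
})

test_that("the LP engine agrees with boot's simplex on random nonnegative LPs", {
  skip_if_not_installed("boot")
  set.seed(41)
  checked <- 0
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:4, 1)
    A1 <- matrix(round(runif(m * n, 0.1, 3), 2), m, n)
    b1 <- round(runif(m, 1, 8), 2)
    a <- round(runif(n, 0.1, 2), 2)
    maxi <- runif(1) < 0.5
    # boot::simplex solves a'x with A1 x <= b1, x >= 0 (b1 >= 0): bounded,
    # feasible at the origin -- the configuration where it is sound
    ref <- boot::simplex(a = a, A1 = A1, b1 = b1, maxi = maxi)
    if (ref$solved != 1) next
    mine <- lp(a, A1, rep("<=", m), b1, rep(0, n), rep(Inf, n), maximize = maxi)
    expect_identical(mine$status, "optimal")
    expect_equal(mine$value, unname(ref$value), tolerance = 1e-7)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("branch-and-bound matches exhaustive enumeration on random ILPs", {
  for (i in 1:40) {
    inst <- mk_random_integer_instance(1000 + i)
    cen <- enumerate_all_optima(inst, strategy = "exhaustive")
    sol <- solve_to_optimality(inst, seed = i)
    if (!cen$feasible) {
      expect_identical(sol$status, "infeasible")
    } else {
      expect_identical(sol$status, "optimal")
      expect_equal(sol$objective_value, cen$optimal_value, tolerance = 1e-9)
      expect_true(solution_key(inst, sol) %in% cen$keys)
      expect_true(is_feasible(inst, sol$values))
    }
  }
})

test_that("branch-and-bound agrees with scipy's HiGHS MILP on mixed instances", {
  # one batched call to the python interpreter that ships in this
  # environment; an independent, widely trusted reference implementation
  python <- Sys.which("python")
  skip_if(python == "", "python not on PATH")
  set.seed(43)
  cases <- list()
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(1:4, 1)
    A <- matrix(sample(-3:3, m * n, replace = TRUE), m, n)
    sense <- sample(c("<=", ">="), m, replace = TRUE)
    ubv <- sample(1:3, n, replace = TRUE)
    x0 <- vapply(seq_len(n), function(j) sample(0:ubv[j], 1), numeric(1))
    rhs <- as.numeric(A %*% x0) +
      ifelse(sense == "<=", sample(0:2, m, TRUE), -sample(0:2, m, TRUE))
    obj <- sample(-4:4, n, replace = TRUE)
    vt <- sample(c("Integer", "Continuous"), n, replace = TRUE, prob = c(.75, .25))
    nm <- paste0("x", seq_len(n))
    inst <- mip_instance(paste0("xv", i),
      data.frame(name = nm, vtype = vt, lb = 0, ub = ubv),
      stats::setNames(obj, nm),
      sample(c("minimize", "maximize"), 1),
      list(A = A, sense = sense, rhs = rhs))
    sol <- solve_to_optimality(inst, seed = i)
    cases[[i]] <- list(
      obj = as.list(obj), A = apply(A, 1, as.list, simplify = FALSE),
      sense = as.list(sense), rhs = as.list(rhs), ub = as.list(ubv),
      integrality = as.list(as.integer(vt == "Integer")),
      maxi = inst$sense == "maximize",
      mine = if (sol$status == "optimal") sol$objective_value else sol$status
    )
  }
  case_file <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cases, case_file, digits = NA, auto_unbox = TRUE)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
cases = json.load(open(sys.argv[1]))
out = []
for c in cases:
    A = np.array(c["A"], dtype=float)
    rhs = np.array(c["rhs"], dtype=float)
    lo = np.where(np.array(c["sense"]) == "<=", -np.inf, rhs)
    hi = np.where(np.array(c["sense"]) == "<=", rhs, np.inf)
    sign = -1.0 if c["maxi"] else 1.0
    r = milp(sign * np.array(c["obj"], dtype=float),
             constraints=LinearConstraint(A, lo, hi),
             bounds=Bounds(np.zeros(len(c["obj"])), np.array(c["ub"], dtype=float)),
             integrality=np.array(c["integrality"]))
    out.append(sign * r.fun if r.status == 0 else ("infeasible" if r.status == 2 else "other"))
print(json.dumps(out))
'
  script_file <- withr::local_tempfile(fileext = ".py")
  writeLines(script, script_file)
  ref <- jsonlite::fromJSON(
    system2(python, c(script_file, case_file), stdout = TRUE),
    simplifyVector = FALSE
  )
  for (i in seq_along(cases)) {
    mine <- cases[[i]]$mine
    if (is.character(mine) || is.character(ref[[i]])) {
      expect_identical(as.character(mine), as.character(ref[[i]]))
    } else {
      expect_equal(mine, ref[[i]], tolerance = 1e-7)
    }
  }
})

test_that("solves are reproducible for a fixed seed and vary across seeds on ties", {
  toy <- toy2()
  s1 <- solve_to_optimality(toy, seed = 7)
  s2 <- solve_to_optimality(toy, seed = 7)
  expect_identical(s1$values, s2$values)
  # both tied optima appear across seeds
  keys <- vapply(1:30, function(s) solution_key(toy, solve_to_optimality(toy, seed = s)),
                 character(1))
  expect_setequal(unique(keys), c("1,2", "2,1"))
})

test_that("infeasible and unbounded instances are diagnosed", {
  bad <- mip_instance("bad",
    data.frame(name = "x", vtype = "Integer", lb = 0, ub = 10),
    c(x = 1), "minimize",
    list(linear_constraint(c(x = 1), ">=", 2),
         linear_constraint(c(x = 1), "<=", 1)))
  expect_identical(solve_to_optimality(bad)$status, "infeasible")

  unb <- mip_instance("unb",
    data.frame(name = "x", vtype = "Integer", lb = 0, ub = Inf),
    c(x = 1), "maximize")
  expect_identical(solve_to_optimality(unb)$status, "unbounded")
})

test_that("unknown backends raise an environment error", {
  expect_error(solve_to_optimality(toy2(), backend = "gurobi"),
               class = "morseopt_environment_error")
})
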