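# All-optima enumeration (exhaustive and cut-based), the uniformity test,
# and the synthetic instance generators.

test_that("the two-variable toy has optimal value 3 and exactly two optima", {
  cen <- enumerate_all_optima(toy2(), strategy = "exhaustive")
  expect_true(cen$feasible)
  expect_true(cen$complete)
  expect_equal(cen$optimal_value, 3)
  expect_setequal(cen$keys, c("1,2", "2,1"))
})

test_that("a unique optimum yields a single key", {
  inst <- mip_instance("uniq",
    data.frame(name = "x", vtype = "Integer", lb = 0, ub = 5),
    c(x = 1), "maximize")
  for (strat in c("exhaustive", "cuts")) {
    cen <- enumerate_all_optima(inst, strategy = strat)
    expect_identical(cen$keys, "5")
    expect_equal(cen$optimal_value, 5)
  }
})

test_that("cut-based and exhaustive censuses agree across a mixed corpus", {
  corpus <- c(
    list(toy2(), generate_selection_instance(8, 5, 0.3, 2),
         generate_selection_instance(6, 6, 0.4, 7)),
    lapply(4000 + (1:12), mk_random_integer_instance)
  )
  for (inst in corpus) {
    ex <- enumerate_all_optima(inst, strategy = "exhaustive")
    cu <- enumerate_all_optima(inst, strategy = "cuts")
    expect_identical(cu$feasible, ex$feasible)
    if (!ex$feasible) next
    expect_true(cu$complete)
    expect_equal(cu$optimal_value, ex$optimal_value, tolerance = 1e-9)
    expect_setequal(cu$keys, ex$keys)
  }
})

test_that("enumeration flags unsupported and infeasible inputs", {
  cont <- mip_instance("cont",
    data.frame(name = "w", vtype = "Continuous", lb = 0, ub = 1),
    c(w = 1), "minimize")
  expect_error(enumerate_all_optima(cont), class = "morseopt_unsupported_error")

  big <- mip_instance("big",
    data.frame(name = paste0("x", 1:8), vtype = "Integer", lb = 0, ub = 9),
    stats::setNames(rep(1, 8), paste0("x", 1:8)), "minimize")
  expect_error(enumerate_all_optima(big, limit = 1e4),
               class = "morseopt_unsupported_error")

  # covering family containing an empty set: unsatisfiable constraint
  nm <- c("e1", "e2")
  infeas <- mip_instance("empty_set",
    data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(c(1, 1), nm), "minimize",
    list(A = rbind(c(1, 1), c(0, 0)), sense = c(">=", ">="), rhs = c(1, 1)))
  for (strat in c("exhaustive", "cuts")) {
    cen <- enumerate_all_optima(infeas, strategy = strat)
    expect_false(cen$feasible)
    expect_length(cen$keys, 0)
  }
})

test_that("the uniformity statistic is the Pearson goodness-of-fit statistic", {
  r <- uniformity_chisq(c(10, 10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$dof, 2)
  r <- uniformity_chisq(c(30, 10))
  expect_equal(r$statistic, 10)  # (30-20)^2/20 + (10-20)^2/20
  expect_equal(r$dof, 1)
  for (k in 2:6) {
    expect_equal(uniformity_chisq(rep(10, k))$dof, k - 1)
  }
  expect_error(uniformity_chisq(c(5)), class = "morseopt_contract_error")
  expect_warning(uniformity_chisq(c(3, 2)), "below 5")
})

test_that("selection instances have the hand-checkable optima", {
  # sets {1,2} and {1,3}: unique minimum hitting set {1}
  nm <- paste0("e", 1:3)
  inst <- mip_instance("hs1",
    data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(rep(1, 3), nm), "minimize",
    list(A = rbind(c(1, 1, 0), c(1, 0, 1)), sense = c(">=", ">="), rhs = c(1, 1)))
  cen <- enumerate_all_optima(inst)
  expect_identical(cen$keys, "1,0,0")
  expect_equal(cen$optimal_value, 1)

  # single set {1,2}: two optima
  cen2 <- enumerate_all_optima(mk_singleton_optima_instance(2))
  expect_setequal(cen2$keys, c("1,0", "0,1"))
})

test_that("asymmetrically overlapping optima are sampled with provably unequal probabilities", {
  # The equal-probability property holds when the optimal-set system is
  # exchangeable. It fails for overlapping optima: with covering sets
  # {e1,e2}, {e3,e4}, {e1,e4}, the minimum hitting sets are exactly
  # {e1,e3}, {e1,e4}, {e2,e4}, and the probability that each minimizes the
  # sum of its i.i.d. uniformly perturbed coefficients is 3/8, 1/4, 3/8
  # (exact, by integrating the pairwise comparisons: {e1,e4} wins iff
  # p4 < p3 and p1 < p2, two independent events of probability 1/2).
  nm <- paste0("e", 1:4)
  inst <- mip_instance("overlap",
    data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(rep(1, 4), nm), "minimize",
    list(A = rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 0, 1)),
         sense = rep(">=", 3), rhs = rep(1, 3)))
  cen <- enumerate_all_optima(inst)
  expect_setequal(cen$keys, c("1,0,1,0", "1,0,0,1", "0,1,0,1"))
  b <- run_batch(inst, seeds = 0:1199, mode = "morse")
  counts <- table(factor(b$keys, levels = c("1,0,1,0", "1,0,0,1", "0,1,0,1")))
  expect_identical(sum(counts), 1200L)
  # consistent with the exact probabilities ...
  exact <- c(3, 2, 3) / 8
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts), p = exact))
  expect_gt(gof$p.value, 0.001)
  # ... and decisively inconsistent with uniform sampling
  expect_lt(uniformity_chisq(as.numeric(counts))$p_value, 0.001)
})

test_that("the selection generator is reproducible and never emits empty sets", {
  a <- generate_selection_instance(10, 8, 0.15, 99)
  b <- generate_selection_instance(10, 8, 0.15, 99)
  p1 <- withr::local_tempfile(fileext = ".mps")
  p2 <- withr::local_tempfile(fileext = ".mps")
  write_mps(a, p1); write_mps(b, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical serialization
  expect_true(all(rowSums(a$constraints$A) >= 1))
  expect_identical(screen_instance(a), "accept")
})

test_that("the gene-target generator reduces to pure hitting set at lb = ub = 1", {
  sp <- hitset_spec(6, list(c(n_tumor = 5, n_healthy = 4)), 0.35, 1.0, 1.0, 5)
  inst <- generate_cellmatrix_instance(sp)
  expect_identical(screen_instance(inst), "accept")
  sol <- solve_to_optimality(inst, seed = 1)
  expect_identical(sol$status, "optimal")
  # reference: brute-force minimum hitting set over the tumor expression matrix
  mats <- morseopt:::with_seed(5L, {
    lapply(sp$patients, function(p) {
      list(tumor = matrix(stats::runif(6 * p[["n_tumor"]]) < 0.35, 6, p[["n_tumor"]]),
           healthy = matrix(stats::runif(6 * p[["n_healthy"]]) < 0.35, 6, p[["n_healthy"]]))
    })
  })
  tm <- mats[[1]]$tumor
  best <- Inf
  for (mask in 0:(2^6 - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (all(colSums(tm[sel, , drop = FALSE]) >= 1)) best <- min(best, sum(sel))
  }
  expect_equal(sol$objective_value, best)
})

test_that("a hand-built expression matrix gives the unique expected target", {
  # two tumor cells; g1 expressed in both, g2 and g3 in one each; full
  # coverage required: {g1} is the unique optimum
  genes <- c("g1", "g2", "g3")
  kn <- c("k1", "k2")
  inst <- mip_instance("hand",
    data.frame(name = c(genes, kn), vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(rep(1, 3), genes), "minimize",
    list(
      linear_constraint(c(g1 = 1, g2 = 1, k1 = -1), ">=", 0),
      linear_constraint(c(g1 = 1, g3 = 1, k2 = -1), ">=", 0),
      linear_constraint(c(k1 = 1, k2 = 1), ">=", 2)
    ))
  cen <- enumerate_all_optima(inst)
  expect_identical(cen$keys, "1,0,0")
})

test_that("tightening the off-target bound forces larger or infeasible target sets", {
  sp_loose <- hitset_spec(7, list(c(n_tumor = 6, n_healthy = 6)), 0.4, 0.8, 1.0, 11)
  sp_tight <- hitset_spec(7, list(c(n_tumor = 6, n_healthy = 6)), 0.4, 0.8, 0.2, 11)
  loose <- solve_to_optimality(generate_cellmatrix_instance(sp_loose), 1)
  tight <- solve_to_optimality(generate_cellmatrix_instance(sp_tight), 1)
  expect_identical(loose$status, "optimal")
  if (tight$status == "optimal") {
    expect_gte(tight$objective_value, loose$objective_value)
  } else {
    expect_identical(tight$status, "infeasible")
  }
})
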