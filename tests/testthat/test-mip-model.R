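# Instance model, screening, objective evaluation, solution keys, MPS and
# solution-record I/O.

test_that("instance construction validates and normalizes", {
  expect_error(
    mip_instance("bad", data.frame(name = "x", vtype = "Integer", lb = 2, ub = 1),
                 c(x = 1), "minimize"),
    "lb > ub"
  )
  expect_error(
    mip_instance("bad", data.frame(name = "x", vtype = "Integer", lb = 0, ub = 1),
                 c(y = 1), "minimize"),
    "undeclared"
  )
  # Binary bounds clipped into [0, 1]
  inst <- mip_instance("b", data.frame(name = "x", vtype = "Binary", lb = -3, ub = 7),
                       c(x = 1), "minimize")
  expect_equal(inst$variables$lb, 0)
  expect_equal(inst$variables$ub, 1)
})

test_that("screening accepts integral objectives and rejects continuous-only ones", {
  expect_identical(screen_instance(toy2()), "accept")

  cont <- mip_instance("cont",
    data.frame(name = c("a", "b"), vtype = "Continuous", lb = 0, ub = 10),
    c(a = 1, b = 2), "minimize")
  expect_identical(screen_instance(cont), "reject")

  # integral variable with zero coefficient does not qualify
  zero <- mip_instance("zero",
    data.frame(name = c("a", "b"), vtype = c("Integer", "Continuous"), lb = 0, ub = 10),
    c(a = 0, b = 2), "minimize")
  expect_identical(screen_instance(zero), "reject")

  empty <- mip_instance("empty",
    data.frame(name = "a", vtype = "Integer", lb = 0, ub = 1),
    numeric(0), "minimize")
  expect_identical(screen_instance(empty), "reject")
})

test_that("screening is invariant under variable permutation and positive scaling", {
  set.seed(11)
  for (i in 1:20) {
    inst <- mk_random_integer_instance(i)
    verdict <- screen_instance(inst)
    perm <- sample(nrow(inst$variables))
    permuted <- mip_instance(inst$name, inst$variables[perm, ],
                             inst$objective[sample(length(inst$objective))],
                             inst$sense,
                             list(A = inst$constraints$A[, perm, drop = FALSE] |>
                                    `colnames<-`(inst$variables$name[perm]),
                                  sense = inst$constraints$sense,
                                  rhs = inst$constraints$rhs))
    expect_identical(screen_instance(permuted), verdict)
    scaled <- inst
    scaled$objective <- inst$objective * runif(1, 0.1, 10)
    expect_identical(screen_instance(scaled), verdict)
  }
})

test_that("objective evaluation is exact and linear", {
  toy <- toy2()
  expect_equal(objective_value(toy, c(x1 = 1, x2 = 2)), 3)
  expect_equal(objective_value(toy, c(x1 = 0, x2 = 0)), 0)
  expect_equal(
    objective_value(toy, c(x1 = 1, x2 = 2),
                    coefficients = c(x1 = 0.99864, x2 = 1.00142)),
    0.99864 * 1 + 1.00142 * 2
  )
  expect_error(objective_value(toy, c(x1 = 1)), class = "morseopt_contract_error")
  # linearity: value(a) + value(b) = value(a + b)
  set.seed(4)
  for (i in 1:10) {
    a <- c(x1 = runif(1), x2 = runif(1))
    b <- c(x1 = runif(1), x2 = runif(1))
    expect_equal(objective_value(toy, a) + objective_value(toy, b),
                 objective_value(toy, a + b))
  }
})

test_that("solution keys round integers, ignore constraint-only variables", {
  toy <- toy2()
  expect_identical(solution_key(toy, c(x1 = 1.0000004, x2 = 1.9999998)), "1,2")
  expect_identical(key_values("1,2", toy), c(x1 = 1, x2 = 2))

  # constraint-only variable differences do not change the key
  inst <- mip_instance("aux",
    data.frame(name = c("x", "s"), vtype = c("Integer", "Continuous"),
               lb = 0, ub = c(5, 10)),
    c(x = 1), "maximize",
    list(linear_constraint(c(x = 1, s = 1), "<=", 7)))
  k1 <- solution_key(inst, c(x = 3, s = 0.5))
  k2 <- solution_key(inst, c(x = 3, s = 4))
  expect_identical(k1, k2)
})

test_that("a hand-written MPS fixture parses to its expected in-memory form", {
  mps <- c(
    "NAME          FIX3",
    "ROWS",
    " N  COST",
    " L  C1",
    " G  C2",
    "COLUMNS",
    "    MARKER1   'MARKER'  'INTORG'",
    "    X1        COST      2.0   C1    1.0",
    "    X1        C2        1.0",
    "    X2        COST      3.0   C1    2.0",
    "    MARKER2   'MARKER'  'INTEND'",
    "    X3        COST      1.5   C2    1.0",
    "RHS",
    "    RHS1      C1        10.0  C2    1.0",
    "BOUNDS",
    " UP BND1      X1        4",
    " BV BND1      X2",
    "ENDATA"
  )
  path <- withr::local_tempfile(fileext = ".mps")
  writeLines(mps, path)
  inst <- read_mps(path)
  expect_identical(inst$name, "FIX3")
  expect_identical(inst$variables$name, c("X1", "X2", "X3"))
  expect_identical(inst$variables$vtype, c("Integer", "Binary", "Continuous"))
  expect_equal(inst$variables$lb, c(0, 0, 0))
  expect_equal(inst$variables$ub, c(4, 1, Inf))
  expect_equal(sort(names(inst$objective)), c("X1", "X2", "X3"))
  expect_equal(unname(inst$objective[c("X1", "X2", "X3")]), c(2, 3, 1.5))
  expect_identical(inst$sense, "minimize")
  expect_equal(length(inst$constraints$rhs), 2)
  expect_equal(inst$constraints$rhs, c(10, 1))
  expect_identical(inst$constraints$sense, c("<=", ">="))
  expect_identical(screen_instance(inst), "accept")
})

test_that("malformed MPS files raise format errors", {
  path <- withr::local_tempfile(fileext = ".mps")
  writeLines(c("NAME X", "ROWS", " N OBJ", "COLUMNS", "    X1 OBJ 1"), path)
  expect_error(read_mps(path), class = "morseopt_format_error")  # no ENDATA
  writeLines(c("NAME X", "GIBBERISH", "ENDATA"), path)
  expect_error(read_mps(path), class = "morseopt_format_error")
  expect_error(read_mps("no/such/file.mps"), "not found")
})

test_that("MPS write/read round-trips instances canonically", {
  set.seed(21)
  fixtures <- c(toy_fixtures()[c("toy_2var", "eps_example", "frac_example")],
                lapply(1:5, mk_random_integer_instance),
                list(generate_selection_instance(6, 4, 0.4, 9)))
  for (inst in fixtures) {
    path <- withr::local_tempfile(fileext = ".mps")
    write_mps(inst, path)
    back <- read_mps(path)
    expect_identical(back$sense, inst$sense)
    expect_identical(back$variables$name, inst$variables$name)
    expect_identical(back$variables$vtype, inst$variables$vtype)
    expect_equal(back$variables$lb, inst$variables$lb)
    expect_equal(back$variables$ub, inst$variables$ub)
    expect_equal(back$objective[order(names(back$objective))],
                 inst$objective[order(names(inst$objective))])
    expect_equal(back$constraints$rhs, inst$constraints$rhs)
    expect_identical(back$constraints$sense, inst$constraints$sense)
    expect_equal(back$constraints$A, inst$constraints$A)
    # and a second write is byte-identical (serialization is deterministic)
    path2 <- withr::local_tempfile(fileext = ".mps")
    write_mps(back, path2)
    write_mps(inst, path)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("solution records round-trip through TSV and JSON", {
  toy <- toy2()
  b <- run_batch(toy, runs = 6, mode = "morse")
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_solutions(b, path, format = fmt)
    df <- read_solutions(path, format = fmt)
    expect_equal(nrow(df), 6)
    ref <- solution_records_frame(b)
    expect_identical(df$solution_key, ref$solution_key)
    expect_equal(df$objective_value_original, ref$objective_value_original)
    expect_equal(df$objective_value_perturbed, ref$objective_value_perturbed,
                 tolerance = 1e-15)
    expect_identical(df$verified_optimal, ref$verified_optimal)
    expect_identical(as.integer(df$seed), ref$seed)
  }
  # empty record list: header-only file
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solutions(list(), path, instance = toy)
  expect_equal(nrow(read_solutions(path)), 0)
})
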