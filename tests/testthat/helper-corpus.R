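# Shared test corpus builders. Everything is generated in code at a fixed
# seed; no fixture files are needed beyond the tiny MPS texts written by the
# tests themselves.

# A random feasible pure-integer instance with integer coefficients and
# finite bounds: the setting in which perturbed-instance optima are
# guaranteed to be optima of the original. Feasibility is guaranteed by
# anchoring the right-hand sides at a random lattice point.
mk_random_integer_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:5, 1)
  m <- sample(2:4, 1)
  ubv <- sample(1:3, n, replace = TRUE)
  A <- matrix(sample(-3:3, m * n, replace = TRUE), m, n)
  sense <- sample(c("<=", ">="), m, replace = TRUE)
  x0 <- vapply(seq_len(n), function(j) sample(0:ubv[j], 1), numeric(1))
  rhs <- as.numeric(A %*% x0) +
    ifelse(sense == "<=", sample(0:2, m, TRUE), -sample(0:2, m, TRUE))
  obj <- sample(c(-4:-1, 1:4), n, replace = TRUE)
  nm <- paste0("x", seq_len(n))
  mip_instance(
    paste0("rand_int_", seed),
    data.frame(name = nm, vtype = "Integer", lb = 0, ub = ubv),
    stats::setNames(obj, nm),
    sample(c("minimize", "maximize"), 1),
    list(A = A, sense = sense, rhs = rhs)
  )
}

# First generated selection instance (scanning generator seeds upward from
# `scan_from`) whose complete optimum census has exactly `m` keys.
find_selection_with_m <- function(m, scan_from = 1, n_elements = 7, n_sets = 5,
                                  density = 0.35, max_scan = 500) {
  for (s in scan_from:(scan_from + max_scan)) {
    inst <- generate_selection_instance(n_elements, n_sets, density, s)
    cen <- enumerate_all_optima(inst)
    if (cen$feasible && cen$complete && length(cen$keys) == m) {
      return(list(instance = inst, census = cen, seed = s))
    }
  }
  stop("no selection instance with ", m, " optima found in scan range")
}

# Selection instance whose optima are the products of independent choices,
# one element from each disjoint pool: |pool1| * |pool2| * ... optima, all of
# size length(pools). The optimal-set system is invariant under permuting
# elements within a pool, so the exchangeability argument behind the
# equal-probability property applies exactly. Optional decoy elements appear
# in no covering constraint and are never selected.
mk_product_selection_instance <- function(pools, n_decoys = 0) {
  n <- sum(pools) + n_decoys
  nm <- paste0("e", seq_len(n))
  A <- matrix(0, length(pools), n, dimnames = list(NULL, nm))
  offset <- 0
  for (i in seq_along(pools)) {
    A[i, offset + seq_len(pools[i])] <- 1
    offset <- offset + pools[i]
  }
  mip_instance(
    paste0("pools_", paste(pools, collapse = "x"), "_d", n_decoys),
    data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(rep(1, n), nm),
    "minimize",
    list(A = A, sense = rep(">=", length(pools)), rhs = rep(1, length(pools)))
  )
}

# Selection instance with m equiprobable singleton optima: one covering set
# containing all m elements.
mk_singleton_optima_instance <- function(m) {
  nm <- paste0("e", seq_len(m))
  mip_instance(
    paste0("singletons_", m),
    data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    stats::setNames(rep(1, m), nm),
    "minimize",
    list(A = matrix(1, 1, m, dimnames = list(NULL, nm)),
         sense = ">=", rhs = 1)
  )
}

toy2 <- function() toy_fixtures()$toy_2var
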