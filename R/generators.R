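# Synthetic instances: covering/selection problems and a single-layer
# gene-target hitting-set generator emulating single-cell expression data,
# plus the small worked-example fixtures used throughout the documentation
# and tests.

#' Generate a random minimum hitting-set (selection) instance
#'
#' Minimize the number of selected elements subject to one covering
#' constraint per set (`sum over the set's elements >= 1`). All variables are
#' binary with unit objective coefficients — a selection problem, for which
#' the perturbation method finds each distinct optimum with equal
#' probability. Sets are drawn by including each element independently with
#' probability `density`; empty draws are redrawn, so the generated instance
#' is never infeasible by construction.
#'
#' @param n_elements Number of elements (binary variables).
#' @param n_sets Number of sets to cover.
#' @param density Inclusion probability in `(0, 1]`.
#' @param seed Integer seed; identical arguments give identical instances.
#' @return A [mip_instance()] named `selection_<n>x<m>_s<seed>`.
#' @examples
#' inst <- generate_selection_instance(6, 4, 0.4, seed = 1)
#' enumerate_all_optima(inst)
#' @export
generate_selection_instance <- function(n_elements, n_sets, density, seed) {
  stopifnot(n_elements >= 1, n_sets >= 1, density > 0, density <= 1)
  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      repeat {
        s <- which(stats::runif(n_elements) < density)
        if (length(s)) return(s)
      }
    })
  })
  nm <- paste0("e", seq_len(n_elements))
  A <- matrix(0, n_sets, n_elements, dimnames = list(NULL, nm))
  for (i in seq_len(n_sets)) A[i, sets[[i]]] <- 1
  mip_instance(
    name = sprintf("selection_%dx%d_s%d", n_elements, n_sets, seed),
    variables = data.frame(name = nm, vtype = "Binary", lb = 0, ub = 1),
    objective = stats::setNames(rep(1, n_elements), nm),
    sense = "minimize",
    constraints = list(A = A, sense = rep(">=", n_sets), rhs = rep(1, n_sets))
  )
}

#' Specify a synthetic gene-target selection problem
#'
#' Parameters of a single-layer hitting-set model of gene-target selection
#' from single-cell expression data: per patient, a binary gene-by-cell
#' expression matrix is drawn; a cell is killed iff it expresses at least one
#' selected gene; the smallest gene set is sought that kills at least a lower
#' bound fraction of each patient's tumor cells while killing at most an
#' upper bound fraction of their healthy cells.
#'
#' @param n_genes Number of candidate target genes.
#' @param patients List (or data.frame with columns `n_tumor`, `n_healthy`)
#'   giving per-patient tumor and healthy cell counts.
#' @param expression_probability Probability that a gene is expressed in a
#'   cell, in `(0, 1)`.
#' @param coverage_lower_bound Required killed fraction of each patient's
#'   tumor cells, in `(0, 1]`.
#' @param offtarget_upper_bound Allowed killed fraction of each patient's
#'   healthy cells, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `hitset_spec`.
#' @export
hitset_spec <- function(n_genes, patients, expression_probability,
                        coverage_lower_bound, offtarget_upper_bound, seed) {
  if (is.data.frame(patients)) {
    patients <- lapply(seq_len(nrow(patients)), function(i) {
      c(n_tumor = patients$n_tumor[i], n_healthy = patients$n_healthy[i])
    })
  }
  stopifnot(n_genes >= 1, length(patients) >= 1,
            expression_probability > 0, expression_probability < 1,
            coverage_lower_bound > 0, coverage_lower_bound <= 1,
            offtarget_upper_bound >= 0, offtarget_upper_bound <= 1)
  structure(
    list(n_genes = as.integer(n_genes), patients = patients,
         expression_probability = expression_probability,
         coverage_lower_bound = coverage_lower_bound,
         offtarget_upper_bound = offtarget_upper_bound,
         seed = as.integer(seed)),
    class = "hitset_spec"
  )
}

#' Generate a gene-target selection instance from a specification
#'
#' Draws the per-patient binary expression matrices at the spec's seed and
#' assembles the ILP: unit-coefficient binary gene selection variables in the
#' objective, one auxiliary binary kill indicator per cell (constraint-only),
#' per-patient tumor-coverage lower bounds (`ceiling(lb * n_tumor)` cells)
#' and healthy-cell off-target upper bounds (`floor(ub * n_healthy)` cells).
#' With both bounds at 1 the instance reduces to a pure minimum hitting set
#' over tumor cells. Feasibility is not decided at generation time.
#'
#' @param spec A [hitset_spec()].
#' @return A [mip_instance()] that always passes [screen_instance()].
#' @examples
#' sp <- hitset_spec(6, list(c(n_tumor = 8, n_healthy = 6)), 0.3, 0.8, 0.5, 1)
#' inst <- generate_cellmatrix_instance(sp)
#' solve_to_optimality(inst)
#' @export
generate_cellmatrix_instance <- function(spec) {
  stopifnot(inherits(spec, "hitset_spec"))
  genes <- paste0("g", seq_len(spec$n_genes))
  mats <- with_seed(spec$seed, {
    lapply(spec$patients, function(p) {
      list(
        tumor = matrix(stats::runif(spec$n_genes * p[["n_tumor"]]) < spec$expression_probability,
                       spec$n_genes, p[["n_tumor"]]),
        healthy = matrix(stats::runif(spec$n_genes * p[["n_healthy"]]) < spec$expression_probability,
                         spec$n_genes, p[["n_healthy"]])
      )
    })
  })
  vars <- data.frame(name = genes, vtype = "Binary", lb = 0, ub = 1)
  cons <- list()
  for (p in seq_along(mats)) {
    tm <- mats[[p]]$tumor
    hm <- mats[[p]]$healthy
    n_tumor <- ncol(tm); n_healthy <- ncol(hm)
    # tumor kill indicators: k <= sum of selected genes expressed in the cell
    knames <- sprintf("k_p%d_c%d", p, seq_len(n_tumor))
    vars <- rbind(vars, data.frame(name = knames, vtype = "Binary", lb = 0, ub = 1))
    for (cix in seq_len(n_tumor)) {
      expressed <- genes[tm[, cix]]
      co <- stats::setNames(c(rep(1, length(expressed)), -1),
                            c(expressed, knames[cix]))
      cons[[length(cons) + 1]] <- linear_constraint(co, ">=", 0)
    }
    cons[[length(cons) + 1]] <- linear_constraint(
      stats::setNames(rep(1, n_tumor), knames), ">=",
      ceiling(spec$coverage_lower_bound * n_tumor))
    # healthy kill indicators: |G_c| * h >= sum of selected genes expressed
    hnames <- sprintf("h_p%d_c%d", p, seq_len(n_healthy))
    vars <- rbind(vars, data.frame(name = hnames, vtype = "Binary", lb = 0, ub = 1))
    for (cix in seq_len(n_healthy)) {
      expressed <- genes[hm[, cix]]
      if (length(expressed)) {
        co <- stats::setNames(c(rep(1, length(expressed)), -length(expressed)),
                              c(expressed, hnames[cix]))
        cons[[length(cons) + 1]] <- linear_constraint(co, "<=", 0)
      }
    }
    cons[[length(cons) + 1]] <- linear_constraint(
      stats::setNames(rep(1, n_healthy), hnames), "<=",
      floor(spec$offtarget_upper_bound * n_healthy))
  }
  mip_instance(
    name = sprintf("hitset_g%d_p%d_s%d", spec$n_genes, length(spec$patients),
                   spec$seed),
    variables = vars,
    objective = stats::setNames(rep(1, spec$n_genes), genes),
    sense = "minimize",
    constraints = cons
  )
}

#' Small worked-example fixtures
#'
#' The instances used in the documentation and tests:
#' * `toy_2var` — maximize `x1 + x2` with `x1, x2` integer in `[0, 2]` and
#'   `x1 + x2 <= 3.5`; optimal value 3, attained by exactly the two optima
#'   `(1, 2)` and `(2, 1)` (lower bounds fixed at 0 so the lattice is
#'   finite).
#' * `eps_example` — objective `2x + 3y + z`, all Integer, `x` in `[-2, 1]`,
#'   `y` in `[1, 4]`, `z` in `[-4, 2]`; `S = 20`, `epsilon = 0.025`.
#' * `eps_example_x5`, `eps_example_div5` — the same instance with all
#'   objective coefficients scaled by 5 and 1/5 (`epsilon` 0.005 and 0.125).
#' * `frac_example` — fractional objective `1.3x + 3.2y + 2.1z` (same
#'   bounds); integralizing scale factor 10.
#'
#' @return Named list of [mip_instance()] objects.
#' @export
toy_fixtures <- function() {
  toy <- mip_instance(
    name = "toy_2var",
    variables = data.frame(name = c("x1", "x2"), vtype = "Integer", lb = 0, ub = 2),
    objective = c(x1 = 1, x2 = 1),
    sense = "maximize",
    constraints = list(linear_constraint(c(x1 = 1, x2 = 1), "<=", 3.5))
  )
  eps_vars <- data.frame(name = c("x", "y", "z"), vtype = "Integer",
                         lb = c(-2, 1, -4), ub = c(1, 4, 2))
  mk_eps <- function(name, coef) {
    mip_instance(name, eps_vars, stats::setNames(coef, c("x", "y", "z")),
                 "minimize")
  }
  list(
    toy_2var = toy,
    eps_example = mk_eps("eps_example", c(2, 3, 1)),
    eps_example_x5 = mk_eps("eps_example_x5", c(10, 15, 5)),
    eps_example_div5 = mk_eps("eps_example_div5", c(0.4, 0.6, 0.2)),
    frac_example = mk_eps("frac_example", c(1.3, 3.2, 2.1))
  )
}
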