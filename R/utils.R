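# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside the package
#' never disturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Greatest common divisor / least common multiple on whole numbers stored as
# doubles. Values must stay below 2^53 for exactness; callers guard overflow.
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(max(a, b, 1))
  (a / gcd2(a, b)) * b
}

# Best rational approximation p/q of x with q <= max_denominator, by
# continued-fraction convergents. Returns c(numerator, denominator).
rational_approx <- function(x, max_denominator = 1e6) {
  stopifnot(is.finite(x), max_denominator >= 1)
  sign_x <- if (x < 0) -1 else 1
  x <- abs(x)
  if (abs(x - round(x)) < .Machine$double.eps * max(1, x) * 4) {
    return(c(sign_x * round(x), 1))
  }
  # convergents h_k / k_k
  h0 <- 1; h1 <- floor(x)
  k0 <- 0; k1 <- 1
  frac <- x - floor(x)
  best <- c(h1, k1)
  for (i in seq_len(64)) {
    if (frac < 1e-15) break
    a <- floor(1 / frac)
    frac <- 1 / frac - a
    h2 <- a * h1 + h0
    k2 <- a * k1 + k0
    if (k2 > max_denominator) break
    h0 <- h1; h1 <- h2
    k0 <- k1; k1 <- k2
    best <- c(h1, k1)
    if (abs(x - h1 / k1) < .Machine$double.eps * max(1, x) * 4) break
  }
  c(sign_x * best[1], best[2])
}

stop_morseopt <- function(msg, class) {
  stop(structure(
    class = c(class, "morseopt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_wholenumber <- function(x, tol = 1e-6) {
  abs(x - round(x)) <= tol
}
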