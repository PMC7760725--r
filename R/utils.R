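# internal numerical helpers

# Cumulative trapezoidal integral of y(t) from t = 0 with an implied (0, 0)
# sample before the first point.  Frame midpoints never include t = 0, but the
# Logan running integrals start at injection, so the origin sample is part of
# the transform.
cumtrapz0 <- function(t, y) {
  stopifnot(length(t) == length(y), all(diff(c(0, t)) > 0))
  dt <- diff(c(0, t))
  cumsum(0.5 * (c(0, y[-length(y)]) + y) * dt)
}

# Row-wise cumtrapz0 for a voxels-by-frames matrix.
cumtrapz0_rows <- function(t, Y) {
  dt <- diff(c(0, t))
  out <- matrix(0, nrow(Y), ncol(Y))
  prev <- numeric(nrow(Y))
  acc <- numeric(nrow(Y))
  for (f in seq_along(t)) {
    acc <- acc + 0.5 * (prev + Y[, f]) * dt[f]
    out[, f] <- acc
    prev <- Y[, f]
  }
  out
}

# Plain cumulative trapezoid on a grid that already starts at its origin.
cumtrapz_grid <- function(t, y) {
  n <- length(t)
  c(0, cumsum(0.5 * (y[-n] + y[-1]) * diff(t)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG state seeded at `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
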