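# Internal helpers shared across modules.

# Classed error constructor so callers can distinguish failure modes
# (format, geometry, coverage, ...) without string matching.
.err <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aneumorph_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) .err(class, msg, ...)
  invisible(TRUE)
}

# Row-wise vector norms of an n x 3 matrix.
.rownorm <- function(m) sqrt(rowSums(m * m))

.normalize_rows <- function(m) {
  n <- .rownorm(m)
  n[n == 0] <- 1
  m / n
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) .err("aneumorph_domain_error", "zero-length direction vector")
  v / n
}

# Any two unit vectors spanning the plane orthogonal to unit vector n.
.plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(pracma_cross(n, a))
  v <- pracma_cross(n, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Trapezoidal integral of y(t) over sampled, strictly increasing t.
.trapz <- function(t, y) {
  n <- length(t)
  if (n == 1L) return(0)
  dt <- diff(t)
  sum(dt * (y[-1] + y[-n]) / 2)
}

# Trapezoidal quadrature weights: .trapz(t, y) == sum(.trapz_weights(t) * y).
# Lets a k x nt matrix of series be integrated in one matrix product.
.trapz_weights <- function(t) {
  n <- length(t)
  if (n == 1L) return(1)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

# Deterministic per-stream RNG seed derived from a base seed; keeps
# values inside the 32-bit integer range.
.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(index)) %% 2147483647)
}
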