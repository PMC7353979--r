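#' @importFrom pracma cumtrapz
#' @importFrom stats approx optimize rnorm runif rlnorm sd median quantile
#' @importFrom utils head tail
NULL

# Second-order finite differences of each column of `y` with respect to the
# (equispaced) grid `x`: central differences in the interior, second-order
# one-sided stencils at the two endpoints.
fdDeriv <- function(y, x) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 grid points for differentiation")
  h <- x[2L] - x[1L]
  d <- matrix(NA_real_, n, ncol(y))
  d[2:(n - 1L), ] <- (y[3:n, , drop = FALSE] - y[1:(n - 2L), , drop = FALSE]) / (2 * h)
  d[1L, ] <- (-3 * y[1L, ] + 4 * y[2L, ] - y[3L, ]) / (2 * h)
  d[n, ] <- (3 * y[n, ] - 4 * y[n - 1L, ] + y[n - 2L, ]) / (2 * h)
  d
}

# Unwrap a vector of angles so no step between consecutive entries exceeds
# pi in magnitude (removes the atan2 branch cut along arclength).
unwrapAngle <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

# Cumulative chord length of an ordered 2-column point matrix.
chordLengths <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

rotationMatrix <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
}

# ---- exact non-negative big integers in base 1e6 (little-endian chunks) ----
# Only what the subset count needs: doubling, decrement, decimal formatting.

bigFromInt <- function(x) as.numeric(x)

bigDouble <- function(chunks) {
  v <- chunks * 2
  carry <- 0
  for (i in seq_along(v)) {
    v[i] <- v[i] + carry
    carry <- v[i] %/% 1e6
    v[i] <- v[i] %% 1e6
  }
  while (carry > 0) {
    v <- c(v, carry %% 1e6)
    carry <- carry %/% 1e6
  }
  v
}

bigDecrement <- function(chunks) {
  i <- 1L
  while (chunks[i] == 0) {
    chunks[i] <- 1e6 - 1
    i <- i + 1L
  }
  chunks[i] <- chunks[i] - 1
  while (length(chunks) > 1L && chunks[length(chunks)] == 0)
    chunks <- chunks[-length(chunks)]
  chunks
}

bigFormat <- function(chunks) {
  n <- length(chunks)
  out <- format(chunks[n], scientific = FALSE)
  if (n > 1L)
    out <- paste0(out, paste(sprintf("%06d", rev(chunks[-n])), collapse = ""))
  out
}

# Residue of a big decimal string modulo a small integer (Horner scheme);
# used by tests as an independent arithmetic check.
bigMod <- function(digits, m) {
  r <- 0
  for (ch in strsplit(digits, "")[[1]])
    r <- (r * 10 + as.integer(ch)) %% m
  r
}
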