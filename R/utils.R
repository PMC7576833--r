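# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap angles (degrees) into (-180, 180].
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

## Circular absolute difference in degrees, in [0, 180].
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Boltzmann constant in kcal/(mol K)
.kB_kcal <- 0.0019872041

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Row-wise cross product for n x 3 matrices.
cross3m <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rownorm <- function(a) sqrt(rowSums(a^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
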