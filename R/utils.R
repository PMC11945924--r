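## small shared helpers

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero-length vector")
  v / n
}

## any vector perpendicular to v (deterministic choice)
perp_vector <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(ref, v))
}

pracma_cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

## rotate vector v about (unit) axis by angle (radians), Rodrigues formula
rotate_about <- function(v, axis, angle) {
  k <- unit(axis)
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

## deterministic temp file inside tempdir
comsia_tempfile <- function(ext) tempfile("comsia-", fileext = ext)
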