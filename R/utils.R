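# Internal geometry and RNG helpers.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-10) {
    stop("degenerate (near-zero) ", what, "; cannot normalize", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  unname(c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1]))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Angle between two vectors, degrees in [0, 180].
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Wrap angles (degrees) onto the principal range [-180, 180).
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180   # guard against fp roundup at the seam
  y
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Standard atomic masses for ring heavy atoms.
ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974, H = 1.008)

element_mass <- function(element) {
  m <- ATOMIC_MASS[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
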