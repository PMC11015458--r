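#' Wrap angles to the interval [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @export
#' @examples
#' wrapDeg(c(-10, 370, 360))
wrapDeg <- function(x) {
  x %% 360
}

#' Signed circular difference in degrees
#'
#' Computes `a - b` on the circle, wrapped to `(-180, 180]`. Positive values
#' mean `a` lies counterclockwise of `b`.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return signed differences in `(-180, 180]`.
#' @export
#' @examples
#' circDiffDeg(350, 10)   # -20
#' circDiffDeg(10, 350)   #  20
circDiffDeg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# degrees -> radians
.deg2rad <- function(x) x * pi / 180

# deterministic stream of sub-seeds derived from a base seed; values < 2^31
.subSeeds <- function(seed, n) {
  s <- as.double(seed %% 2147483647L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    # Lehmer / Park-Miller step, kept in double precision (exact below 2^53)
    s <- (s * 48271) %% 2147483647
    if (s == 0) s <- 1
    out[i] <- s
  }
  as.integer(out)
}

# run expr with a local RNG state seeded at `seed`; restores caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
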