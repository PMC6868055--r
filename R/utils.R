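#' @importFrom stats rnorm runif rexp rpois median mad sd prcomp wilcox.test
#' @importFrom stats pnorm dnorm var quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

# Largest admissible seed for derived sub-streams (R integers are 32-bit).
.MAX_SEED <- .Machine$integer.max - 1L

#' Derive independent sub-seeds from a master seed
#'
#' Used throughout the package so that one master seed reproducibly controls
#' every source of randomness (model ensembles, thermal noise, camera noise,
#' data splits, weight initialisation).
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds to draw.
#' @return integer vector of `n` distinct seeds.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.MAX_SEED, n))
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if ((strict && x <= min) || (!strict && x < min))
    stop(sprintf("'%s' must be %s %g", name, if (strict) ">" else ">=", min),
         call. = FALSE)
  invisible(x)
}

# Unit vectors perpendicular to a unit axis u (3-vector); returns list(e1, e2).
perp_basis <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2L] * e1[3L] - u[3L] * e1[2L],
    u[3L] * e1[1L] - u[1L] * e1[3L],
    u[1L] * e1[2L] - u[2L] * e1[1L]
  )
  list(e1 = e1, e2 = e2)
}

# Rotation matrix from Z-Y-X Euler angles (radians).
euler_matrix <- function(a, b, g) {
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(g), -sin(g)), c(0, sin(g), cos(g)))
  Rz %*% Ry %*% Rx
}
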