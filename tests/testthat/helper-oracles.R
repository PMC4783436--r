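# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a reproducible random proper rotation + translation
random_transform <- function(max_angle = 170, max_trans = 50) {
  rigid_transform(
    euler_to_rotation(c(runif(1, -max_angle, max_angle),
                        runif(1, -85, 85),
                        runif(1, -max_angle, max_angle))),
    runif(3, -max_trans, max_trans))
}

# brute-force RMS of a fitted transform over paired points (residual oracle)
brute_rms <- function(tf, source, target) {
  moved <- apply_transform(tf, source)
  sqrt(mean(rowSums((moved - target)^2)))
}

# independent Wilcoxon signed-rank oracle: full 2^n enumeration computed
# from first principles (no shared code with the implementation)
enum_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    wp <- sum(r[signs])
    if (min(wp, total - wp) <= w_obs) count <- count + 1L
  }
  count / 2^n
}

# least-squares quartic through the normal equations (oracle for the QR fit)
normal_equations_quartic <- function(a, b) {
  A <- outer(a, 0:4, "^")
  solve(crossprod(A), crossprod(A, b))[, 1]
}

# small phantom config used where full CT resolution is not the point
small_config <- function(...) {
  phantom_config(shape = c(64L, 64L, 64L), spacing_mm = c(1.6, 1.6, 1.6), ...)
}

# angle (degrees) between two rotations
rotation_angle_deg <- function(r1, r2 = diag(3)) {
  rel <- t(r2) %*% r1
  acos(max(-1, min(1, (sum(diag(rel)) - 1) / 2))) * 180 / pi
}
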