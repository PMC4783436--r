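# Internal helpers shared across modules.

os_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "orthosim_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    os_abort(sprintf("%s must be finite numeric", what), "invalid_argument")
  }
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) os_abort("cannot normalize a zero vector", "degenerate_configuration")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

as_points <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3) os_abort(sprintf("%s must be an N x 3 matrix", what), "invalid_argument")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) os_abort(sprintf("%s contain non-finite values", what), "invalid_argument")
  x
}

# Brute-force nearest neighbour from each query row to the reference rows,
# chunked so the distance matrix never exceeds ~chunk x nrow(ref).
nearest_neighbor <- function(query, ref, chunk = 512L) {
  query <- as_points(query, "query points")
  ref <- as_points(ref, "reference points")
  nq <- nrow(query)
  idx <- integer(nq)
  d2 <- numeric(nq)
  rn2 <- rowSums(ref^2)
  for (start in seq(1L, nq, by = chunk)) {
    end <- min(start + chunk - 1L, nq)
    q <- query[start:end, , drop = FALSE]
    # squared distances via |q|^2 + |r|^2 - 2 q.r
    g <- q %*% t(ref)
    m <- sweep(-2 * g, 2, rn2, "+") + rowSums(q^2)
    j <- max.col(-m, ties.method = "first")
    idx[start:end] <- j
    d2[start:end] <- m[cbind(seq_len(nrow(m)), j)]
  }
  list(index = idx, distance = sqrt(pmax(d2, 0)))
}

# Vectorized closest point on triangles (a, b, c) from points p (all N x 3);
# the standard region-based algorithm, evaluated per row.
closest_point_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  n <- nrow(p)
  out <- matrix(NA_real_, n, 3)
  set_rows <- function(mask, val) {
    mask <- mask & is.na(out[, 1])
    if (any(mask)) out[mask, ] <<- val[mask, , drop = FALSE]
  }
  set_rows(d1 <= 0 & d2 <= 0, a)                                  # vertex a
  set_rows(d3 >= 0 & d4 <= d3, b)                                 # vertex b
  set_rows(d6 >= 0 & d5 <= d6, c)                                 # vertex c
  t_ab <- d1 / pmax(d1 - d3, 1e-300)
  set_rows(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * t_ab)            # edge ab
  t_ac <- d2 / pmax(d2 - d6, 1e-300)
  set_rows(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * t_ac)            # edge ac
  t_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  set_rows(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c - b) * t_bc)
  denom <- va + vb + vc
  v <- vb / ifelse(denom == 0, 1, denom)
  w <- vc / ifelse(denom == 0, 1, denom)
  set_rows(rep(TRUE, n), a + ab * v + ac * w)                     # interior
  out
}

# Otsu's threshold on a numeric vector (maximal between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0) {
    os_abort("cannot threshold a constant intensity set", "invalid_argument")
  }
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[nbins]
  tot_mu <- mu[nbins]
  w0 <- w[-nbins]
  w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-nbins] / w0
  m1 <- (tot_mu - mu[-nbins]) / w1
  between <- w0 * w1 * (m0 - m1)^2
  between[!valid] <- -Inf
  mids[which.max(between)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
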