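# Accuracy protocol: landmark moving distances in virtual vs real
# measurements over repeated arbitrary repositionings of the lower dental
# cast, summarized per landmark with a Wilcoxon signed-rank test.

#' Landmark moving distances
#'
#' Euclidean distance per named landmark between an initial and a final
#' configuration.
#'
#' @param initial,final named lists (or 3-row named matrices) of landmark
#'   points (mm) with identical names.
#' @return Named numeric vector of distances (mm).
#' @export
landmark_moving_distance <- function(initial, final) {
  as_lmk <- function(x) {
    if (is.matrix(x)) x <- apply(x, 1, identity, simplify = FALSE)
    x
  }
  initial <- as_lmk(initial)
  final <- as_lmk(final)
  if (!setequal(names(initial), names(final)) || is.null(names(initial))) {
    os_abort("initial and final landmark names do not match", "invalid_argument")
  }
  vapply(names(initial),
         function(nm) vnorm(final[[nm]] - initial[[nm]]),
         numeric(1))
}

#' Wilcoxon signed-rank test (exact by enumeration for small n)
#'
#' Classical paired signed-rank procedure: zero differences are dropped,
#' tied absolute differences are mid-ranked, and the statistic `W` is the
#' smaller of the positive- and negative-rank sums. The two-sided p-value
#' is exact -- computed by full enumeration of all `2^n` sign assignments --
#' for `n <= 12` after dropping zeros, and uses the normal approximation
#' with continuity correction (and tie correction in the variance) for
#' larger `n`.
#'
#' @param a,b paired numeric vectors, or `a` an N x 2 matrix / data frame of
#'   pairs with `b` missing.
#' @param zero_tol absolute differences at or below this are treated as
#'   zero and dropped (default 0, the classical rule).
#' @return A list with `statistic` (W), `n` (pairs used), `p_value`,
#'   `significant_5pct`, `method` (`"exact"` or `"normal_approx"`), and
#'   `degenerate` (`TRUE` when all differences are zero; no p-value then).
#' @examples
#' wilcoxon_signed_rank(1:5, 2:6)  # W = 0, exact p = 2/32
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, zero_tol = 0) {
  if (is.null(b)) {
    a <- as.matrix(a)
    if (ncol(a) != 2) os_abort("need paired data", "invalid_argument")
    b <- a[, 2]; a <- a[, 1]
  }
  if (length(a) != length(b)) os_abort("paired vectors differ in length", "invalid_argument")
  d <- a - b
  d <- d[abs(d) > zero_tol]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0L, p_value = NA_real_,
                significant_5pct = FALSE, method = "degenerate",
                degenerate = TRUE))
  }
  if (n < 5) {
    warning("fewer than 5 nonzero differences: p-value is unreliable")
  }
  r <- rank(abs(d))  # ties mid-ranked
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= 12) {
    # enumerate all sign assignments; under H0 each is equally likely
    total <- sum(r)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    pos_sums <- as.numeric(signs %*% r)
    stat_all <- pmin(pos_sums, total - pos_sums)
    p <- mean(stat_all <= w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal_approx"
  }
  list(statistic = w, n = n, p_value = p,
       significant_5pct = is.finite(p) && p < 0.05,
       method = method, degenerate = FALSE)
}

#' Run the repeated-repositioning accuracy protocol
#'
#' Emulates the published accuracy experiment: per repetition the lower
#' dental cast is "arbitrarily moved" (a random rigid transform with
#' translations uniform within +/- `translation_range_mm` per axis and
#' rotations uniform within +/- `rotation_range_deg` per axis), the three
#' landmark moving distances are measured on the real cast (ground-truth
#' geometry) and on the virtual model through the full pipeline -- noisy
#' stylus digitization of the splint spheres, tracker-to-virtual
#' calibration, a noisy two-sample pose stream (reference pose and moved
#' pose), segment transform, landmark displacement -- and the per-landmark
#' absolute virtual-vs-real differences are tabulated. The summary has the
#' layout of the published accuracy table (average / sd / min / max per
#' landmark for virtual, real and absolute difference) plus a Wilcoxon
#' signed-rank test of virtual against real per landmark.
#'
#' @param n_repetitions number of repositionings (default 25).
#' @param noise_spec a [tracker_noise_spec()]; default the device band.
#' @param seed integer seed; the protocol is deterministic given it.
#' @param config a [phantom_config()] providing the arch landmarks and
#'   splint spheres.
#' @param translation_range_mm,rotation_range_deg half-widths of the
#'   uniform "arbitrary movement" distribution.
#' @return An object of class `accuracy_report`: `records` (one row per
#'   repetition x landmark), `summary` (average/sd/min/max), `wilcoxon`
#'   (per landmark), `n`.
#' @export
run_accuracy_protocol <- function(n_repetitions = 25L,
                                  noise_spec = device_band_noise_spec(),
                                  seed = 1L,
                                  config = phantom_config(),
                                  translation_range_mm = 10,
                                  rotation_range_deg = 10) {
  if (n_repetitions < 5) os_abort("need at least 5 repetitions", "invalid_argument")
  landmarks <- arch_landmark_points()
  spheres_virtual <- nominal_sphere_centers()
  # ground-truth tracker-to-virtual transform: the tracker sits in its own
  # frame, here a fixed generic pose relative to virtual space
  v_gt <- rigid_transform(euler_to_rotation(c(25, -10, 15)), c(180, -40, 60))
  v_inv <- invert_transform(v_gt)
  spheres_tracker <- apply_transform(v_inv, spheres_virtual)
  # receiver home pose in the tracker frame (arbitrary, cancels by design)
  p_ref <- rigid_transform(euler_to_rotation(c(5, 3, -8)), c(20, 15, -10))

  lm_names <- names(landmarks)
  rec <- list()
  for (rep_i in seq_len(n_repetitions)) {
    base_seed <- seed + 1000L * rep_i
    m_gt <- with_seed(base_seed, {
      rigid_transform(
        euler_to_rotation(runif(3, -rotation_range_deg, rotation_range_deg)),
        runif(3, -translation_range_mm, translation_range_mm))
    })
    # real measurement: ground-truth landmark displacement
    real_d <- landmark_moving_distance(
      landmarks, lapply(landmarks, function(p) apply_transform(m_gt, p)))
    # virtual measurement through the pipeline
    digitized <- digitize_spheres(spheres_tracker,
                                  config$sphere_diameter_mm,
                                  noise_spec = noise_spec,
                                  seed = base_seed + 1L)
    calib <- calibrate_splint(digitized, spheres_virtual)
    # cast poses in the tracker frame: home, then moved by the virtual
    # motion conjugated into the tracker frame
    p_cur <- compose_transforms(compose_transforms(v_inv, m_gt),
                                compose_transforms(v_gt, p_ref))
    motion <- function(t) if (t < 0.5 / 60) p_ref else p_cur
    stream <- simulate_tracker_stream(motion, duration_s = 2 / 60, rate_hz = 60,
                                      noise_spec = noise_spec,
                                      seed = base_seed + 2L)
    seg_tf <- cast_pose_to_segment_transform(stream_pose(stream, 2),
                                             stream_pose(stream, 1), calib)
    virt_d <- landmark_moving_distance(
      landmarks, lapply(landmarks, function(p) apply_transform(seg_tf, p)))
    rec[[rep_i]] <- data.frame(repetition = rep_i, landmark = lm_names,
                               virtual_mm = as.numeric(virt_d[lm_names]),
                               real_mm = as.numeric(real_d[lm_names]),
                               row.names = NULL)
  }
  records <- do.call(rbind, rec)
  records$abs_difference_mm <- abs(records$virtual_mm - records$real_mm)

  summarize <- function(x) c(average = mean(x), sd = sd(x),
                             minimum = min(x), maximum = max(x))
  summ <- do.call(rbind, lapply(lm_names, function(nm) {
    sub <- records[records$landmark == nm, ]
    data.frame(landmark = nm,
               measure = rep(c("virtual", "real", "abs_difference"), each = 4),
               statistic = rep(c("average", "sd", "minimum", "maximum"), 3),
               value_mm = c(summarize(sub$virtual_mm), summarize(sub$real_mm),
                            summarize(sub$abs_difference_mm)),
               row.names = NULL)
  }))
  wil <- lapply(setNames(lm_names, lm_names), function(nm) {
    sub <- records[records$landmark == nm, ]
    # differences below numerical measurement resolution count as ties
    wilcoxon_signed_rank(sub$virtual_mm, sub$real_mm, zero_tol = 1e-9)
  })
  structure(list(records = records, summary = summ, wilcoxon = wil,
                 n = n_repetitions, noise_spec = noise_spec, seed = seed),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d repositionings\n", x$n))
  for (nm in names(x$wilcoxon)) {
    sub <- x$summary[x$summary$landmark == nm, ]
    g <- function(measure, stat) sub$value_mm[sub$measure == measure &
                                                sub$statistic == stat]
    w <- x$wilcoxon[[nm]]
    sig <- if (isTRUE(w$degenerate)) "degenerate" else if (w$significant_5pct)
      "significant at 5%" else "n.s."
    cat(sprintf("  %-12s virtual %5.2f mm, real %5.2f mm, |diff| %5.3f mm (mean); Wilcoxon %s\n",
                nm, g("virtual", "average"), g("real", "average"),
                g("abs_difference", "average"), sig))
  }
  invisible(x)
}

#' Write an accuracy report as CSV (published-table layout)
#' @param report an `accuracy_report`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_accuracy_csv <- function(report, path) {
  write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}
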