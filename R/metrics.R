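#' Per-pixel squared-error map between two stacks
#'
#' @param stack_a,stack_b [flip_stack()]s of identical shape.
#' @return A [flip_stack()] of `(a - b)^2`.
#' @export
squared_error_map <- function(stack_a, stack_b) {
  check_stack(stack_a, "stack_a"); check_stack(stack_b, "stack_b")
  if (!all(dim(stack_a) == dim(stack_b)))
    stop("stacks have different shapes", call. = FALSE)
  flip_stack((stack_a$data - stack_b$data)^2, stack_a$dt)
}

#' Integrated (summed) intensity per frame
#'
#' @param stack a [flip_stack()].
#' @return Numeric vector, one total per frame.
#' @export
integrated_intensity <- function(stack) {
  check_stack(stack)
  apply(stack$data, 3, sum)
}

#' Peak signal-to-noise ratio between a clean reference and a test stack
#'
#' `10 log10(peak^2 / MSE)` with `peak` the maximum of the clean stack
#' (float stacks carry no canonical bit depth, so the data maximum is the
#' peak). Identical stacks give `Inf`.
#'
#' @param clean reference [flip_stack()] (not all-zero).
#' @param test [flip_stack()] of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(clean, test) {
  check_stack(clean, "clean"); check_stack(test, "test")
  if (!all(dim(clean) == dim(test)))
    stop("stacks have different shapes", call. = FALSE)
  peak <- max(clean$data)
  if (peak == 0) stop("'clean' stack is all zero", call. = FALSE)
  mse <- mean((clean$data - test$data)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Mean-intensity time course in a rectangular ROI
#'
#' @param stack a [flip_stack()].
#' @param box integer `c(row_min, row_max, col_min, col_max)`, 1-based
#'   inclusive.
#' @return Numeric vector, one mean per frame.
#' @export
roi_decay <- function(stack, box) {
  check_stack(stack)
  d <- dim(stack)
  if (length(box) != 4 || box[1] < 1 || box[3] < 1 ||
      box[2] > d[1] || box[4] > d[2] || box[1] > box[2] || box[3] > box[4])
    stop("ROI box out of bounds", call. = FALSE)
  apply(stack$data[box[1]:box[2], box[3]:box[4], , drop = FALSE], 3, mean)
}

#' Intensity profile along a line segment
#'
#' Bilinear sampling of one frame along the segment from `p0` to `p1`
#' (continuous 0-based `(x, y)` pixel coordinates).
#'
#' @param frame `height x width` matrix.
#' @param p0,p1 numeric `c(x, y)` endpoints.
#' @param n number of samples (default: one per pixel of length, min 2).
#' @return Data frame with `distance` (pixels from `p0`) and `intensity`.
#' @export
line_profile <- function(frame, p0, p1, n = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(n)) n <- max(2L, ceiling(len) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  if (any(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1))
    stop("line endpoints out of image bounds", call. = FALSE)
  x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(r, c) frame[cbind(r + 1, c + 1)]
  val <- (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x0 + 1) +
    (1 - fx) * fy * idx(y0 + 1, x0) + fx * fy * idx(y0 + 1, x0 + 1)
  data.frame(distance = tt * len, intensity = val)
}

#' Fit a stretched-exponential decay to an intensity trace
#'
#' Least-squares fit of `I(t) = I0 exp(-(t / tau)^h)` (Kohlrausch decay;
#' `h = 1` recovers a single exponential, `h < 1` indicates kinetic
#' heterogeneity). Initialization: `I0` = first sample, `tau` = time at
#' which the trace first falls to `I0/e` (linear interpolation, falling
#' back to the trace duration), `h = 1`; bounds `h` in `[0.2, 3]`,
#' `tau > 0`. The loss rate is reported with Table-style sign convention
#' as `rate = -1/tau`; the `h`-corrected mean time constant
#' `tau * gamma(1/h) / h` is also returned.
#'
#' @param trace positive intensity samples at uniform spacing `dt`.
#' @param dt sample interval (s).
#' @return Object of class `stretched_exp_fit`: list with `I0`, `tau`, `h`,
#'   `rate` (`-1/tau`, 1/s), `tau_mean`, `rss` and `converged`. A constant
#'   (no-decay) trace or a failed optimization is flagged
#'   `converged = FALSE` with `rss = Inf`.
#' @export
stretched_exp_fit <- function(trace, dt) {
  if (length(trace) < 5) stop("need at least 5 samples", call. = FALSE)
  if (any(trace <= 0)) stop("trace must be positive", call. = FALSE)
  tt <- (seq_along(trace) - 1) * dt
  failed <- function() structure(list(I0 = NA_real_, tau = NA_real_,
                                      h = NA_real_, rate = NA_real_,
                                      tau_mean = NA_real_, rss = Inf,
                                      converged = FALSE),
                                 class = "stretched_exp_fit")
  I0 <- trace[1]
  if (max(trace) - min(trace) < 1e-12 * max(trace)) return(failed())
  target <- I0 / exp(1)
  below <- which(trace <= target)
  tau0 <- if (length(below)) {
    i <- below[1]
    if (i == 1) max(tt[2], dt)
    else tt[i - 1] + dt * (trace[i - 1] - target) / (trace[i - 1] - trace[i])
  } else max(tt)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-(t / tau)^h),
                      data = data.frame(t = tt, y = trace),
                      start = list(I0 = I0, tau = tau0, h = 1),
                      lower = c(I0 = 0, tau = 1e-9, h = 0.2),
                      upper = c(I0 = Inf, tau = Inf, h = 3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- coef(fit)
  structure(list(I0 = unname(cf["I0"]), tau = unname(cf["tau"]),
                 h = unname(cf["h"]), rate = -1 / unname(cf["tau"]),
                 tau_mean = unname(cf["tau"]) * gamma(1 / cf["h"]) / cf["h"],
                 rss = sum(residuals(fit)^2), converged = TRUE),
            class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  if (!x$converged) cat("stretched-exponential fit: not converged\n")
  else cat(sprintf(
    "stretched-exponential fit: I0 = %.4g, tau = %.4g s, h = %.4g (rate %.5g 1/s)\n",
    x$I0, x$tau, x$h, x$rate))
  invisible(x)
}

#' Pixel-wise stretched-exponential parameter maps
#'
#' Fits [stretched_exp_fit()] to every pixel trace whose initial intensity
#' exceeds `floor_frac` of the first frame's maximum (skipping background),
#' optionally restricted to a mask.
#'
#' @param stack a [flip_stack()].
#' @param mask optional logical image restricting the fitted pixels.
#' @param floor_frac intensity floor as a fraction of the frame-1 maximum
#'   (default 0.02).
#' @return List of images `tau`, `h`, `rate` and logical `fitted`
#'   (unfitted/unconverged pixels are `NA`).
#' @export
stretched_exp_map <- function(stack, mask = NULL, floor_frac = 0.02) {
  check_stack(stack)
  d <- dim(stack)
  f1 <- stack$data[, , 1]
  sel <- f1 > floor_frac * max(f1)
  if (!is.null(mask)) sel <- sel & mask
  tau <- h <- rate <- matrix(NA_real_, d[1], d[2])
  fitted <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!sel[i, j]) next
    tr <- stack$data[i, j, ]
    if (any(tr <= 0)) tr <- pmax(tr, 1e-9 * max(tr))
    ft <- stretched_exp_fit(tr, stack$dt)
    if (ft$converged) {
      tau[i, j] <- ft$tau; h[i, j] <- ft$h; rate[i, j] <- ft$rate
      fitted[i, j] <- TRUE
    }
  }
  list(tau = tau, h = h, rate = rate, fitted = fitted)
}
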