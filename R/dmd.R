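#' Snapshot matrices of an image stack
#'
#' Each frame is flattened row-major into a column vector; the data matrix
#' `X` holds frames `1 ... k-1` and the time-shifted matrix `X_prime` holds
#' frames `2 ... k`, so that column `n` of `X_prime` is the image one frame
#' interval after column `n` of `X`.
#'
#' @param stack a [flip_stack()] with at least 3 frames.
#' @return Object of class `snapshot_pair`: list with `X`, `X_prime`
#'   (`n_pixels x (k-1)` matrices), `dt` and `image_shape`.
#' @export
stack_to_snapshots <- function(stack) {
  check_stack(stack)
  k <- n_frames(stack)
  if (k < 3) stop("need at least 3 frames to form a shifted snapshot pair",
                  call. = FALSE)
  h <- dim(stack)[1]; w <- dim(stack)[2]
  cols <- vapply(seq_len(k), function(n) as.vector(t(stack$data[, , n])),
                 numeric(h * w))
  structure(list(X = cols[, 1:(k - 1), drop = FALSE],
                 X_prime = cols[, 2:k, drop = FALSE],
                 dt = stack$dt, image_shape = c(h, w)),
            class = "snapshot_pair")
}

#' Rebuild an image stack from flattened snapshot columns
#'
#' Inverse of the flattening in [stack_to_snapshots()]: the round trip is
#' bit-identical.
#'
#' @param mat `n_pixels x n_frames` matrix of row-major flattened frames.
#' @param image_shape integer `c(height, width)`.
#' @param dt frame interval (s).
#' @return A [flip_stack()].
#' @export
snapshots_to_stack <- function(mat, image_shape, dt) {
  h <- image_shape[1]; w <- image_shape[2]
  if (nrow(mat) != h * w)
    stop("matrix rows do not match image_shape", call. = FALSE)
  arr <- array(0, c(h, w, ncol(mat)))
  for (n in seq_len(ncol(mat))) arr[, , n] <- t(matrix(mat[, n], w, h))
  flip_stack(arr, dt)
}

unflatten <- function(v, image_shape) {
  t(matrix(v, image_shape[2], image_shape[1]))
}

#' Optimal hard threshold for singular-value truncation
#'
#' Gavish-Donoho rule for unknown noise level: retain singular values above
#' `tau = omega(beta) * median(singular values)` with aspect ratio
#' `beta = min(n, m)/max(n, m)` and the published polynomial approximation
#' `omega(beta) = 0.56 beta^3 - 0.95 beta^2 + 1.82 beta + 1.43`. At least
#' one singular value is always retained.
#'
#' @param singular_values full spectrum, descending.
#' @param n_rows,n_cols dimensions of the decomposed matrix.
#' @return Integer rank `r >= 1`.
#' @export
optimal_rank <- function(singular_values, n_rows, n_cols) {
  if (length(singular_values) == 0)
    stop("empty singular-value spectrum", call. = FALSE)
  beta <- min(n_rows, n_cols) / max(n_rows, n_cols)
  omega <- 0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
  tau <- omega * median(singular_values)
  max(1L, sum(singular_values > tau))
}

#' Rescale discrete DMD eigenvalues to continuous rates
#'
#' `omega = log(lambda) / dt` using the principal branch of the complex
#' logarithm, so `Im(omega)` lies in `(-pi/dt, pi/dt]`. Eigenvalues on the
#' negative real axis alias an oscillation at the Nyquist frequency and
#' trigger a warning.
#'
#' @param lam complex (or numeric) eigenvalues; none may be 0.
#' @param dt frame interval (s), > 0.
#' @return Complex vector of continuous eigenvalues (1/s).
#' @examples
#' Re(rescale_eigenvalues(0.996257, dt = 1))  # -0.00375
#' @export
rescale_eigenvalues <- function(lam, dt) {
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  lam <- as.complex(lam)
  if (any(Mod(lam) == 0))
    stop("zero eigenvalue: infinitely fast decay (excluded by rank truncation)",
         call. = FALSE)
  if (any(Im(lam) == 0 & Re(lam) < 0))
    warning("eigenvalue on the negative real axis: principal-branch log ",
            "yields a Nyquist-aliased oscillation", call. = FALSE)
  log(lam) / dt
}

#' Exact dynamic mode decomposition of a FLIP image stack
#'
#' Forms the shifted snapshot matrices, takes the SVD of `X`, truncates at
#' `rank` (or at the Gavish-Donoho optimal hard threshold when
#' `rank = "optimal"`), builds the rank-reduced propagator
#' `A' = U_r* X' V_r S_r^-1`, and eigendecomposes it. Modes are by default
#' the exact-DMD modes `Phi = X' V_r S_r^-1 W`; `mode_type = "projected"`
#' gives `Phi = U_r W`. Amplitudes `b` solve the least-squares problem
#' `Phi b ~ x_1` against the first snapshot. Continuous eigenvalues are
#' `omega = log(lambda)/dt`. Modes are ordered by `|omega|` ascending
#' (slowest first); this ordering defines mode 1, 2, ... in all outputs.
#'
#' @param stack a [flip_stack()] with at least 3 frames.
#' @param rank `"optimal"` or a positive integer `<= k - 1`.
#' @param mode_type `"exact"` or `"projected"`.
#' @return Object of class `dmd_model`: list with `Phi` (complex
#'   `n_pixels x r`), `lam`, `omega`, `b` (complex length `r`), `dt`,
#'   `image_shape`, `rank`, `n_frames`, `mode_type` and `singular_values`
#'   (full spectrum of `X`).
#' @export
dmd <- function(stack, rank = "optimal", mode_type = c("exact", "projected")) {
  mode_type <- match.arg(mode_type)
  snaps <- stack_to_snapshots(stack)
  X <- snaps$X; Xp <- snaps$X_prime
  if (max(abs(X)) == 0)
    stop("all-zero stack: nothing to decompose", call. = FALSE)
  sv <- svd(X)
  m <- ncol(X)
  r <- if (identical(rank, "optimal")) {
    # cap at the numerical rank: the hard threshold is median-based and can
    # otherwise retain numerically-zero directions of exactly low-rank data
    min(optimal_rank(sv$d, nrow(X), m),
        max(1L, sum(sv$d > sv$d[1] * 1e-12)))
  } else {
    rank <- as.integer(rank)
    if (is.na(rank) || rank < 1 || rank > m)
      stop("'rank' must be in 1..k-1 or \"optimal\"", call. = FALSE)
    rank
  }
  if (sv$d[r] <= max(sv$d) * 1e-13)
    stop("singular value ", r, " is numerically zero; use a lower rank",
         call. = FALSE)
  Ur <- sv$u[, 1:r, drop = FALSE]
  Vr <- sv$v[, 1:r, drop = FALSE]
  XpVS <- Xp %*% sweep(Vr, 2, sv$d[1:r], `/`)
  Atilde <- crossprod(Ur, XpVS)
  eig <- eigen(Atilde)
  W <- matrix(as.complex(eig$vectors), r, r)
  lam <- as.complex(eig$values)
  Phi <- if (mode_type == "exact") XpVS %*% W else Ur %*% W
  # amplitudes: least squares against the first snapshot (normal equations,
  # r is small)
  PhH <- Conj(t(Phi))
  b <- solve(PhH %*% Phi, PhH %*% as.complex(X[, 1]))[, 1]
  omega <- rescale_eigenvalues(lam, snaps$dt)
  ord <- order(Mod(omega))
  structure(list(Phi = Phi[, ord, drop = FALSE], lam = lam[ord],
                 omega = omega[ord], b = b[ord], dt = snaps$dt,
                 image_shape = snaps$image_shape, rank = r,
                 n_frames = n_frames(stack), mode_type = mode_type,
                 singular_values = sv$d),
            class = "dmd_model")
}

#' @export
print.dmd_model <- function(x, ...) {
  cat(sprintf("DMD model: rank %d (%s modes), %dx%d px, %d frames, dt = %g s\n",
              x$rank, x$mode_type, x$image_shape[1], x$image_shape[2],
              x$n_frames, x$dt))
  cat("  modes (slowest first):\n")
  for (j in seq_len(x$rank))
    cat(sprintf("   %2d: omega = %+.5f%+.5fi 1/s  |lambda| = %.5f\n",
                j, Re(x$omega[j]), Im(x$omega[j]), Mod(x$lam[j])))
  invisible(x)
}

check_model <- function(model) {
  if (!inherits(model, "dmd_model"))
    stop("'model' must be a dmd_model", call. = FALSE)
  model
}

# complex mode expansion evaluated at (1-based) frame numbers
expand_modes <- function(model, frames, modes = seq_len(model$rank),
                         continuous = FALSE) {
  p <- prod(model$image_shape)
  arr <- array(0, c(model$image_shape, length(frames)))
  Phi <- model$Phi[, modes, drop = FALSE]
  for (i in seq_along(frames)) {
    n <- frames[i]
    temporal <- if (continuous)
      exp(model$omega[modes] * (n - 1) * model$dt) * model$b[modes]
    else
      model$lam[modes]^(n - 1) * model$b[modes]
    v <- as.vector(Phi %*% temporal)
    arr[, , i] <- unflatten(Re(v), model$image_shape)
  }
  arr
}

#' Reconstruct frames from a DMD model
#'
#' Evaluates the mode expansion `x_n = sum_j phi_j lambda_j^(n-1) b_j`
#' (real part) at the requested frame numbers; frame 1 is the first fitted
#' snapshot. The equivalent continuous form `sum_j phi_j e^(omega_j t) b_j`
#' at `t = (n - 1) dt` agrees to numerical precision.
#'
#' @param model a [dmd()] model.
#' @param frames 1-based frame numbers (defaults to all fitted frames;
#'   indices beyond the fitted window extrapolate).
#' @param continuous evaluate the continuous-time form instead of powers of
#'   `lambda` (the two agree to ~1e-10).
#' @return A [flip_stack()].
#' @export
dmd_reconstruct <- function(model, frames = NULL, continuous = FALSE) {
  check_model(model)
  if (is.null(frames)) frames <- seq_len(model$n_frames)
  flip_stack(expand_modes(model, frames, continuous = continuous), model$dt)
}

#' Predict future frames beyond the fitted window
#'
#' Extrapolates the fitted exponentials to frames
#' `n_frames + 1 ... n_frames + n_future`. Growing modes
#' (`|lambda| > 1 + 1e-6`) make extrapolation unreliable and trigger a
#' warning.
#'
#' @param model a [dmd()] model.
#' @param n_future number of frames past the end of the fitted stack.
#' @return A [flip_stack()] of the predicted frames.
#' @export
dmd_predict <- function(model, n_future) {
  check_model(model)
  if (n_future < 1) stop("'n_future' must be >= 1", call. = FALSE)
  if (any(Mod(model$lam) > 1 + 1e-6))
    warning("model contains growing modes (|lambda| > 1); ",
            "extrapolation is unreliable", call. = FALSE)
  frames <- model$n_frames + seq_len(n_future)
  flip_stack(expand_modes(model, frames), model$dt)
}
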