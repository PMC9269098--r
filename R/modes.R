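#' 2-D map of a dynamic mode
#'
#' Reshapes mode `phi_j` to the image grid and splits it into real and
#' imaginary images. For stacks with no oscillation or lateral motion the
#' imaginary part is zero (to numerical precision). Maps are exported in
#' the stack's native orientation.
#'
#' @param model a [dmd()] model.
#' @param j mode number, 1-based, slowest (`|omega|` smallest) first.
#' @return List with `map_real` and `map_imag` matrices.
#' @export
mode_map <- function(model, j) {
  check_model(model)
  if (j < 1 || j > model$rank) stop("mode index out of range", call. = FALSE)
  v <- model$Phi[, j]
  list(map_real = unflatten(Re(v), model$image_shape),
       map_imag = unflatten(Im(v), model$image_shape))
}

#' Temporal dynamics of a mode
#'
#' The complex series `b_j * lambda_j^(n-1)` for frames `n = 1 ... n_frames`
#' (the mode-decay curves plotted against the unit circle spectrum).
#'
#' @inheritParams mode_map
#' @param n_frames number of frames to evaluate (default: fitted length).
#' @return Complex vector of length `n_frames`.
#' @export
mode_dynamics <- function(model, j, n_frames = model$n_frames) {
  check_model(model)
  if (j < 1 || j > model$rank) stop("mode index out of range", call. = FALSE)
  model$b[j] * model$lam[j]^(seq_len(n_frames) - 1)
}

#' Unit-circle eigenvalue table
#'
#' One row per mode with the discrete eigenvalue's real and imaginary
#' parts, modulus, continuous rate and a flag for decaying dynamics
#' (`|lambda| <= 1` within tolerance).
#'
#' @param model a [dmd()] model.
#' @param tol tolerance on `|lambda| <= 1` for the `decaying` flag.
#' @return Data frame with columns `mode_index` (1-based), `re_lambda`,
#'   `im_lambda`, `mod_lambda`, `re_omega`, `im_omega`, `decaying`.
#' @export
eigenvalue_circle <- function(model, tol = 1e-6) {
  check_model(model)
  data.frame(mode_index = seq_len(model$rank),
             re_lambda = Re(model$lam), im_lambda = Im(model$lam),
             mod_lambda = Mod(model$lam),
             re_omega = Re(model$omega), im_omega = Im(model$omega),
             decaying = Mod(model$lam) <= 1 + tol)
}

#' Per-mode reconstruction stack
#'
#' Time evolution `Re(phi_j lambda_j^(n-1) b_j)` of one mode (or the sum of
#' several). By linearity the sum of all single-mode stacks equals the full
#' reconstruction exactly.
#'
#' @inheritParams mode_dynamics
#' @param j mode number or vector of mode numbers (summed).
#' @return A [flip_stack()].
#' @export
mode_stack <- function(model, j, n_frames = model$n_frames) {
  check_model(model)
  if (any(j < 1 | j > model$rank))
    stop("mode index out of range", call. = FALSE)
  flip_stack(expand_modes(model, seq_len(n_frames), modes = j), model$dt)
}

#' Assign modes to labelled regions
#'
#' For each mode, the fraction of its `|Re(phi)|` mass (default; `"abs"`
#' uses `|phi|`) falling in each region mask; a mode is labelled with the
#' argmax region. The absolute-real-part metric makes the assignment
#' insensitive to the sign structure of the mode maps. Ties are broken
#' toward the earlier region in `region_masks`, with a warning. A mode is
#' additionally classified `"stable"` when `Re(omega)` lies within
#' `stable_band` of zero (default `[-1e-4, 0]` 1/s, i.e. essentially no
#' fluorescence loss: an immobile/non-exchanging pool or an unbleached
#' cell), and `"exchanging"` when it decays faster.
#'
#' @param model a [dmd()] model.
#' @param region_masks named list of logical masks on the image grid.
#' @param metric `"abs_re"` (default) or `"abs"`.
#' @param stable_band numeric `c(lo, hi)` band of `Re(omega)` (1/s)
#'   reported as "stable".
#' @return Data frame with one row per mode: `mode_index`, `re_omega`,
#'   `im_omega`, `mod_lambda`, one fraction column per region, `label`,
#'   `classification`.
#' @export
assign_modes_to_regions <- function(model, region_masks,
                                    metric = c("abs_re", "abs"),
                                    stable_band = c(-1e-4, 0)) {
  check_model(model)
  metric <- match.arg(metric)
  if (length(region_masks) == 0 || is.null(names(region_masks)))
    stop("'region_masks' must be a non-empty named list", call. = FALSE)
  p <- prod(model$image_shape)
  flat <- lapply(region_masks, function(m) {
    if (!is.logical(m) || !all(dim(m) == model$image_shape))
      stop("each mask must be a logical image of the model's shape",
           call. = FALSE)
    if (!any(m)) stop("empty region mask", call. = FALSE)
    as.vector(t(m))
  })
  rows <- lapply(seq_len(model$rank), function(j) {
    mass <- if (metric == "abs_re") abs(Re(model$Phi[, j]))
            else Mod(model$Phi[, j])
    tot <- sum(mass)
    fr <- vapply(flat, function(m) sum(mass[m]) / tot, numeric(1))
    best <- which(fr == max(fr))
    if (length(best) > 1)
      warning("tied region assignment for mode ", j,
              "; taking the earlier region", call. = FALSE)
    cls <- if (Re(model$omega[j]) >= stable_band[1] &&
               Re(model$omega[j]) <= stable_band[2] + 1e-9)
      "stable" else "exchanging"
    c(list(mode_index = j, re_omega = Re(model$omega[j]),
           im_omega = Im(model$omega[j]), mod_lambda = Mod(model$lam[j])),
      as.list(fr), list(label = names(flat)[best[1]], classification = cls))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
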