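#' Scene geometry helpers
#'
#' Pixel coordinates are 0-based and continuous, `x` along columns and `y`
#' along rows; the pixel at row `i`, column `j` (1-based array indices) has
#' center `(x, y) = (j - 1, i - 1)`.
#'
#' @param shape integer `c(height, width)`.
#' @param cx,cy center (pixels, 0-based).
#' @param a,b ellipse semi-axes along x and y (pixels).
#' @return Logical `height x width` mask.
#' @export
ellipse_mask <- function(shape, cx, cy, a, b) {
  h <- shape[1]; w <- shape[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Anti-aliased disk coverage image
#'
#' Area-weighted rasterization of a disk at a continuous center: coverage
#' ramps linearly from 1 to 0 across the one-pixel-wide rim
#' (`clamp(radius - distance + 0.5, 0, 1)`), which avoids intensity flicker
#' when a disk moves by sub-pixel amounts.
#'
#' @inheritParams ellipse_mask
#' @param r disk radius (pixels).
#' @return Numeric `height x width` coverage image in `[0, 1]`.
#' @export
disk_coverage <- function(shape, cx, cy, r) {
  h <- shape[1]; w <- shape[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  pmin(pmax(r - d + 0.5, 0), 1)
}

#' Per-axis Brownian step width in pixels
#'
#' For normal diffusion with coefficient `D` and time step `dt`, per-axis
#' displacements are Gaussian with standard deviation `sqrt(2 D dt)`;
#' dividing by the pixel size gives the step width in pixels. Step sampling
#' in the simulator draws these deviates by the Box-Muller transform of two
#' uniform variates.
#'
#' @param D diffusion coefficient (µm^2/s), >= 0.
#' @param dt time step (s), >= 0.
#' @param pixel_size pixel size (µm/pixel), > 0.
#' @return Step standard deviation in pixels.
#' @examples
#' brownian_sigma_px(0.004, 1, 0.125)  # 0.71554 px
#' @export
brownian_sigma_px <- function(D, dt, pixel_size) {
  if (D < 0 || dt < 0) stop("'D' and 'dt' must be >= 0", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be > 0", call. = FALSE)
  sqrt(2 * D * dt) / pixel_size
}

#' Standard Gaussian deviates via the Box-Muller transform
#'
#' Draws `n` N(0, 1) deviates from pairs of uniform variates:
#' `z1 = sqrt(-2 log u1) cos(2 pi u2)`, `z2 = sqrt(-2 log u1) sin(2 pi u2)`.
#' Consumes the current RNG stream.
#'
#' @param n number of deviates.
#' @return Numeric vector of length `n`.
#' @export
box_muller <- function(n) {
  m <- ceiling(n / 2)
  u1 <- runif(m); u2 <- runif(m)
  rad <- sqrt(-2 * log(u1)); ang <- 2 * pi * u2
  z <- rbind(rad * cos(ang), rad * sin(ang))
  z[seq_len(n)]
}

#' Simulate a Brownian (plus optional flow) track in pixel coordinates
#'
#' Positions advance by Box-Muller Gaussian steps of per-axis width
#' [brownian_sigma_px()]; a constant flow `v` (µm per frame) is subtracted
#' from the x coordinate each step (directed motion in the negative x
#' direction). Consumes the current RNG stream.
#'
#' @param n_steps number of steps (track has `n_steps + 1` positions).
#' @param D diffusion coefficient (µm^2/s).
#' @param v flow speed (µm/frame, applied along -x).
#' @param dt time per step (s).
#' @param pixel_size µm per pixel.
#' @param origin starting `c(x, y)` in pixels.
#' @return `(n_steps + 1) x 2` matrix of `x`, `y` positions (pixels).
#' @export
simulate_track <- function(n_steps, D, v = 0, dt = 1, pixel_size = 0.125,
                           origin = c(0, 0)) {
  sig <- brownian_sigma_px(D, dt, pixel_size)
  steps <- matrix(0, n_steps, 2)
  if (sig > 0) steps <- matrix(box_muller(2 * n_steps) * sig, n_steps, 2)
  steps[, 1] <- steps[, 1] - v / pixel_size
  pos <- apply(steps, 2, cumsum)
  rbind(origin, sweep(matrix(pos, n_steps, 2), 2, origin, `+`))
}

noise_params <- function(model = c("none", "gaussian", "poisson"),
                         sigma = 0.02, photon_scale = 100) {
  model <- match.arg(model)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (photon_scale <= 0) stop("'photon_scale' must be > 0", call. = FALSE)
  list(model = model, sigma = sigma, photon_scale = photon_scale)
}

scene_presets <- c("basic", "with_neighbor", "mobile_aggregate",
                   "flow_aggregate")

#' Synthetic FLIP scene presets
#'
#' Builds a fully specified, seeded simulation scene: a 128 x 128 px image
#' (0.125 µm/pixel), dt = 1 s, 300 frames, an elliptical cell with an
#' elliptical nucleus, three circular cytoplasmic aggregates of radii 2, 4
#' and 6 px, and a circular bleach ROI (radius 5 px) in the cytoplasm.
#' Compartment kinetics default to symmetric nucleo-cytoplasmic exchange
#' `k1 = k_m1 = 0.016194`, aggregate release `k2 = 0.005` and bleach rate
#' `k3 = 0.617582` (1/s), starting from uniform unit intensity. Presets:
#'
#' * `basic`: static scene, no neighbor cell.
#' * `with_neighbor`: adds an unbleached neighboring cell of constant
#'   intensity (the bleached cell is shifted left to make room).
#' * `mobile_aggregate`: the smallest aggregate diffuses with
#'   `D = 0.004` µm^2/s.
#' * `flow_aggregate`: the smallest aggregate moves with a constant flow of
#'   `v = 0.00625` µm/frame (5% of a pixel) in the negative x direction.
#'
#' @param preset one of `"basic"`, `"with_neighbor"`, `"mobile_aggregate"`,
#'   `"flow_aggregate"`.
#' @param n_frames number of frames.
#' @param dt frame interval (s).
#' @param rates a [rate_constants()] object.
#' @param init named initial intensities `c(A, C, N)`.
#' @param noise list from `noise_params()`-style fields: `model`
#'   (`"none"`, `"gaussian"`, `"poisson"`), `sigma` (Gaussian sd as a
#'   fraction of the initial maximum intensity; default 0.02) and
#'   `photon_scale` (counts per intensity unit for Poisson noise).
#' @param seed integer RNG seed; identical scenes render bit-identically.
#' @return An object of class `flip_scene`.
#' @export
flip_scene <- function(preset = c("basic", "with_neighbor",
                                  "mobile_aggregate", "flow_aggregate"),
                       n_frames = 300L, dt = 1,
                       rates = rate_constants(k1 = 0.016194, k_m1 = 0.016194,
                                              k2 = 0.005, k3 = 0.617582),
                       init = c(A = 1, C = 1, N = 1),
                       noise = list(model = "gaussian", sigma = 0.02),
                       seed = 1L) {
  if (is.character(preset) && length(preset) == 1L &&
      !preset %in% scene_presets)
    stop("unknown preset '", preset, "'; available presets: ",
         paste(scene_presets, collapse = ", "), call. = FALSE)
  preset <- match.arg(preset)
  shape <- c(128L, 128L)
  noise <- do.call(noise_params, noise)
  neighbor <- NULL
  if (preset == "with_neighbor") {
    cell <- ellipse_mask(shape, 44, 64, 32, 38)
    nucleus <- ellipse_mask(shape, 34, 64, 11, 10)
    aggregates <- data.frame(x = c(58, 62, 54), y = c(44, 66, 90),
                             radius = c(2, 4, 6), mobile = FALSE)
    bleach <- disk_coverage(shape, 44, 32, 5) > 0.5
    neighbor <- ellipse_mask(shape, 102, 64, 22, 30)
  } else {
    cell <- ellipse_mask(shape, 64, 64, 46, 40)
    nucleus <- ellipse_mask(shape, 46, 64, 15, 12)
    aggregates <- data.frame(x = c(88, 92, 82), y = c(42, 66, 92),
                             radius = c(2, 4, 6), mobile = FALSE)
    bleach <- disk_coverage(shape, 64, 30, 5) > 0.5
  }
  motion <- list(D = 0, v = 0)
  if (preset == "mobile_aggregate") {
    aggregates$mobile[which.min(aggregates$radius)] <- TRUE
    motion$D <- 0.004
  } else if (preset == "flow_aggregate") {
    aggregates$mobile[which.min(aggregates$radius)] <- TRUE
    motion$v <- 0.00625
  }
  structure(list(preset = preset, image_shape = shape, pixel_size = 0.125,
                 dt = dt, n_frames = as.integer(n_frames),
                 cell_mask = cell, nucleus_mask = nucleus,
                 bleach_roi_mask = bleach, neighbor_cell_mask = neighbor,
                 aggregates = aggregates, init = init,
                 rates = as_rates(rates), motion = motion, noise = noise,
                 seed = as.integer(seed)),
            class = "flip_scene")
}

#' @export
print.flip_scene <- function(x, ...) {
  cat(sprintf("FLIP scene '%s': %dx%d px (%g um/px), %d frames, dt = %g s\n",
              x$preset, x$image_shape[1], x$image_shape[2], x$pixel_size,
              x$n_frames, x$dt))
  cat(sprintf("  %d aggregates (radii %s px)%s; noise %s; seed %d\n",
              nrow(x$aggregates),
              paste(x$aggregates$radius, collapse = "/"),
              if (is.null(x$neighbor_cell_mask)) "" else "; neighbor cell",
              x$noise$model, x$seed))
  invisible(x)
}

# Run code under a scene seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Render a synthetic FLIP image stack
#'
#' Evaluates the compartment model at each frame time `t = (n - 1) dt` and
#' paints: nucleus pixels with `N(t)`, cytoplasm (including the bleach ROI,
#' which is part of the cytoplasmic pool) with `C(t)`, aggregate disks with
#' `A(t)` (anti-aliased rims blend into the cytoplasm), the optional
#' neighbor cell with its constant initial intensity, and background 0.
#' Mobile aggregates follow a Box-Muller Brownian walk with optional flow
#' (all motion tracks are drawn first from the seeded stream, then noise,
#' frame by frame); moves that would push a disk outside the cell are
#' rejected, with one warning per run. Gaussian noise has standard deviation
#' `sigma * max(initial frame)`; Poisson noise replaces each pixel with
#' `rpois(value * photon_scale) / photon_scale`.
#'
#' @param scene a [flip_scene()].
#' @return An object of class `flip_sim`: list with `stack` (noisy
#'   [flip_stack()]), `clean` (noise-free ground truth), `centers`
#'   (data frame of per-frame aggregate centers) and `scene`.
#' @export
render_stack <- function(scene) {
  if (!inherits(scene, "flip_scene"))
    stop("'scene' must be a flip_scene", call. = FALSE)
  shape <- scene$image_shape
  k <- scene$n_frames
  times <- (seq_len(k) - 1) * scene$dt
  traj <- solve_compartments(scene$rates, scene$init, times)
  cyto <- scene$cell_mask & !scene$nucleus_mask
  nagg <- nrow(scene$aggregates)
  with_local_seed(scene$seed, {
    # aggregate center tracks (motion stream first, then noise stream)
    tracks <- vector("list", nagg)
    warned <- FALSE
    for (a in seq_len(nagg)) {
      ag <- scene$aggregates[a, ]
      if (ag$mobile && (scene$motion$D > 0 || scene$motion$v > 0)) {
        tr <- simulate_track(k - 1, scene$motion$D, scene$motion$v,
                             scene$dt, scene$pixel_size,
                             origin = c(ag$x, ag$y))
        # reject moves whose disk support leaves the cell
        for (n in 2:nrow(tr)) {
          cov <- disk_coverage(shape, tr[n, 1], tr[n, 2], ag$radius)
          if (any(cov[!scene$cell_mask] > 0)) {
            if (!warned) {
              warning("mobile aggregate clipped at the cell boundary",
                      call. = FALSE)
              warned <- TRUE
            }
            tr[n, ] <- tr[n - 1, ] + c(-scene$motion$v / scene$pixel_size, 0)
          }
        }
        tracks[[a]] <- tr
      } else {
        tracks[[a]] <- matrix(rep(c(ag$x, ag$y), each = k), k, 2)
      }
    }
    static_cov <- lapply(seq_len(nagg), function(a) {
      ag <- scene$aggregates[a, ]
      if (ag$mobile) NULL
      else disk_coverage(shape, ag$x, ag$y, ag$radius)
    })
    clean <- array(0, c(shape, k))
    for (n in seq_len(k)) {
      fr <- matrix(0, shape[1], shape[2])
      fr[cyto] <- traj[n, "C"]
      fr[scene$nucleus_mask] <- traj[n, "N"]
      for (a in seq_len(nagg)) {
        cov <- if (is.null(static_cov[[a]]))
          disk_coverage(shape, tracks[[a]][n, 1], tracks[[a]][n, 2],
                        scene$aggregates$radius[a])
        else static_cov[[a]]
        fr <- fr * (1 - cov) + cov * traj[n, "A"]
      }
      fr[!scene$cell_mask] <- 0
      if (!is.null(scene$neighbor_cell_mask))
        fr[scene$neighbor_cell_mask] <- unname(scene$init["C"])
      clean[, , n] <- fr
    }
    noisy <- clean
    if (scene$noise$model == "gaussian" && scene$noise$sigma > 0) {
      sdev <- scene$noise$sigma * max(clean[, , 1])
      noisy <- clean + array(rnorm(length(clean), 0, sdev), dim(clean))
    } else if (scene$noise$model == "poisson") {
      sc <- scene$noise$photon_scale
      noisy <- array(rpois(length(clean), pmax(clean, 0) * sc) / sc,
                     dim(clean))
    }
    centers <- do.call(rbind, lapply(seq_len(nagg), function(a)
      data.frame(frame = seq_len(k), aggregate = a,
                 x = tracks[[a]][, 1], y = tracks[[a]][, 2])))
    structure(list(stack = flip_stack(noisy, scene$dt),
                   clean = flip_stack(clean, scene$dt),
                   centers = centers, scene = scene),
              class = "flip_sim")
  })
}

#' @export
print.flip_sim <- function(x, ...) {
  cat("FLIP simulation (noisy stack + clean ground truth)\n")
  print(x$scene)
  invisible(x)
}

#' Region masks of a scene
#'
#' Named list of the region masks used for mode-to-region assignment:
#' `aggregates` (union of aggregate disks at their initial positions),
#' `nucleus`, `cytoplasm` (cell minus nucleus minus aggregates) and, when
#' present, `neighbor`.
#'
#' @param scene a [flip_scene()].
#' @return Named list of logical masks.
#' @export
scene_region_masks <- function(scene) {
  shape <- scene$image_shape
  agg <- Reduce(`|`, lapply(seq_len(nrow(scene$aggregates)), function(a)
    disk_coverage(shape, scene$aggregates$x[a], scene$aggregates$y[a],
                  scene$aggregates$radius[a]) > 0.5))
  out <- list(aggregates = agg,
              nucleus = scene$nucleus_mask,
              cytoplasm = scene$cell_mask & !scene$nucleus_mask & !agg)
  if (!is.null(scene$neighbor_cell_mask))
    out$neighbor <- scene$neighbor_cell_mask
  out
}
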