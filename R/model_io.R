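#' Write / read a DMD model archive
#'
#' The archive is a directory of portable files: the complex mode matrix as
#' paired real/imaginary multi-page TIFFs (`Phi_re.tif`, `Phi_im.tif`, one
#' page per mode, affinely rescaled to `[0, 1]` with the affine recorded in
#' the metadata), a `modes.csv` eigenvalue/amplitude table and a
#' `model.json` metadata block (`dt`, shape, rank, eigenvalues, amplitudes,
#' singular values). The round trip preserves `lam`, `omega` and `b`
#' exactly and `Phi` to float32 precision.
#'
#' @param model a [dmd()] model.
#' @param dir archive directory (created if needed).
#' @return `dir` (`write`), or the restored `dmd_model` (`read`).
#' @export
write_dmd_model <- function(model, dir) {
  check_model(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_part <- function(M, file) {
    lo <- min(M); hi <- max(M)
    span <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(ncol(M)), function(j)
      (unflatten(M[, j], model$image_shape) - lo) / span)
    tiff::writeTIFF(pages, file.path(dir, file), bits.per.sample = 32L,
                    reduce = FALSE)
    c(lo = lo, span = span)
  }
  aff_re <- write_part(Re(model$Phi), "Phi_re.tif")
  aff_im <- write_part(Im(model$Phi), "Phi_im.tif")
  meta <- list(dt = model$dt, image_shape = model$image_shape,
               rank = model$rank, n_frames = model$n_frames,
               mode_type = model$mode_type,
               lam_re = Re(model$lam), lam_im = Im(model$lam),
               b_re = Re(model$b), b_im = Im(model$b),
               singular_values = model$singular_values,
               phi_re_affine = as.list(aff_re),
               phi_im_affine = as.list(aff_im))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  export_modes_csv(model, file.path(dir, "modes.csv"))
  invisible(dir)
}

#' @rdname write_dmd_model
#' @export
read_dmd_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$image_shape)
  read_part <- function(file, aff) {
    pages <- tiff::readTIFF(file.path(dir, file), all = TRUE)
    vapply(pages, function(pg) as.vector(t(pg)) * aff$span + aff$lo,
           numeric(prod(shape)))
  }
  Phi <- read_part("Phi_re.tif", meta$phi_re_affine) +
    1i * read_part("Phi_im.tif", meta$phi_im_affine)
  lam <- complex(real = meta$lam_re, imaginary = meta$lam_im)
  structure(list(Phi = Phi, lam = lam,
                 omega = log(lam) / meta$dt,
                 b = complex(real = meta$b_re, imaginary = meta$b_im),
                 dt = meta$dt, image_shape = shape, rank = meta$rank,
                 n_frames = meta$n_frames, mode_type = meta$mode_type,
                 singular_values = meta$singular_values),
            class = "dmd_model")
}

#' Export the mode table as CSV
#'
#' Columns: `mode_index` (0-based, matching the field's mode-0 naming),
#' `re_omega`, `im_omega`, `mod_lambda`, `re_b`, `im_b`.
#'
#' @param model a [dmd()] model.
#' @param path output CSV path.
#' @export
export_modes_csv <- function(model, path) {
  check_model(model)
  df <- data.frame(mode_index = seq_len(model$rank) - 1L,
                   re_omega = Re(model$omega), im_omega = Im(model$omega),
                   mod_lambda = Mod(model$lam),
                   re_b = Re(model$b), im_b = Im(model$b))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
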