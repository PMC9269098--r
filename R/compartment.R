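#' Rate constants of the three-compartment FLIP model
#'
#' The bleach-limited FLIP kinetics of a cell with cytoplasmic protein
#' aggregates are described by three well-mixed compartments: aggregates
#' `A`, cytoplasm `C` and nucleus `N`. Protein exchanges between cytoplasm
#' and nucleus with rates `k1` (C -> N) and `k_m1` (N -> C), is slowly
#' released from aggregates into the cytoplasm with rate `k2` (no
#' rebinding), and is removed from the cytoplasmic pool by repeated
#' photobleaching with effective rate `k3`.
#'
#' @param k1 cytoplasm-to-nucleus exchange rate (1/s).
#' @param k_m1 nucleus-to-cytoplasm exchange rate (1/s).
#' @param k2 aggregate release rate (1/s).
#' @param k3 effective bleach rate acting on the cytoplasmic pool (1/s).
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(k1 = 0.016194, k_m1 = 0.016194, k2 = 0.005, k3 = 0.617582)
#' @export
rate_constants <- function(k1 = 0, k_m1 = 0, k2 = 0, k3 = 0) {
  r <- c(k1 = k1, k_m1 = k_m1, k2 = k2, k3 = k3)
  if (!is.numeric(r) || length(r) != 4L || anyNA(r) || any(!is.finite(r)))
    stop("rate constants must be finite numbers", call. = FALSE)
  if (any(r < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  structure(as.list(r), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("FLIP rate constants (1/s):\n")
  cat(sprintf("  k1 = %g  k_m1 = %g  k2 = %g  k3 = %g\n",
              x$k1, x$k_m1, x$k2, x$k3))
  invisible(x)
}

as_rates <- function(rates) {
  if (inherits(rates, "rate_constants")) return(rates)
  if (is.numeric(rates) && !is.null(names(rates)))
    return(do.call(rate_constants, as.list(rates)))
  if (is.list(rates)) return(do.call(rate_constants, rates))
  stop("'rates' must be a rate_constants object or named list/vector",
       call. = FALSE)
}

#' System matrix of the compartment ODEs
#'
#' Builds the 3x3 matrix `M` of the linear system
#' `d[A, C, N]/dt = M %*% c(A, C, N)`:
#' `dA/dt = -k2 A`; `dC/dt = k2 A - (k1 + k3) C + k_m1 N`;
#' `dN/dt = k1 C - k_m1 N`. Mass leaves the system only through bleaching,
#' so column sums are 0 except the C column, which sums to `-k3`.
#'
#' @param rates a [rate_constants()] object (or coercible named list).
#' @return 3x3 numeric matrix with dimnames `c("A", "C", "N")`.
#' @export
system_matrix <- function(rates) {
  r <- as_rates(rates)
  M <- rbind(c(-r$k2, 0, 0),
             c(r$k2, -(r$k1 + r$k3), r$k_m1),
             c(0, r$k1, -r$k_m1))
  dimnames(M) <- list(c("A", "C", "N"), c("A", "C", "N"))
  M
}

#' Analytic eigenvalues of the compartment model
#'
#' The aggregate compartment is decoupled in the loss direction, so its
#' eigenvalue is exactly `l1 = -k2`. The nucleus/cytoplasm sub-system
#' contributes the two characteristic roots
#' `l2, l3 = (-(k1 + k_m1 + k3) -/+ sqrt((k1 + k_m1 + k3)^2 - 4 k_m1 k3))/2`,
#' ordered so that `l2 <= l3 <= 0` (`l2` fast, `l3` slow). For symmetric
#' exchange (`k1 = k_m1`) the discriminant reduces to `k3^2 + 4 k1 k_m1`.
#'
#' @inheritParams system_matrix
#' @return Named numeric vector `c(l1, l2, l3)` in 1/s.
#' @examples
#' model_eigenvalues(rate_constants(0.016194, 0.016194, 0.005, 0.617582))
#' @export
model_eigenvalues <- function(rates) {
  r <- as_rates(rates)
  s <- r$k1 + r$k_m1 + r$k3
  disc <- s^2 - 4 * r$k_m1 * r$k3
  # disc = (k1 + k_m1 - k3)^2 + 4 k1 k3 >= 0: roots are always real
  sq <- sqrt(max(disc, 0))
  c(l1 = -r$k2, l2 = (-s - sq) / 2, l3 = (-s + sq) / 2)
}

#' Solve the compartment model
#'
#' Exact solution of the linear ODE system at the requested times, either by
#' eigen-decomposition of the system matrix or by the matrix exponential
#' (`Matrix::expm`). The default `"auto"` uses the eigen route and falls
#' back to the matrix exponential when eigenvalues (nearly) coincide, where
#' the eigenvector basis can be defective.
#'
#' @inheritParams system_matrix
#' @param init named numeric vector `c(A, C, N)` of non-negative initial
#'   intensities (arbitrary units).
#' @param times non-negative times (seconds); scalar or vector.
#' @param method `"auto"`, `"eigen"` or `"expm"`.
#' @return Matrix with `length(times)` rows and columns `A`, `C`, `N`.
#' @examples
#' r <- rate_constants(0.016194, 0.016194, 0.005, 0.617582)
#' solve_compartments(r, c(A = 1, C = 1, N = 1), times = c(0, 100, 200))
#' @export
solve_compartments <- function(rates, init = c(A = 1, C = 1, N = 1), times,
                               method = c("auto", "eigen", "expm")) {
  method <- match.arg(method)
  r <- as_rates(rates)
  init <- unlist(init)[c("A", "C", "N")]
  if (anyNA(init) || any(init < 0))
    stop("'init' must be a named non-negative vector with A, C and N",
         call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  M <- system_matrix(r)
  if (method == "auto") {
    ev <- sort(Re(eigen(M, only.values = TRUE)$values))
    gap <- min(diff(ev), Inf)
    method <- if (gap < 1e-9) "expm" else "eigen"
  }
  out <- if (method == "eigen") {
    e <- eigen(M)
    co <- solve(e$vectors, init)
    t(vapply(times, function(tt) Re(e$vectors %*% (co * exp(e$values * tt)))[, 1],
             numeric(3)))
  } else {
    t(vapply(times,
             function(tt) as.numeric(Matrix::expm(M * tt) %*% init),
             numeric(3)))
  }
  out[times == 0, ] <- rep(init, each = sum(times == 0))  # exact identity
  dimnames(out) <- list(format(times, trim = TRUE), c("A", "C", "N"))
  out
}

#' Write / read rate constants and initial state as flat JSON
#'
#' @param rates a [rate_constants()] object.
#' @param init optional named initial state `c(A, C, N)`.
#' @param path file path for the JSON record.
#' @return `write_rates` returns `path` invisibly; `read_rates` returns a
#'   list with elements `rates` and (if present) `init`.
#' @export
write_rates <- function(rates, path, init = NULL) {
  r <- as_rates(rates)
  rec <- list(k1 = r$k1, k_m1 = r$k_m1, k2 = r$k2, k3 = r$k3)
  if (!is.null(init)) {
    init <- unlist(init)[c("A", "C", "N")]
    rec <- c(rec, list(A = unname(init["A"]), C = unname(init["C"]),
                       N = unname(init["N"])))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(rates = rate_constants(rec$k1, rec$k_m1, rec$k2, rec$k3))
  if (!is.null(rec$A))
    out$init <- c(A = rec$A, C = rec$C, N = rec$N)
  out
}

#' Export model eigenvalues as CSV
#'
#' @param eig named vector from [model_eigenvalues()].
#' @param path output CSV path (columns: name, value_s^-1).
#' @export
write_eigenvalues_csv <- function(eig, path) {
  df <- data.frame(name = names(eig), `value_s^-1` = as.numeric(eig),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
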