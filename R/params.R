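#' Microzone geometry
#'
#' Defines the size of the simulated cerebellar microzone: `S * L` Purkinje
#' cells on a rectangular grid (extent `S` sagittally, `L` laterally), `T`
#' discrete time bins per movement, `N` mossy fibres per sagittal position
#' (so `N * S` fibres in total) and `p` input patterns ("movements").
#'
#' `N * S` must be even: each pattern activates exactly `N * S / 2` fibres.
#'
#' @param S Sagittal extent (number of Purkinje cell rows).
#' @param L Lateral extent (number of Purkinje cell columns; also the number
#'   of projection neurones, nucleo-olivary neurones and climbing fibres).
#' @param T Number of time bins per movement.
#' @param N Mossy fibres per sagittal position.
#' @param p Number of patterns (movements) to learn.
#' @return An object of class `sgdege_shape` (a named list).
#' @examples
#' shape_params() # defaults used throughout: S=10, L=40, T=10, N=2000, p=2
#' @export
shape_params <- function(S = 10L, L = 40L, T = 10L, N = 2000L, p = 2L) {
  vals <- list(S = S, L = L, T = T, N = N, p = p)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 1 || v != round(v)) {
      stop("shape parameter `", nm, "` must be a single positive integer",
           call. = FALSE)
    }
    vals[[nm]] <- as.integer(v)
  }
  if ((vals$N * vals$S) %% 2L != 0L) {
    stop("N * S must be even (each pattern activates exactly N*S/2 fibres)",
         call. = FALSE)
  }
  structure(vals, class = "sgdege_shape")
}

#' @export
print.sgdege_shape <- function(x, ...) {
  cat("<sgdege_shape> S =", x$S, " L =", x$L, " T =", x$T,
      " N =", x$N, " p =", x$p, "\n")
  cat("  ", x$S * x$L, "Purkinje cells,", x$N * x$S, "mossy fibres,",
      x$L * x$T, "output variables per movement\n")
  invisible(x)
}

#' Network model parameters
#'
#' Parameters of the full microzone simulation. Defaults are the reference
#' parameter set used throughout the package. The fixed synaptic weights are
#' derived from the rate scales and are not free:
#' \deqn{u_{M \to PN} = 4 T L \bar r_D / (N S), \quad
#'       u_{PC \to PN} = -\bar r_D / (\bar r_{PC} S), \quad
#'       u_{PC \to NO} = q\, u_{PC \to PN}.}
#' With the defaults these evaluate to 2.4, -0.06 and -0.03.
#'
#' @param shape An [shape_params()] object.
#' @param rmax Saturation rate of the threshold-linear f-I curve (Hz).
#' @param rho Probability per movement that each climbing fibre emits a
#'   perturbation complex spike.
#' @param A Amplitude of the Purkinje cell firing perturbation (Hz).
#' @param alpha_w Learning rate of mossy fibre to Purkinje cell synapses.
#' @param alpha_v Learning rate of mossy fibre to nucleo-olivary synapses.
#' @param rbar_PC Mean Purkinje cell firing rate (Hz), sets initial `w` scale.
#' @param rbar_D Desired mean firing rate of nuclear neurones (Hz); targets
#'   are uniform on `[0, 2 * rbar_D]`.
#' @param q Strength of the PC to nucleo-olivary connection relative to the
#'   PC to projection-neurone connection (dimensionless).
#' @param NO0 Initial mean nucleo-olivary rate (Hz); chosen so that the
#'   initial inhibition of the olive roughly matches the expected initial
#'   error.
#' @return An object of class `sgdege_network_params`.
#' @examples
#' pars <- network_params()
#' pars$u_M_PN   # 2.4
#' pars$u_PC_PN  # -0.06
#' @export
network_params <- function(shape = shape_params(),
                           rmax = 300,
                           rho = 0.03,
                           A = 2,
                           alpha_w = 0.02,
                           alpha_v = 2e-4,
                           rbar_PC = 50,
                           rbar_D = 30,
                           q = 0.5,
                           NO0 = 15) {
  stopifnot(inherits(shape, "sgdege_shape"))
  if (rmax <= 0) stop("rmax must be positive", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (A <= 0) stop("A must be positive", call. = FALSE)
  if (alpha_w <= 0 || alpha_v <= 0) stop("learning rates must be positive", call. = FALSE)
  if (rbar_PC <= 0 || rbar_D <= 0) stop("mean rates must be positive", call. = FALSE)
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  u_PC_PN <- -rbar_D / (rbar_PC * shape$S)
  structure(list(
    shape = shape, rmax = rmax, rho = rho, A = A,
    alpha_w = alpha_w, alpha_v = alpha_v,
    rbar_PC = rbar_PC, rbar_D = rbar_D, q = q, NO0 = NO0,
    u_M_PN = 4 * shape$T * shape$L * rbar_D / (shape$N * shape$S),
    u_PC_PN = u_PC_PN,
    u_PC_NO = q * u_PC_PN
  ), class = "sgdege_network_params")
}

#' @export
print.sgdege_network_params <- function(x, ...) {
  cat("<sgdege_network_params>\n")
  print(x$shape)
  cat(sprintf("  rmax=%g Hz  rho=%g  A=%g Hz  alpha_w=%g  alpha_v=%g\n",
              x$rmax, x$rho, x$A, x$alpha_w, x$alpha_v))
  cat(sprintf("  rbar_PC=%g Hz  rbar_D=%g Hz  q=%g  NO0=%g Hz\n",
              x$rbar_PC, x$rbar_D, x$q, x$NO0))
  cat(sprintf("  fixed weights: u_M_PN=%g  u_PC_PN=%g  u_PC_NO=%g\n",
              x$u_M_PN, x$u_PC_PN, x$u_PC_NO))
  invisible(x)
}

#' Saturating threshold-linear f-I curve
#'
#' The rate transfer function used by every neurone in the model:
#' 0 below threshold, linear in between, saturating at `rmax`.
#'
#' @param x Input drive (scalar or array), rate-like units.
#' @param rmax Saturation rate (Hz), must be positive.
#' @return `x` rectified below at 0 and clipped above at `rmax`, elementwise.
#' @examples
#' phi(c(-5, 123.4, 400), rmax = 300) # 0, 123.4, 300
#' @export
phi <- function(x, rmax) {
  if (!is.numeric(rmax) || length(rmax) != 1L || rmax <= 0) {
    stop("rmax must be a single positive number", call. = FALSE)
  }
  pmin(pmax(x, 0), rmax)
}

# Derive an independent sub-stream seed from a root seed and a stream name,
# so e.g. changing the trial count never alters pattern generation.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483647)
}
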