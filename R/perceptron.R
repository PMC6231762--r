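#' Analog perceptron parameters
#'
#' A single P-cell with `Nm` binary input fibres at coding level `f`
#' (each fibre active in a pattern with probability `f`), threshold-linear
#' output saturating at `Pmax`, and sign-constrained (non-negative) weights.
#' Learning either uses SGDEGE (perturbation + estimated-error comparison,
#' with the reduced-model step sizes `dP`, `dJ` mapped onto per-synapse
#' weight steps) or the classical delta rule as the full-information
#' comparison.
#'
#' @param Nm Number of input fibres.
#' @param f Input coding level, in (0, 1).
#' @param Pmax Saturation rate (Hz).
#' @param theta Threshold (input-current units).
#' @param gamma Gain (Hz per unit current).
#' @param A,rho,dP,dJ,q SGDEGE parameters as in [reduced_params()].
#' @param p Number of input-output associations (patterns).
#' @param target_mean Mean of the uniform target-rate distribution (Hz);
#'   targets are uniform on `[0, 2 * target_mean]`.
#' @param lr Delta-rule relative learning rate (one update moves the rate by
#'   `lr * (R - P)` in the linear, unclipped regime).
#' @return An object of class `perceptron_params`.
#' @examples
#' perceptron_params(p = 50)
#' @export
perceptron_params <- function(Nm = 1000L, f = 0.2, Pmax = 100, theta = 12.85,
                              gamma = 1, A = 2, rho = 0.2, dP = 0.2,
                              dJ = 0.4, q = 0.5, p = 1L, target_mean = 30,
                              lr = 0.1) {
  if (f <= 0 || f >= 1) stop("f must lie in (0, 1)", call. = FALSE)
  if (Nm < 1) stop("Nm must be >= 1", call. = FALSE)
  if (Pmax <= 0 || gamma <= 0) stop("Pmax and gamma must be positive", call. = FALSE)
  if (2 * target_mean > Pmax) {
    stop("target range [0, 2*target_mean] must lie within [0, Pmax]",
         call. = FALSE)
  }
  structure(list(Nm = as.integer(Nm), f = f, Pmax = Pmax, theta = theta,
                 gamma = gamma, A = A, rho = rho, dP = dP, dJ = dJ, q = q,
                 p = as.integer(p), target_mean = target_mean, lr = lr),
            class = "perceptron_params")
}

#' Generate perceptron input-output associations
#'
#' Inputs are i.i.d. Bernoulli(`f`) binary vectors; target rates are uniform
#' on `[0, 2 * target_mean]`. Initial weights are uniform on
#' `[0, 2 theta / (f Nm)]` (so the initial mean drive is at threshold) and
#' initial `v` uniform on `[0, 2 target_mean / (f Nm)]` (so the initial
#' error estimate is on the scale of the initial error).
#'
#' @param params A [perceptron_params()] object.
#' @param seed Integer seed.
#' @return List with `x` (`Nm x p` 0/1 matrix), `R` (targets, Hz), and the
#'   initial state `w`, `v` (length `Nm`, non-negative).
#' @export
generate_pattern_set <- function(params, seed) {
  stopifnot(inherits(params, "perceptron_params"))
  set.seed(substream_seed(seed, "perceptron_patterns"))
  x <- matrix(as.integer(stats::runif(params$Nm * params$p) < params$f),
              params$Nm, params$p)
  R <- stats::runif(params$p, 0, 2 * params$target_mean)
  set.seed(substream_seed(seed, "perceptron_weights"))
  w <- stats::runif(params$Nm, 0, 2 * params$theta / (params$f * params$Nm))
  v <- stats::runif(params$Nm, 0, 2 * params$target_mean / (params$f * params$Nm))
  list(x = x, R = R, w = w, v = v)
}

#' Perceptron output rate
#'
#' `P = Phi(gamma (w . x - theta) + A [perturbed])`, rectified at 0 and
#' saturated at `Pmax`.
#'
#' @param w Weight vector (length `Nm`).
#' @param x Binary input vector.
#' @param perturbed Logical: add the perturbation `A`?
#' @param params A [perceptron_params()] object.
#' @return Rate in `[0, Pmax]` (Hz).
#' @export
perceptron_rate <- function(w, x, perturbed, params) {
  drive <- params$gamma * (sum(w * x) - params$theta) +
    if (isTRUE(perturbed)) params$A else 0
  phi(drive, params$Pmax)
}

#' One SGDEGE perceptron trial
#'
#' Computes the (possibly perturbed) rate, the error `|P - R|` and its
#' estimate `[v . x - q P]+`, then applies constant-step updates with sign
#' `c`: on perturbed trials the active weights move by `-c dP / (gamma
#' n_active)` each (so the rate moves by `dP` in the linear regime), and on
#' every trial `v` moves by `+c dJ / n_active` on active fibres. Both weight
#' vectors are clipped at zero.
#'
#' @param w,v Current weights.
#' @param x Binary input vector of the presented pattern.
#' @param R Target rate of the presented pattern (Hz).
#' @param perturbed Logical, whether a perturbation occurred.
#' @param params A [perceptron_params()] object.
#' @return List with updated `w`, `v`, the trial's `P`, `error`, `estimate`
#'   and sign `c`.
#' @export
sgdege_percep_trial <- function(w, v, x, R, perturbed, params) {
  act <- which(x > 0)
  P <- perceptron_rate(w, x, perturbed, params)
  err <- abs(P - R)
  est <- max(sum(v * x) - params$q * P, 0)
  c <- if (err - est > 0) 1L else -1L
  if (isTRUE(perturbed) && length(act) > 0) {
    w[act] <- pmax(w[act] - c * params$dP / (params$gamma * length(act)), 0)
  }
  if (length(act) > 0) {
    v[act] <- pmax(v[act] + c * params$dJ / length(act), 0)
  }
  list(w = w, v = v, P = P, error = err, estimate = est, c = c)
}

#' One delta-rule perceptron trial
#'
#' Full-information comparison: the active weights move by
#' `lr (R - P) / (gamma n_active)` each, so the rate moves by `lr (R - P)`
#' in the linear, unclipped regime. Weights are clipped at zero; there is no
#' perturbation and no error-estimate pathway.
#'
#' @inheritParams sgdege_percep_trial
#' @param lr Relative learning rate, positive.
#' @return List with updated `w` and the trial's `P`.
#' @export
delta_rule_trial <- function(w, x, R, lr, params) {
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  act <- which(x > 0)
  P <- perceptron_rate(w, x, FALSE, params)
  if (length(act) > 0) {
    w[act] <- pmax(w[act] + lr * (R - P) / (params$gamma * length(act)), 0)
  }
  list(w = w, P = P)
}

#' Run perceptron learning
#'
#' Patterns are presented cyclically; one sweep is one presentation of each
#' of the `p` patterns. The learning curve records the mean unperturbed
#' error over patterns at each sweep (evaluated just before each pattern's
#' update).
#'
#' @param algorithm `"sgdege"` or `"delta"`.
#' @param params A [perceptron_params()] object.
#' @param n_sweeps Trials per pattern.
#' @param seed Integer seed (patterns, initial weights, perturbations).
#' @param set Optional pattern set from [generate_pattern_set()] to reuse.
#' @return Object of class `perceptron_sim`: `curve` tibble
#'   (sweep, mean_error_hz), `patterns_summary` tibble with final per-pattern
#'   unperturbed rate, target, error and nucleo-olivary drive `J = v . x`,
#'   final `w`, `v`, `params`, `algorithm`.
#' @export
run_perceptron <- function(algorithm = c("sgdege", "delta"), params,
                           n_sweeps, seed, set = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(params, "perceptron_params"))
  if (is.null(set)) set <- generate_pattern_set(params, seed)
  p <- params$p
  act <- lapply(seq_len(p), function(mu) which(set$x[, mu] > 0) - 1L)
  offsets <- c(0L, cumsum(lengths(act)))
  act_cat <- as.integer(unlist(act))
  if (algorithm == "sgdege" && n_sweeps > 0) {
    set.seed(substream_seed(seed, "perceptron_perturbations"))
    pflags <- stats::runif(n_sweeps * p) < params$rho
  } else {
    pflags <- logical(0)
  }
  if (n_sweeps > 0) {
    res <- cpp_run_perceptron(act_cat, offsets, set$R, set$w, set$v,
                              params$Pmax, params$theta, params$gamma,
                              params$A, params$q, params$dP, params$dJ,
                              params$lr, algorithm == "sgdege", pflags,
                              as.integer(n_sweeps), as.integer(p))
    w <- as.vector(res$w); v <- as.vector(res$v)
    curve <- tibble::tibble(sweep = seq_len(n_sweeps),
                            mean_error_hz = as.vector(res$curve))
  } else {
    w <- set$w; v <- set$v
    curve <- tibble::tibble(sweep = integer(0), mean_error_hz = numeric(0))
  }
  P_final <- vapply(seq_len(p), function(mu)
    perceptron_rate(w, set$x[, mu], FALSE, params), numeric(1))
  J_final <- as.vector(crossprod(set$x, v))
  psum <- tibble::tibble(pattern = seq_len(p), rate_hz = P_final,
                         target_hz = set$R,
                         error_hz = abs(P_final - set$R),
                         J_hz = J_final)
  structure(list(curve = curve, patterns_summary = psum, w = w, v = v,
                 params = params, algorithm = algorithm,
                 n_sweeps = as.integer(n_sweeps), seed = seed,
                 initial_error_hz = mean(vapply(seq_len(p), function(mu)
                   abs(perceptron_rate(set$w, set$x[, mu], FALSE, params) -
                         set$R[mu]), numeric(1)))),
            class = "perceptron_sim")
}

#' @export
print.perceptron_sim <- function(x, ...) {
  g <- glance(x)
  cat("<perceptron_sim>", x$algorithm, "-", x$params$p, "pattern(s),",
      x$n_sweeps, "sweeps; final mean error",
      round(g$final_error_hz, 3), "Hz\n")
  invisible(x)
}

#' @export
tidy.perceptron_sim <- function(x, ...) x$curve

#' @export
glance.perceptron_sim <- function(x, ...) {
  tail_n <- max(1L, ceiling(x$n_sweeps * 0.05))
  tail_idx <- seq.int(max(1L, x$n_sweeps - tail_n + 1L), max(1L, x$n_sweeps))
  tibble::tibble(
    algorithm = x$algorithm,
    p = x$params$p,
    n_sweeps = x$n_sweeps,
    initial_error_hz = x$initial_error_hz,
    final_error_hz = if (x$n_sweeps > 0) mean(x$curve$mean_error_hz[tail_idx])
                     else x$initial_error_hz,
    auc = if (x$n_sweeps > 0) sum(x$curve$mean_error_hz) else NA_real_,
    floor_hz = x$params$A * (1 + x$params$q) / 2,
    seed = x$seed)
}

#' @export
autoplot.perceptron_sim <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$sweep, y = .data$mean_error_hz)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "trials per pattern", y = "mean error (Hz)",
                  title = paste("Perceptron learning:", object$algorithm))
}

#' Empirical storage-capacity scan
#'
#' Runs learning at each pattern count in `p_grid` and reports the largest
#' count whose final mean error is below criterion: `error_threshold` for
#' the delta rule (which reaches zero error below capacity), or the
#' perturbation floor `A(1+q)/2` plus `floor_tolerance` for SGDEGE.
#'
#' @param algorithm `"sgdege"` or `"delta"`.
#' @param params A [perceptron_params()] object (`p` is overridden).
#' @param p_grid Ascending pattern counts to test.
#' @param n_sweeps Trials per pattern at each grid point.
#' @param error_threshold Delta-rule convergence criterion (Hz).
#' @param floor_tolerance SGDEGE allowance above the floor (Hz).
#' @param seed Integer seed.
#' @return Object of class `capacity_scan`: tibble `results`
#'   (p, final_error_hz, converged) and `critical_p`.
#' @export
capacity_scan <- function(algorithm = c("delta", "sgdege"), params, p_grid,
                          n_sweeps, error_threshold = 1,
                          floor_tolerance = 1, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (length(p_grid) == 0) stop("p_grid is empty", call. = FALSE)
  if (is.unsorted(p_grid)) stop("p_grid must be ascending", call. = FALSE)
  thr <- if (algorithm == "delta") error_threshold
         else params$A * (1 + params$q) / 2 + floor_tolerance
  rows <- purrr::map(p_grid, function(pp) {
    pars <- params
    pars$p <- as.integer(pp)
    sim <- run_perceptron(algorithm, pars, n_sweeps, seed)
    g <- glance(sim)
    tibble::tibble(p = pp, final_error_hz = g$final_error_hz,
                   converged = g$final_error_hz < thr)
  })
  results <- dplyr::bind_rows(rows)
  conv <- results$p[results$converged]
  structure(list(results = results,
                 critical_p = if (length(conv)) max(conv) else NA_integer_,
                 threshold_hz = thr, algorithm = algorithm,
                 n_sweeps = n_sweeps, seed = seed),
            class = "capacity_scan")
}

#' @export
print.capacity_scan <- function(x, ...) {
  cat("<capacity_scan>", x$algorithm, "- critical p =", x$critical_p,
      "(threshold", round(x$threshold_hz, 2), "Hz)\n")
  print(x$results)
  invisible(x)
}

#' @export
autoplot.capacity_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$p, y = .data$final_error_hz)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold_hz,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "number of patterns", y = "final mean error (Hz)",
                  title = paste("Capacity scan:", object$algorithm))
}
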