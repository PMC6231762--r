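#' Reduced single-cell model parameters
#'
#' The single P-cell abstraction of the algorithm: the state is the pair
#' `(P, J)` of the principal-cell rate and the mossy drive to the
#' nucleo-olivary pathway. On each trial a perturbation of amplitude `A`
#' occurs with probability `rho`; the error is `|P (+A) - R|` and its running
#' estimate is the rectified inhibition `[J - qP (-qA)]+`. Comparison of the
#' two moves `P` by `dP` (perturbed trials only) and `J` by `dJ` (every
#' trial).
#'
#' @param R Target rate (Hz).
#' @param A Perturbation amplitude (Hz), positive.
#' @param rho Perturbation probability per trial, in (0, 1).
#' @param dP P step per perturbed trial (Hz).
#' @param dJ J step per trial (Hz).
#' @param q Relative strength of the P-cell inhibition of the
#'   nucleo-olivary pathway (dimensionless, non-negative).
#' @return An object of class `reduced_params`; `beta = dJ/dP` is derived.
#' @examples
#' reduced_params(R = 100, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5)
#' @export
reduced_params <- function(R, A = 10, rho = 0.2, dP = 1, dJ = 2, q = 0.5) {
  if (A <= 0) stop("A must be positive", call. = FALSE)
  if (dP <= 0 || dJ <= 0) stop("dP and dJ must be positive", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)", call. = FALSE)
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  structure(list(R = R, A = A, rho = rho, dP = dP, dJ = dJ, q = q,
                 beta = dJ / dP),
            class = "reduced_params")
}

#' One trial of the reduced dynamics
#'
#' On a perturbed trial the error is `|P + A - R|` and the estimate is
#' `[J - q(P + A)]+`; if the error exceeds the estimate (`c = +1`) the
#' perturbation was deleterious, so `P` decreases by `dP` and `J` increases
#' by `dJ`; otherwise (`c = -1`, ties included) the opposite. On an
#' unperturbed trial `P` is unchanged and only `J` moves, using error
#' `|P - R|` against estimate `J - qP` (rectified by default; set
#' `rectify_unperturbed = FALSE` for the unrectified literal form -- the two
#' differ only when `J < qP`).
#'
#' @param state Named list or vector with `P` and `J` (Hz).
#' @param params A [reduced_params()] object.
#' @param perturbed Logical: did a perturbation occur this trial?
#' @param rectify_unperturbed Rectify the estimate on unperturbed trials.
#' @return List with the new `P`, `J`, and the update sign `c`.
#' @export
reduced_step <- function(state, params, perturbed,
                         rectify_unperturbed = TRUE) {
  P <- state$P; J <- state$J
  if (perturbed) {
    err <- abs(P + params$A - params$R)
    est <- max(J - params$q * (P + params$A), 0)
    c <- if (err - est > 0) 1L else -1L
    P <- P - c * params$dP
  } else {
    err <- abs(P - params$R)
    est <- J - params$q * P
    if (rectify_unperturbed) est <- max(est, 0)
    c <- if (err - est > 0) 1L else -1L
  }
  list(P = P, J = J + c * params$dJ, c = c)
}

#' Convergence-corridor geometry in the (P, J) plane
#'
#' The update directions change sign on two borders: `C`, where
#' `J - qP - qA = |P - R + A|` (perturbed-trial comparison), and `D`, where
#' `J - qP = |P - R|` (unperturbed). Each border is a pair of half-lines
#' (`+`/`-` by slope); the corridors between `C+`/`D+` and `C-`/`D-` funnel
#' the dynamics towards the intersection of `C+` and `D-`, which exists iff
#' `q < 1` and lies at
#' \deqn{(P^*, J^*) = \big(R - A(q+1)/2,\; qR + (1-q^2)A/2\big).}
#'
#' @param params A [reduced_params()] object.
#' @return Object of class `corridor_geometry`: a tibble `lines` with one row
#'   per half-line (name, slope, intercept, domain bound) and `fixed_point`
#'   (named vector `P`, `J`, plus the final-error offset `R - P`), or `NULL`
#'   when `q >= 1`.
#' @examples
#' corridor_geometry(reduced_params(R = 100, A = 10, q = 0.5))$fixed_point
#' @export
corridor_geometry <- function(params) {
  R <- params$R; A <- params$A; q <- params$q
  lines <- tibble::tibble(
    line = c("C+", "C-", "D+", "D-"),
    slope = c(1 + q, q - 1, 1 + q, q - 1),
    intercept = c((1 + q) * A - R, (q - 1) * A + R, -R, R),
    domain = c("P >= R - A", "P < R - A", "P >= R", "P < R"))
  fp <- NULL
  if (q < 1) {
    Pstar <- R - A * (q + 1) / 2
    fp <- c(P = Pstar, J = q * R + (1 - q^2) * A / 2, offset = R - Pstar)
  }
  structure(list(lines = lines, fixed_point = fp, params = params),
            class = "corridor_geometry")
}

#' @export
print.corridor_geometry <- function(x, ...) {
  cat("<corridor_geometry> q =", x$params$q, "\n")
  print(x$lines)
  if (is.null(x$fixed_point)) {
    cat("  no fixed point (C+ and D- do not cross for q >= 1)\n")
  } else {
    cat(sprintf("  fixed point P* = %.4g, J* = %.4g (offset R - P* = %.4g)\n",
                x$fixed_point["P"], x$fixed_point["J"], x$fixed_point["offset"]))
  }
  invisible(x)
}

#' Check the sufficient conditions for convergence
#'
#' The stochastic descent reaches and descends a corridor when
#' `0 < rho < 1`, `dJ < (1 - q) A`, `dP + dJ/(1+q) < A`, and `q < 1`
#' (so that the corridor intersection exists). Larger steps can jump over
#' the corridor; `q >= 1` corrupts the error estimate more than the error.
#'
#' @param params A [reduced_params()] object.
#' @return A one-row tibble with one logical column per condition and
#'   `all_pass`.
#' @export
check_convergence_conditions <- function(params) {
  out <- tibble::tibble(
    rho_in_0_1 = params$rho > 0 && params$rho < 1,
    dJ_small = params$dJ < (1 - params$q) * params$A,
    dP_dJ_small = params$dP + params$dJ / (1 + params$q) < params$A,
    q_below_1 = params$q < 1)
  out$all_pass <- all(unlist(out))
  out
}

#' Simulate the reduced model
#'
#' Iterates [reduced_step()] from `(P0, J0)` for `n_trials` trials.
#'
#' @param params A [reduced_params()] object.
#' @param P0,J0 Initial state (Hz).
#' @param n_trials Number of trials.
#' @param seed Integer seed for the perturbation draws.
#' @param rectify_unperturbed See [reduced_step()].
#' @param engine `"cpp"` (default) or `"r"` reference loop.
#' @return Object of class `reduced_sim` with a `trajectory` tibble
#'   (trial, P, J, perturbed, c), the parameters and the geometry.
#' @export
run_reduced <- function(params, P0, J0, n_trials, seed,
                        rectify_unperturbed = TRUE,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "reduced_params"), n_trials >= 1)
  set.seed(substream_seed(seed, "reduced"))
  perturbed <- stats::runif(n_trials) < params$rho
  if (engine == "cpp") {
    res <- cpp_run_reduced(P0, J0, params$R, params$A, params$q,
                           params$dP, params$dJ, perturbed,
                           rectify_unperturbed)
    traj <- tibble::tibble(trial = seq_len(n_trials),
                           P = as.vector(res$P), J = as.vector(res$J),
                           perturbed = perturbed, c = as.integer(res$c))
  } else {
    P <- J <- numeric(n_trials)
    cc <- integer(n_trials)
    st <- list(P = P0, J = J0)
    for (tr in seq_len(n_trials)) {
      st <- reduced_step(st, params, perturbed[tr], rectify_unperturbed)
      P[tr] <- st$P; J[tr] <- st$J; cc[tr] <- st$c
    }
    traj <- tibble::tibble(trial = seq_len(n_trials), P = P, J = J,
                           perturbed = perturbed, c = cc)
  }
  structure(list(trajectory = traj, params = params, P0 = P0, J0 = J0,
                 n_trials = as.integer(n_trials), seed = seed,
                 geometry = corridor_geometry(params)),
            class = "reduced_sim")
}

#' @export
print.reduced_sim <- function(x, ...) {
  g <- glance(x)
  cat("<reduced_sim>", x$n_trials, "trials; late mean P =",
      round(g$late_mean_P, 2), "(target", x$params$R, ")\n")
  invisible(x)
}

#' @export
tidy.reduced_sim <- function(x, ...) x$trajectory

#' @export
glance.reduced_sim <- function(x, ...) {
  w <- run_windows(x$n_trials)
  tr <- x$trajectory
  fp <- x$geometry$fixed_point
  tibble::tibble(
    n_trials = x$n_trials,
    late_mean_P = mean(tr$P[w$tail]),
    late_sd_P = stats::sd(tr$P[w$tail]),
    late_mean_abs_error = mean(abs(tr$P[w$tail] - x$params$R)),
    fixed_point_P = if (is.null(fp)) NA_real_ else unname(fp["P"]),
    predicted_floor = x$params$A * (x$params$q + 1) / 2,
    seed = x$seed)
}

#' @export
autoplot.reduced_sim <- function(object, ...) {
  geo <- object$geometry
  pl <- ggplot2::ggplot(object$trajectory,
                        ggplot2::aes(x = .data$P, y = .data$J)) +
    ggplot2::geom_path(alpha = 0.6, colour = "grey30") +
    ggplot2::labs(x = "P (Hz)", y = "J (Hz)",
                  title = "Reduced-model trajectory in the (P, J) plane")
  if (!is.null(geo$fixed_point)) {
    pl <- pl + ggplot2::annotate("point", x = geo$fixed_point["P"],
                                 y = geo$fixed_point["J"],
                                 colour = "red", size = 2)
  }
  pl
}
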