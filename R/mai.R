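#' Marr-Albus-Ito baseline parameters
#'
#' The comparison model without perturbations or nucleo-olivary cells: the
#' climbing fibre broadcasts the movement error itself. When the error is
#' positive, active mossy fibre to Purkinje cell synapses are depressed by
#' `alpha_w`; otherwise all weights drift up by `beta_w`.
#'
#' @param alpha_w LTD step per active synapse.
#' @param beta_w LTP drift increment applied to every weight.
#' @param error_mode `"signed"` (mean of `R - PN`; can be negative) or
#'   `"unsigned"` (mean of `|PN - R|`).
#' @return An object of class `mai_params`.
#' @export
mai_params <- function(alpha_w = 0.02, beta_w = 0.002,
                       error_mode = c("signed", "unsigned")) {
  if (alpha_w <= 0 || beta_w <= 0) {
    stop("alpha_w and beta_w must be positive", call. = FALSE)
  }
  structure(list(alpha_w = alpha_w, beta_w = beta_w,
                 error_mode = match.arg(error_mode)),
            class = "mai_params")
}

#' Movement error for the baseline model
#'
#' @param pn `L x T` projection neurone rates (Hz).
#' @param target `L x T` target rates (Hz).
#' @param mode `"signed"` returns `mean(target - pn)` (antisymmetric, can be
#'   negative); `"unsigned"` returns `mean(|pn - target|)`.
#' @return Error (Hz).
#' @export
mai_error <- function(pn, target, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  if (!identical(dim(pn), dim(target))) {
    stop("pn and target must have identical dimensions", call. = FALSE)
  }
  if (mode == "signed") mean(target - pn) else mean(abs(pn - target))
}

#' One Marr-Albus-Ito weight update
#'
#' If the (mode-dependent) error is positive, weights of synapses whose mossy
#' fibre was active in the movement are decreased by `alpha_w` (LTD under the
#' broadcast error spike); otherwise every weight drifts up by `beta_w`.
#'
#' @param state A `network_state` (the `v` component is ignored).
#' @param pattern One pattern slice (see [purkinje_rates()]).
#' @param error Error computed in the configured mode (Hz).
#' @param params A [mai_params()] object.
#' @return Updated `network_state`.
#' @export
mai_update <- function(state, pattern, error, params) {
  w <- state$w
  if (error > 0) {
    w[pattern$active, ] <- w[pattern$active, ] - params$alpha_w
  } else {
    w <- w + params$beta_w
  }
  structure(list(w = w, v = state$v, conn = state$conn, shape = state$shape),
            class = "network_state")
}

#' Simulate the Marr-Albus-Ito baseline
#'
#' Same microzone, connectivity and initial weights as [run_network()], but
#' no perturbations, no nucleo-olivary population, and the broadcast-error
#' plasticity rule of [mai_update()]. Demonstrates that a single broadcast
#' error optimises the population-average signed error only, and fails
#' outright (saturating rates) on the unsigned error.
#'
#' @param params A [mai_params()] object.
#' @param net A [network_params()] object (geometry, rates, fixed weights).
#' @param patterns,targets,n_trials,seed,engine,state As in [run_network()].
#' @return Object of class `mai_sim`: `trajectory` tibble (trial, pattern,
#'   error_hz in the configured mode, unsigned_error_hz, mean_pn_hz),
#'   final `state`, `params`, `net`.
#' @export
run_mai <- function(params, net, patterns, targets, n_trials, seed,
                    engine = c("cpp", "r"), state = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "mai_params"),
            inherits(net, "sgdege_network_params"))
  shape <- net$shape
  if (is.null(state)) {
    conn <- build_connectivity(shape, seed)
    state <- init_weights(net, conn, seed)
  }
  mu_seq <- if (n_trials > 0) ((seq_len(n_trials) - 1L) %% shape$p) + 1L else integer(0)
  if (n_trials == 0) {
    traj <- tibble::tibble(trial = integer(0), pattern = integer(0),
                           error_hz = numeric(0), unsigned_error_hz = numeric(0),
                           mean_pn_hz = numeric(0))
    return(structure(list(trajectory = traj, state = state, params = params,
                          net = net, n_trials = 0L, seed = seed,
                          patterns_cache = patterns),
                     class = "mai_sim"))
  }
  if (engine == "cpp") {
    res <- cpp_run_mai(
      patterns$active - 1L, patterns$bin - 1L,
      state$w, state$conn$sigma,
      state$conn$pn_assign - 1L, as.vector(targets$R),
      shape$S, shape$L, shape$T, shape$N,
      net$rmax, net$u_M_PN, net$u_PC_PN,
      params$alpha_w, params$beta_w,
      params$error_mode == "signed", as.integer(n_trials))
    state <- structure(list(w = res$w, v = state$v, conn = state$conn,
                            shape = shape), class = "network_state")
    traj <- tibble::tibble(trial = seq_len(n_trials), pattern = mu_seq,
                           error_hz = as.vector(res$error),
                           unsigned_error_hz = as.vector(res$unsigned),
                           mean_pn_hz = as.vector(res$mean_pn))
  } else {
    err <- uerr <- mpn <- numeric(n_trials)
    eta0 <- matrix(0, shape$L, shape$T)
    for (tr in seq_len(n_trials)) {
      mu <- mu_seq[tr]
      pat <- pattern_slice(patterns, mu)
      pc <- purkinje_rates(state, pat, eta0, net)
      nuc <- nuclear_rates(state, pat, pc, net)
      err[tr] <- mai_error(nuc$pn, targets$R[, , mu], params$error_mode)
      uerr[tr] <- mai_error(nuc$pn, targets$R[, , mu], "unsigned")
      mpn[tr] <- mean(nuc$pn)
      state <- mai_update(state, pat, err[tr], params)
    }
    traj <- tibble::tibble(trial = seq_len(n_trials), pattern = mu_seq,
                           error_hz = err, unsigned_error_hz = uerr,
                           mean_pn_hz = mpn)
  }
  structure(list(trajectory = traj, state = state, params = params,
                 net = net, n_trials = as.integer(n_trials), seed = seed,
                 patterns_cache = patterns),
            class = "mai_sim")
}

#' @export
print.mai_sim <- function(x, ...) {
  cat("<mai_sim>", x$params$error_mode, "error,", x$n_trials, "trials\n")
  invisible(x)
}

#' @export
tidy.mai_sim <- function(x, ...) x$trajectory

#' @export
glance.mai_sim <- function(x, ...) {
  w <- run_windows(x$n_trials)
  tr <- x$trajectory
  sat <- saturation_fractions(x)
  tibble::tibble(
    error_mode = x$params$error_mode,
    n_trials = x$n_trials,
    initial_error_hz = mean(tr$error_hz[w$initial]),
    final_error_hz = mean(tr$error_hz[w$tail]),
    initial_unsigned_hz = mean(tr$unsigned_error_hz[w$initial]),
    final_unsigned_hz = mean(tr$unsigned_error_hz[w$tail]),
    final_mean_pn_hz = mean(tr$mean_pn_hz[w$tail]),
    pc_saturated_frac = sat$pc,
    pn_saturated_frac = sat$pn,
    seed = x$seed)
}

# Fraction of unperturbed PC / PN rates pinned at 0 or rmax under the final
# weights, pooled over patterns.
saturation_fractions <- function(sim, patterns = sim$patterns_cache) {
  net <- sim$net
  shape <- net$shape
  if (is.null(patterns)) return(list(pc = NA_real_, pn = NA_real_))
  eta0 <- matrix(0, shape$L, shape$T)
  pcs <- pns <- c()
  for (mu in seq_len(shape$p)) {
    pat <- pattern_slice(patterns, mu)
    pc <- purkinje_rates(sim$state, pat, eta0, net)
    nuc <- nuclear_rates(sim$state, pat, pc, net)
    pcs <- c(pcs, as.vector(pc))
    pns <- c(pns, as.vector(nuc$pn))
  }
  eps <- 1e-9
  list(pc = mean(pcs <= eps | pcs >= net$rmax - eps),
       pn = mean(pns <= eps | pns >= net$rmax - eps))
}

#' @export
autoplot.mai_sim <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$trial, y = .data$error_hz)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "trial", y = paste0(object$params$error_mode, " error (Hz)"),
                  title = "Marr-Albus-Ito baseline")
}
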