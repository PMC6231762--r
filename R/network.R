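#' Initialise plastic synaptic weights
#'
#' Mossy fibre to Purkinje cell weights `w` are drawn uniformly on
#' `[0, 8 T rbar_PC / N]` so that initial Purkinje rates average `rbar_PC`;
#' mossy fibre to nucleo-olivary weights `v` are drawn uniformly on
#' `[0, (NO0 + q rbar_D) 4 T L / (N S)]` so that initial nucleo-olivary rates
#' average `NO0`. `w` is unconstrained in sign thereafter (effective negative
#' weights can arise through interneuron pathways); `v` is kept non-negative
#' by the update rule.
#'
#' @param params A [network_params()] object.
#' @param conn A [build_connectivity()] object with the same shape.
#' @param seed Integer seed.
#' @return An object of class `network_state`: `w` (`N*S x L` matrix),
#'   `v` (length `N*S` vector, one weight per fibre onto its assigned
#'   nucleo-olivary neurone) and the connectivity.
#' @export
init_weights <- function(params, conn, seed) {
  stopifnot(inherits(params, "sgdege_network_params"),
            inherits(conn, "mf_connectivity"))
  shape <- params$shape
  n_fib <- shape$N * shape$S
  set.seed(substream_seed(seed, "weights"))
  w_hi <- 8 * shape$T * params$rbar_PC / shape$N
  v_hi <- (params$NO0 + params$q * params$rbar_D) * 4 * shape$T * shape$L /
    (shape$N * shape$S)
  w <- matrix(stats::runif(n_fib * shape$L, 0, w_hi), n_fib, shape$L)
  v <- stats::runif(n_fib, 0, v_hi)
  structure(list(w = w, v = v, conn = conn, shape = shape),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state>", nrow(x$w), "fibres x", ncol(x$w),
      "columns; mean w", signif(mean(x$w), 3), "; mean v", signif(mean(x$v), 3), "\n")
  invisible(x)
}

#' Extract one pattern from a pattern set
#'
#' @param patterns A [generate_patterns()] set.
#' @param mu Pattern index (1-based).
#' @return List with `active` (flat fibre indices), `bin` (firing bins) and
#'   the shape, as consumed by [purkinje_rates()] and friends.
#' @export
pattern_slice <- function(patterns, mu) {
  list(active = patterns$active[, mu], bin = patterns$bin[, mu],
       shape = patterns$shape)
}

#' Purkinje cell rates for one movement
#'
#' \deqn{PC_{s,l}(t) = \Phi\Big(\sum_i w_{i,s}^l \sigma_{i,s}^l M_{i,s}(t)
#'   + \eta_l(t) A\Big)}
#' where `eta` marks perturbation complex spikes (one bin per perturbed
#' climbing fibre, shared by the whole sagittal column of Purkinje cells).
#'
#' @param state A [init_weights()] state.
#' @param pattern One pattern, as returned by `pattern_slice(patterns, mu)`
#'   (a list with `active` flat fibre indices and `bin` firing bins).
#' @param pert `L x T` 0/1 matrix of perturbation complex spikes.
#' @param params A [network_params()] object.
#' @return Numeric array `S x L x T` of rates in `[0, rmax]` (Hz).
#' @export
purkinje_rates <- function(state, pattern, pert, params) {
  shape <- params$shape
  S <- shape$S; L <- shape$L; TT <- shape$T
  stopifnot(nrow(pert) == L, ncol(pert) == TT)
  ws <- state$w * state$conn$sigma
  s_of <- ((pattern$active - 1L) %/% shape$N) + 1L
  grp <- (s_of - 1L) * TT + pattern$bin
  G <- matrix(0, S * TT, L)
  agg <- rowsum(ws[pattern$active, , drop = FALSE], group = grp)
  G[as.integer(rownames(agg)), ] <- agg
  # G rows are (s, t) with t fastest; reshape to [t, s, l] then permute
  drive <- array(G, dim = c(TT, S, L))
  pert_add <- params$A * aperm(array(pert, dim = c(L, TT, S)), c(2, 3, 1))
  phi(aperm(drive + pert_add, c(2, 3, 1)), params$rmax)
}

#' Nuclear cell rates for one movement
#'
#' Projection neurones combine fixed-weight mossy drive with inhibition from
#' their Purkinje cell column; nucleo-olivary neurones combine plastic mossy
#' drive `v` with the same inhibition scaled by `q`:
#' \deqn{PN_l(t) = \Phi\big(u_{M\to PN}\, n_l(t) + u_{PC\to PN} \sum_s PC_{s,l}(t)\big)}
#' and analogously for `NO` with `v` and `u_{PC\to NO}`.
#'
#' @param state,pattern,params As in [purkinje_rates()].
#' @param pc Purkinje rate array `S x L x T` computed for the same pattern.
#' @return List with `pn` and `no`, both `L x T` matrices in `[0, rmax]` (Hz).
#' @export
nuclear_rates <- function(state, pattern, pc, params) {
  shape <- params$shape
  L <- shape$L; TT <- shape$T
  stopifnot(all(dim(pc) == c(shape$S, L, TT)))
  conn <- state$conn
  idx <- cbind(conn$pn_assign[pattern$active], pattern$bin)
  cnt <- matrix(0, L, TT)
  for (k in seq_along(pattern$active)) {
    cnt[idx[k, 1L], idx[k, 2L]] <- cnt[idx[k, 1L], idx[k, 2L]] + 1
  }
  vd <- matrix(0, L, TT)
  vsel <- state$v[pattern$active]
  no_l <- conn$no_assign[pattern$active]
  for (k in seq_along(pattern$active)) {
    vd[no_l[k], pattern$bin[k]] <- vd[no_l[k], pattern$bin[k]] + vsel[k]
  }
  pcsum <- apply(pc, c(2, 3), sum)
  list(pn = phi(params$u_M_PN * cnt + params$u_PC_PN * pcsum, params$rmax),
       no = phi(vd + params$u_PC_NO * pcsum, params$rmax))
}

#' Global movement error
#'
#' Mean absolute difference between projection-neurone output and target,
#' over all neurones and time bins -- the single scalar the olive receives
#' as excitation.
#'
#' @param pn `L x T` projection neurone rates (Hz).
#' @param target `L x T` target rates (Hz).
#' @return Mean of `|pn - target|` (Hz).
#' @export
movement_error <- function(pn, target) {
  if (!identical(dim(pn), dim(target))) {
    stop("pn and target must have identical dimensions", call. = FALSE)
  }
  mean(abs(pn - target))
}

#' Olivary inhibition for one movement
#'
#' Mean nucleo-olivary rate over neurones and time bins: the adaptively
#' learned cancellation of the average error at the inferior olive.
#'
#' @param no `L x T` nucleo-olivary rates (Hz).
#' @return Mean rate (Hz).
#' @export
olive_inhibition <- function(no) mean(no)

#' Sign of the error complex spike decision
#'
#' An error complex spike is broadcast to all Purkinje cells when the olivary
#' drive `error - inhibition` is strictly positive; `c = +1` then, and `-1`
#' otherwise (including the tie, where no spike is emitted).
#'
#' @param error Global movement error (Hz).
#' @param inhibition Olivary inhibition (Hz).
#' @return `+1L` or `-1L`.
#' @export
ecs_sign <- function(error, inhibition) {
  if (error - inhibition > 0) 1L else -1L
}

#' One SGDEGE weight update
#'
#' After a movement with update sign `c`:
#' `w` changes only at synapses whose mossy fibre fired in the same bin as a
#' perturbation of that column's climbing fibre
#' (`w <- w - alpha_w c sum_t eta_l(t) M(t)`), while `v` changes at every
#' synapse of every fibre active anywhere in the movement
#' (`v <- [v + alpha_v c sum_t M(t)]_+`, rectified at zero).
#'
#' @param state,pattern,pert,params As in [purkinje_rates()].
#' @param c Update sign from [ecs_sign()], `+1` or `-1`.
#' @return The updated `network_state`.
#' @export
sgdege_update <- function(state, pattern, pert, c, params) {
  stopifnot(c %in% c(-1L, 1L))
  w <- state$w
  for (l in which(rowSums(pert) > 0)) {
    for (b in which(pert[l, ] > 0)) {
      idx <- pattern$active[pattern$bin == b]
      w[idx, l] <- w[idx, l] - params$alpha_w * c
    }
  }
  v <- state$v
  v[pattern$active] <- pmax(v[pattern$active] + params$alpha_v * c, 0)
  structure(list(w = w, v = v, conn = state$conn, shape = state$shape),
            class = "network_state")
}

#' Draw perturbation complex spikes for a run
#'
#' Each of the `L` climbing fibres perturbs independently with probability
#' `rho` on each movement; a perturbed fibre fires in a single bin drawn
#' uniformly from the `T` bins.
#'
#' @param L,T Microzone extent and bins.
#' @param rho Perturbation probability per fibre per movement.
#' @param n_trials Number of movements.
#' @param seed Optional integer seed (omit to use the current RNG state).
#' @return List of two `L x n_trials` matrices: logical `flag` and integer `bin`.
#' @export
draw_perturbations <- function(L, T, rho, n_trials, seed = NULL) {
  if (!is.null(seed)) set.seed(substream_seed(seed, "perturbations"))
  list(flag = matrix(stats::runif(L * n_trials) < rho, L, n_trials),
       bin = matrix(sample.int(T, L * n_trials, replace = TRUE), L, n_trials))
}

# L x T 0/1 matrix for one trial's perturbations
pert_matrix <- function(pert, trial, L, T) {
  eta <- matrix(0, L, T)
  on <- which(pert$flag[, trial])
  eta[cbind(on, pert$bin[on, trial])] <- 1
  eta
}

#' Simulate cerebellar learning with SGDEGE
#'
#' Runs the full microzone model: patterns are presented cyclically; on each
#' presentation perturbation complex spikes are drawn, rates and the global
#' error/inhibition comparison are evaluated, and the two plasticity rules
#' ([sgdege_update()]) are applied offline with the resulting sign.
#'
#' @param params A [network_params()] object.
#' @param patterns A [generate_patterns()] set with matching shape.
#' @param targets A [generate_targets()] array with matching dimensions.
#' @param n_trials Total number of movements (pattern presentations).
#' @param seed Integer seed controlling initial weights and perturbations.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference loop;
#'   identical results, much slower -- intended for small instances).
#' @param state Optional initial `network_state` (default: [init_weights()]
#'   from `seed`).
#' @return An object of class `sgdege_sim` with elements `trajectory`
#'   (a tibble: trial, pattern, error_hz, inhibition_hz, olive_drive_hz,
#'   ecs, n_perturbations), `state` (final weights), `params`, `seed`.
#' @examples
#' shape <- shape_params(S = 2, L = 4, T = 5, N = 20, p = 2)
#' pars <- network_params(shape)
#' pats <- generate_patterns(shape, seed = 1)
#' tg <- generate_targets(shape$L, shape$T, shape$p, pars$rbar_D, seed = 1)
#' sim <- run_network(pars, pats, tg, n_trials = 50, seed = 1)
#' glance(sim)
#' @export
run_network <- function(params, patterns, targets, n_trials, seed,
                        engine = c("cpp", "r"), state = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sgdege_network_params"),
            inherits(patterns, "mossy_patterns"),
            inherits(targets, "target_rates"))
  shape <- params$shape
  if (!identical(unclass(patterns$shape), unclass(shape))) {
    stop("patterns were generated for a different shape", call. = FALSE)
  }
  if (!all(dim(targets$R) == c(shape$L, shape$T, shape$p))) {
    stop("targets have wrong dimensions for this shape", call. = FALSE)
  }
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (is.null(state)) {
    conn <- build_connectivity(shape, seed)
    state <- init_weights(params, conn, seed)
  }
  pert <- draw_perturbations(shape$L, shape$T, params$rho, n_trials,
                             seed = seed)
  if (engine == "cpp") {
    res <- cpp_run_network(
      patterns$active - 1L, patterns$bin - 1L,
      state$w, state$conn$sigma, state$v,
      state$conn$pn_assign - 1L, state$conn$no_assign - 1L,
      as.vector(targets$R),
      shape$S, shape$L, shape$T, shape$N,
      params$rmax, params$A, params$alpha_w, params$alpha_v,
      params$u_M_PN, params$u_PC_PN, params$u_PC_NO,
      pert$flag, pert$bin - 1L, as.integer(n_trials))
    final <- structure(list(w = res$w, v = as.vector(res$v),
                            conn = state$conn, shape = shape),
                       class = "network_state")
    traj <- tibble::tibble(
      trial = seq_len(n_trials),
      pattern = as.integer(res$pattern) + 1L,
      error_hz = as.vector(res$error),
      inhibition_hz = as.vector(res$inhibition),
      ecs = as.integer(res$ecs),
      n_perturbations = as.integer(res$npert))
  } else {
    err <- inh <- numeric(n_trials)
    cc <- np <- integer(n_trials)
    mu_seq <- ((seq_len(n_trials) - 1L) %% shape$p) + 1L
    for (tr in seq_len(n_trials)) {
      mu <- mu_seq[tr]
      pat <- pattern_slice(patterns, mu)
      eta <- pert_matrix(pert, tr, shape$L, shape$T)
      pc <- purkinje_rates(state, pat, eta, params)
      nuc <- nuclear_rates(state, pat, pc, params)
      err[tr] <- movement_error(nuc$pn, targets$R[, , mu])
      inh[tr] <- olive_inhibition(nuc$no)
      cc[tr] <- ecs_sign(err[tr], inh[tr])
      np[tr] <- sum(eta)
      state <- sgdege_update(state, pat, eta, cc[tr], params)
    }
    final <- state
    traj <- tibble::tibble(trial = seq_len(n_trials), pattern = mu_seq,
                           error_hz = err, inhibition_hz = inh,
                           ecs = cc, n_perturbations = np)
  }
  traj$olive_drive_hz <- traj$error_hz - traj$inhibition_hz
  traj <- traj[, c("trial", "pattern", "error_hz", "inhibition_hz",
                   "olive_drive_hz", "ecs", "n_perturbations")]
  structure(list(trajectory = traj, state = final, params = params,
                 n_trials = as.integer(n_trials), seed = seed,
                 engine = engine),
            class = "sgdege_sim")
}

#' @export
print.sgdege_sim <- function(x, ...) {
  g <- glance(x)
  cat("<sgdege_sim>", x$n_trials, "trials,",
      x$params$shape$p, "pattern(s)\n")
  cat(sprintf("  error %.2f Hz -> %.2f Hz (fold reduction %.1f)\n",
              g$initial_error_hz, g$final_error_hz, g$fold_reduction))
  invisible(x)
}

# Window means used for run summaries: the initial window is the first
# min(500 * p, n) presentations (500 trials per pattern); the tail window is
# the last ceiling(n/12) presentations -- per-pattern trials 55,000-60,000
# for the reference run of 60,000 trials per pattern.
run_windows <- function(n, p = 1L) {
  list(initial = seq_len(min(500L * p, n)),
       tail = seq.int(n - ceiling(n / 12) + 1L, n))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sgdege_sim <- function(x, ...) x$trajectory

#' @export
glance.sgdege_sim <- function(x, ...) {
  w <- run_windows(x$n_trials, x$params$shape$p)
  e0 <- mean(x$trajectory$error_hz[w$initial])
  e1 <- mean(x$trajectory$error_hz[w$tail])
  tibble::tibble(
    n_trials = x$n_trials,
    initial_error_hz = e0,
    final_error_hz = e1,
    fold_reduction = if (e1 > 0) e0 / e1 else Inf,
    final_inhibition_hz = mean(x$trajectory$inhibition_hz[w$tail]),
    mean_abs_olive_drive_hz = mean(abs(x$trajectory$olive_drive_hz[w$tail])),
    seed = x$seed)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line labs
#' @export
autoplot.sgdege_sim <- function(object, every = max(1L, object$n_trials %/% 5000L),
                                ...) {
  df <- object$trajectory[seq(1L, object$n_trials, by = every), ]
  long <- tidyr::pivot_longer(df, c("error_hz", "inhibition_hz"),
                              names_to = "signal", values_to = "hz")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$hz,
                                     colour = .data$signal)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "trial", y = "rate (Hz)",
                  title = "Global error and olivary cancellation")
}

#' Nuclear output profiles for each pattern
#'
#' Unperturbed projection-neurone firing profiles under the current weights,
#' next to their targets -- the before/after view of learning.
#'
#' @param state A `network_state`.
#' @param patterns,targets,params As in [run_network()].
#' @return Tibble with pattern, neurone, time, pn_hz, target_hz.
#' @export
nuclear_output <- function(state, patterns, targets, params) {
  shape <- params$shape
  eta0 <- matrix(0, shape$L, shape$T)
  out <- vector("list", shape$p)
  for (mu in seq_len(shape$p)) {
    pat <- pattern_slice(patterns, mu)
    pc <- purkinje_rates(state, pat, eta0, params)
    nuc <- nuclear_rates(state, pat, pc, params)
    out[[mu]] <- tibble::tibble(
      pattern = mu,
      neurone = rep(seq_len(shape$L), times = shape$T),
      time = rep(seq_len(shape$T), each = shape$L),
      pn_hz = as.vector(nuc$pn),
      target_hz = as.vector(targets$R[, , mu]))
  }
  dplyr::bind_rows(out)
}
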