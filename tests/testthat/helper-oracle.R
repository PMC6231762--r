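# Naive nested-loop reference implementations, kept deliberately independent
# of the package's vectorised/compiled paths, plus small fixture builders.

tiny_shape <- function(S = 2L, L = 3L, T = 3L, N = 4L, p = 2L) {
  shape_params(S = S, L = L, T = T, N = N, p = p)
}

tiny_setup <- function(seed, ...) {
  shape <- tiny_shape(...)
  params <- network_params(shape)
  patterns <- generate_patterns(shape, seed)
  targets <- generate_targets(shape$L, shape$T, shape$p, params$rbar_D, seed)
  conn <- build_connectivity(shape, seed)
  state <- init_weights(params, conn, seed)
  list(shape = shape, params = params, patterns = patterns,
       targets = targets, conn = conn, state = state)
}

# Dense N*S x T binary activity matrix for one pattern
dense_pattern <- function(patterns, mu) {
  shape <- patterns$shape
  M <- matrix(0, shape$N * shape$S, shape$T)
  M[cbind(patterns$active[, mu], patterns$bin[, mu])] <- 1
  M
}

phi_scalar <- function(x, rmax) min(max(x, 0), rmax)

# PC_{s,l}(t) = Phi(sum_i w sigma M + eta_l(t) A), all explicit loops
oracle_pc_rates <- function(state, M, pert, params) {
  shape <- params$shape
  out <- array(0, c(shape$S, shape$L, shape$T))
  for (s in seq_len(shape$S)) {
    for (l in seq_len(shape$L)) {
      for (t in seq_len(shape$T)) {
        drive <- 0
        for (i in seq_len(shape$N)) {
          flat <- (s - 1L) * shape$N + i
          drive <- drive + state$w[flat, l] * state$conn$sigma[flat, l] * M[flat, t]
        }
        out[s, l, t] <- phi_scalar(drive + pert[l, t] * params$A, params$rmax)
      }
    }
  }
  out
}

# PN_l(t) and NO_l(t) with explicit loops
oracle_nuclear_rates <- function(state, M, pc, params) {
  shape <- params$shape
  pn <- no <- matrix(0, shape$L, shape$T)
  for (l in seq_len(shape$L)) {
    for (t in seq_len(shape$T)) {
      mossy_pn <- 0
      mossy_no <- 0
      for (flat in seq_len(shape$N * shape$S)) {
        if (M[flat, t] > 0) {
          if (state$conn$pn_assign[flat] == l) {
            mossy_pn <- mossy_pn + params$u_M_PN
          }
          if (state$conn$no_assign[flat] == l) {
            mossy_no <- mossy_no + state$v[flat]
          }
        }
      }
      pc_sum <- sum(pc[, l, t])
      pn[l, t] <- phi_scalar(mossy_pn + params$u_PC_PN * pc_sum, params$rmax)
      no[l, t] <- phi_scalar(mossy_no + params$u_PC_NO * pc_sum, params$rmax)
    }
  }
  list(pn = pn, no = no)
}

# Exhaustive restatement of the reduced-model update rule, written from the
# case analysis rather than the package's arithmetic.
oracle_reduced_step <- function(P, J, params, perturbed) {
  if (perturbed) {
    rate <- P + params$A
    err <- abs(rate - params$R)
    est <- J - params$q * rate
    if (est < 0) est <- 0
    if (err > est) list(P = P - params$dP, J = J + params$dJ, c = 1L)
    else list(P = P + params$dP, J = J - params$dJ, c = -1L)
  } else {
    err <- abs(P - params$R)
    est <- max(J - params$q * P, 0)
    if (err > est) list(P = P, J = J + params$dJ, c = 1L)
    else list(P = P, J = J - params$dJ, c = -1L)
  }
}

# Pure-R perceptron sweeps using the exported single-trial operations
r_perceptron_sweeps <- function(algorithm, params, set, n_sweeps, pflags) {
  w <- set$w; v <- set$v
  curve <- numeric(n_sweeps)
  k <- 0L
  for (sw in seq_len(n_sweeps)) {
    errs <- numeric(params$p)
    for (mu in seq_len(params$p)) {
      k <- k + 1L
      x <- set$x[, mu]
      errs[mu] <- abs(perceptron_rate(w, x, FALSE, params) - set$R[mu])
      if (algorithm == "delta") {
        res <- delta_rule_trial(w, x, set$R[mu], params$lr, params)
        w <- res$w
      } else {
        res <- sgdege_percep_trial(w, v, x, set$R[mu], pflags[k], params)
        w <- res$w; v <- res$v
      }
    }
    curve[sw] <- mean(errs)
  }
  list(w = w, v = v, curve = curve)
}
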