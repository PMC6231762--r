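#' Generate binary spatiotemporal mossy-fibre patterns
#'
#' Each pattern activates exactly `N*S/2` of the `N*S` mossy fibres, drawn
#' without replacement; every active fibre fires in a single time bin drawn
#' uniformly from the `T` bins, and is silent elsewhere. Patterns are drawn
#' independently of each other.
#'
#' Fibres are indexed by a flat index `fibre_id = (s - 1) * N + i` combining
#' the sagittal position `s` and the within-row index `i` (all 1-based).
#'
#' @param shape An [shape_params()] object (`p` patterns are generated).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `mossy_patterns`: a list with `shape` and
#'   integer matrices `active` and `bin`, both `N*S/2 x p` (column = pattern),
#'   giving the flat indices of the active fibres and their firing bins.
#' @examples
#' pats <- generate_patterns(shape_params(S = 2, N = 4, T = 3, L = 2, p = 1), seed = 7)
#' nrow(pats$active) # 4 active fibres (= N*S/2)
#' @export
generate_patterns <- function(shape, seed) {
  stopifnot(inherits(shape, "sgdege_shape"))
  n_fib <- shape$N * shape$S
  n_act <- n_fib %/% 2L
  set.seed(substream_seed(seed, "patterns"))
  active <- matrix(0L, n_act, shape$p)
  bin <- matrix(0L, n_act, shape$p)
  for (mu in seq_len(shape$p)) {
    active[, mu] <- sort(sample.int(n_fib, n_act, replace = FALSE))
    bin[, mu] <- sample.int(shape$T, n_act, replace = TRUE)
  }
  structure(list(shape = shape, active = active, bin = bin),
            class = "mossy_patterns")
}

#' @export
print.mossy_patterns <- function(x, ...) {
  cat("<mossy_patterns>", ncol(x$active), "pattern(s),",
      nrow(x$active), "active fibres each (of", x$shape$N * x$shape$S, ")\n")
  invisible(x)
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.mossy_patterns <- function(x, ...) {
  N <- x$shape$N
  p <- ncol(x$active)
  flat <- as.vector(x$active)
  tibble::tibble(
    pattern = rep(seq_len(p), each = nrow(x$active)),
    fibre = ((flat - 1L) %% N) + 1L,
    sagittal = ((flat - 1L) %/% N) + 1L,
    time = as.vector(x$bin)
  )
}

# Dense N*S x T binary matrix for one pattern (small instances / oracles).
pattern_matrix <- function(patterns, mu) {
  shape <- patterns$shape
  M <- matrix(0, shape$N * shape$S, shape$T)
  M[cbind(patterns$active[, mu], patterns$bin[, mu])] <- 1
  M
}

#' Generate target firing-rate profiles
#'
#' Target rates for each projection neurone, time bin and pattern are i.i.d.
#' uniform on `[0, 2 * mean_rate]`, so the ensemble mean is `mean_rate`.
#'
#' @param L Number of projection neurones.
#' @param T Time bins per movement.
#' @param p Number of patterns.
#' @param mean_rate Desired mean target rate (Hz), must be positive.
#' @param seed Integer seed.
#' @return An object of class `target_rates`: numeric array `L x T x p` (Hz).
#' @examples
#' tg <- generate_targets(L = 40, T = 10, p = 2, mean_rate = 30, seed = 1)
#' range(tg$R) # within [0, 60]
#' @export
generate_targets <- function(L, T, p, mean_rate, seed) {
  if (!is.numeric(mean_rate) || length(mean_rate) != 1L || mean_rate <= 0) {
    stop("mean_rate must be a single positive number (Hz)", call. = FALSE)
  }
  set.seed(substream_seed(seed, "targets"))
  R <- array(stats::runif(L * T * p, 0, 2 * mean_rate), dim = c(L, T, p))
  structure(list(R = R), class = "target_rates")
}

#' @export
print.target_rates <- function(x, ...) {
  d <- dim(x$R)
  cat("<target_rates>", d[1], "neurones x", d[2], "bins x", d[3],
      "pattern(s), mean", round(mean(x$R), 2), "Hz\n")
  invisible(x)
}

#' @export
as_tibble.target_rates <- function(x, ...) {
  d <- dim(x$R)
  tibble::tibble(
    pattern = rep(seq_len(d[3]), each = d[1] * d[2]),
    neurone = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    rate = as.vector(x$R)
  )
}

#' Draw the random connectivity of the microzone
#'
#' Two independent random structures: the mossy fibre to Purkinje cell contact
#' mask `sigma` (each fibre contacts each Purkinje cell of its sagittal row
#' with probability 1/2, independently per (fibre, column) pair), and the
#' nuclear assignment `pn_assign` mapping each fibre to the single projection
#' neurone -- and, identically in the default model, the single nucleo-olivary
#' neurone (`no_assign`) -- that it contacts, uniform over the `L` columns.
#'
#' @param shape An [shape_params()] object.
#' @param seed Integer seed.
#' @return An object of class `mf_connectivity`: `sigma` is an `N*S x L` 0/1
#'   matrix (rows = flat fibre index), `pn_assign` and `no_assign` are integer
#'   vectors of length `N*S` with values in `1..L`.
#' @examples
#' conn <- build_connectivity(shape_params(S = 2, L = 4, N = 10, T = 3, p = 1), seed = 2)
#' table(conn$pn_assign)
#' @export
build_connectivity <- function(shape, seed) {
  stopifnot(inherits(shape, "sgdege_shape"))
  n_fib <- shape$N * shape$S
  set.seed(substream_seed(seed, "connectivity"))
  sigma <- matrix(stats::rbinom(n_fib * shape$L, 1L, 0.5), n_fib, shape$L)
  pn_assign <- sample.int(shape$L, n_fib, replace = TRUE)
  structure(list(shape = shape, sigma = sigma,
                 pn_assign = pn_assign, no_assign = pn_assign),
            class = "mf_connectivity")
}

#' @export
print.mf_connectivity <- function(x, ...) {
  cat("<mf_connectivity>", nrow(x$sigma), "fibres x", ncol(x$sigma),
      "columns; contact fraction", round(mean(x$sigma), 3), "\n")
  invisible(x)
}
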