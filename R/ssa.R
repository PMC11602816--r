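#' Lattice state constructor
#'
#' @param model an `mg_model`.
#' @param n,m non-negative integer count vectors (lengths `K_A`, `K_B`);
#'   default the empty lattice.
#' @param t simulation time.
#' @return An object of class `mg_state`.
#' @export
lattice_state <- function(model, n = NULL, m = NULL, t = 0) {
  stopifnot(inherits(model, "mg_model"))
  if (is.null(n)) n <- integer(model$K_A)
  if (is.null(m)) m <- integer(model$K_B)
  if (length(n) != model$K_A || length(m) != model$K_B)
    stop("state dimensions do not match the model", call. = FALSE)
  if (any(n < 0) || any(m < 0) || any(n != round(n)) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(n = as.integer(n), m = as.integer(m), t = t),
            class = "mg_state")
}

#' Event table of all propensities in a given state
#'
#' Enumerates every possible jump and reaction event with its propensity:
#' production (`k1` into the first A-compartment), per-direction diffusion
#' jumps `n_j D_A/h_A^2` and `m_i D_B/h_B^2` (boundary compartments only
#' jump inward), conversion `A_j -> B_i` at `k2 W[i,j] n_j` (first-order) or
#' dimerization `A_j + A_j -> B_i` at `(k2/h_A) W[i,j] n_j (n_j - 1)/2`
#' (per-pair rate `k2/h_A`, consistent with the Doi bridge `k2 = 2 rho
#' lambda`), and degradation `k3 m_i`. Cross-grid events exist only for pairs with
#' positive overlap weight.
#'
#' This R-level table is the readable reference used in tests and for small
#' systems; [simulate_ssa()] runs the equivalent compiled core.
#'
#' @param state an `mg_state` (or list with `n`, `m`).
#' @param model an `mg_model`.
#' @return A data frame with columns `kind`, `j` (source A-compartment or
#'   NA), `i` (B-compartment or NA), `propensity`.
#' @export
propensities <- function(state, model) {
  stopifnot(inherits(model, "mg_model"))
  n <- state$n; m <- state$m
  if (length(n) != model$K_A || length(m) != model$K_B)
    stop("state dimensions do not match the model", call. = FALSE)
  if (any(n < 0) || any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  KA <- model$K_A; KB <- model$K_B
  dA <- model$D_A / model$h_A^2; dB <- model$D_B / model$h_B^2
  dimer <- model$network == "dimerization"
  W <- overlap_weights(model)

  ev <- list(data.frame(kind = "produce_A", j = 1L, i = NA_integer_,
                        propensity = model$k1))
  if (KA > 1) {
    ev <- c(ev, list(
      data.frame(kind = "diffuse_A_right", j = seq_len(KA - 1L), i = NA_integer_,
                 propensity = dA * n[seq_len(KA - 1L)]),
      data.frame(kind = "diffuse_A_left", j = 2:KA, i = NA_integer_,
                 propensity = dA * n[2:KA])))
  }
  if (KB > 1) {
    ev <- c(ev, list(
      data.frame(kind = "diffuse_B_right", j = NA_integer_, i = seq_len(KB - 1L),
                 propensity = dB * m[seq_len(KB - 1L)]),
      data.frame(kind = "diffuse_B_left", j = NA_integer_, i = 2:KB,
                 propensity = dB * m[2:KB])))
  }
  nz <- which(W > 0, arr.ind = TRUE)
  if (dimer) {
    prop <- (model$k2 / (2 * model$h_A)) * W[nz] *
      pmax(n[nz[, 2]] * (n[nz[, 2]] - 1), 0)
    ev <- c(ev, list(data.frame(kind = "dimerize", j = nz[, 2], i = nz[, 1],
                                propensity = prop)))
  } else {
    ev <- c(ev, list(data.frame(kind = "convert", j = nz[, 2], i = nz[, 1],
                                propensity = model$k2 * W[nz] * n[nz[, 2]])))
  }
  ev <- c(ev, list(data.frame(kind = "degrade_B", j = NA_integer_, i = seq_len(KB),
                              propensity = model$k3 * m)))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Exact stochastic simulation of the lattice model (Gillespie direct method)
#'
#' Simulates the continuous-time Markov jump process of the dual-grid
#' lattice model exactly: exponential waiting times with the total
#' propensity, categorical event choice, state update. The compiled core
#' accumulates exact time-weighted first and second moments of every
#' compartment over `[burn_in, t_end]` plus batch means for Monte-Carlo
#' standard errors, and can record state snapshots at fixed intervals.
#'
#' @param model an `mg_model`.
#' @param t_end simulation horizon (> 0).
#' @param seed integer seed (`NULL` leaves the RNG state untouched).
#' @param init `"empty"`, `"poisson"` (Poisson draws at the stationary
#'   means, first-order network only; reduces burn-in), or an `mg_state`.
#' @param burn_in time discarded before moment accumulation.
#' @param record_interval snapshot spacing (0 = no snapshots).
#' @param nbatch number of batches for standard errors.
#' @return An object of class `mg_trajectory`: time-averaged means and
#'   variances (`mean_n`, `var_n`, `mean_m`, `var_m`), batch means,
#'   event counts, mean reaction/total propensity, snapshots, final state.
#' @export
simulate_ssa <- function(model, t_end, seed = NULL, init = "empty",
                         burn_in = 0, record_interval = 0, nbatch = 20L) {
  stopifnot(inherits(model, "mg_model"))
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (burn_in >= t_end) stop("'burn_in' must be below 't_end'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(init, "mg_state")) {
    n0 <- init$n; m0 <- init$m
  } else if (identical(init, "poisson") && model$network == "first_order") {
    sol <- solve_stationary_means(model)
    n0 <- stats::rpois(model$K_A, sol$Abar)
    m0 <- stats::rpois(model$K_B, sol$Bbar)
  } else {
    n0 <- integer(model$K_A); m0 <- integer(model$K_B)
  }
  W <- overlap_weights(model)
  res <- ssa_core(model$K_A, model$K_B, model$L, model$D_A, model$D_B,
                  model$k1, model$k2, model$k3,
                  as.integer(model$network == "dimerization"), W,
                  as.integer(n0), as.integer(m0),
                  t_end, burn_in, record_interval, as.integer(nbatch))
  res$model <- model
  res$t_end <- t_end; res$burn_in <- burn_in; res$seed <- seed
  nb <- length(res$batch_sumN)
  res$se_sumN <- stats::sd(res$batch_sumN) / sqrt(nb)
  res$se_sumM <- stats::sd(res$batch_sumM) / sqrt(nb)
  res$se_reac <- stats::sd(res$batch_reac) / sqrt(nb)
  class(res) <- "mg_trajectory"
  res
}

#' @export
print.mg_trajectory <- function(x, ...) {
  cat(sprintf("<mg_trajectory: %s, t_end = %g (burn-in %g), seed = %s>\n",
              x$model$network, x$t_end, x$burn_in,
              if (is.null(x$seed)) "NULL" else x$seed))
  cat(sprintf("  events: %s\n",
              paste(names(x$event_counts), format(x$event_counts, big.mark = ","),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  time-avg totals: A = %.4g (SE %.2g), B = %.4g (SE %.2g)\n",
              sum(x$mean_n), x$se_sumN, sum(x$mean_m), x$se_sumM))
  invisible(x)
}

#' Time-weighted steady-state moments of a piecewise-constant trajectory
#'
#' Computes time-weighted means and variances of per-compartment counts from
#' a step-function trajectory: `counts[k, ]` holds on `[times[k],
#' times[k+1])` and the last state up to `t_end`. SSA trajectories are
#' event-spaced, so time weighting (not per-sample averaging) is the
#' consistent estimator.
#'
#' For an `mg_trajectory` the exact accumulators from the simulation run are
#' returned directly (the recorded burn-in applies).
#'
#' @param trajectory an `mg_trajectory`, or a list with `times` (strictly
#'   increasing), `counts` (matrix, one row per time) and `t_end`.
#' @param burn_in time discarded from the start (matrix form only).
#' @return List with `mean` and `var` vectors.
#' @export
estimate_steady_state <- function(trajectory, burn_in = 0) {
  if (inherits(trajectory, "mg_trajectory")) {
    return(list(mean = c(trajectory$mean_n, trajectory$mean_m),
                var = c(trajectory$var_n, trajectory$var_m)))
  }
  times <- trajectory$times
  counts <- as.matrix(trajectory$counts)
  t_end <- trajectory$t_end
  if (is.null(t_end)) t_end <- times[length(times)]
  if (burn_in >= t_end) stop("'burn_in' must be below the trajectory horizon", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  ends <- c(times[-1], t_end)
  w <- pmax(pmin(ends, t_end) - pmax(times, burn_in), 0)
  Tw <- sum(w)
  if (Tw <= 0) stop("no trajectory mass after burn-in", call. = FALSE)
  mu <- as.numeric(crossprod(counts, w)) / Tw
  m2 <- as.numeric(crossprod(counts^2, w)) / Tw
  list(mean = mu, var = m2 - mu^2)
}
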