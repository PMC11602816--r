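#' Brownian-dynamics configuration
#'
#' Settings for the particle-based ground-truth simulator: explicit
#' Euler-Maruyama time stepping with reflecting boundaries at 0 and `L`,
#' Poisson production at the source, per-particle exponential survival
#' sampling for first-order events, and the Doi (lambda-rho) rule for
#' dimerization (a pair within distance `rho` fires at rate `lambda`).
#'
#' The default timestep keeps the root-mean-square displacement per step of
#' the fastest species below `rho/2` for the dimerization network
#' (`dt <= rho^2 / (8 D_A)`), so particles do not tunnel through the
#' reaction radius; a warning is issued when either this or `lambda*dt <=
#' 0.1` is violated.
#'
#' @param dt timestep (> 0); default `1e-3` (first-order) or
#'   `rho^2/(8 D_A)` capped at `1e-3` (dimerization).
#' @param t_end simulation horizon.
#' @param burn_in time discarded before accumulation.
#' @param seed integer seed.
#' @param source `"origin"` (new A exactly at x = 0, the delta-source
#'   convention) or `"uniform_first"` (uniform on the first A-compartment,
#'   mirroring the lattice production reaction).
#' @param product placement of the dimer product B: `"midpoint"` (default),
#'   `"first"` or `"second"` reactant position.
#' @param nbatch batches for Monte-Carlo standard errors.
#' @param model optional `mg_model` used to derive the dimerization default
#'   `dt` and to validate warnings.
#' @return A list of class `bd_config`.
#' @export
bd_config <- function(dt = NULL, t_end = 1000, burn_in = 0, seed = NULL,
                      source = c("origin", "uniform_first"),
                      product = c("midpoint", "first", "second"),
                      nbatch = 20L, model = NULL) {
  source <- match.arg(source)
  product <- match.arg(product)
  if (is.null(dt)) {
    dt <- 1e-3
    if (!is.null(model) && model$network == "dimerization" &&
        !is.null(model$rho) && model$D_A > 0)
      dt <- min(1e-3, model$rho^2 / (8 * model$D_A))
  }
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (burn_in >= t_end) stop("'burn_in' must be below 't_end'", call. = FALSE)
  if (!is.null(model)) {
    if (model$network == "dimerization" && !is.null(model$lambda) &&
        model$lambda * dt > 0.1)
      warning("lambda * dt > 0.1: per-step reaction probability is not small")
    if (model$network == "dimerization" && !is.null(model$rho) &&
        sqrt(2 * model$D_A * dt) > model$rho / 2)
      warning("per-step displacement exceeds rho/2: consider a smaller dt")
  }
  structure(list(dt = dt, t_end = t_end, burn_in = burn_in, seed = seed,
                 source = source, product = product, nbatch = as.integer(nbatch)),
            class = "bd_config")
}

#' All unordered pairs of sorted positions within a distance
#'
#' Sorted sweep in `O(n + #pairs)`: for each particle, scan forward until
#' the gap exceeds `rho`.
#'
#' @param positions sorted numeric vector.
#' @param rho maximum separation (inclusive).
#' @return Two-column integer matrix of index pairs (i < j); zero rows when
#'   none.
#' @export
pair_candidates <- function(positions, rho) {
  n <- length(positions)
  if (is.unsorted(positions)) stop("'positions' must be sorted", call. = FALSE)
  out_i <- integer(0); out_j <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && positions[j] - positions[i] <= rho) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        j <- j + 1L
      }
    }
  }
  cbind(i = out_i, j = out_j)
}

#' One Brownian-dynamics step (reference implementation)
#'
#' Readable R implementation of a single timestep, mirroring the compiled
#' core used by [bd_simulate()]: Gaussian displacements with reflection,
#' Poisson production, exponential-survival first-order events, and Doi
#' pair reactions resolved in random order (a consumed particle invalidates
#' its remaining candidate pairs).
#'
#' @param state list with numeric position vectors `ax`, `bx` and time `t`.
#' @param model an `mg_model`.
#' @param config a `bd_config`.
#' @return The updated state.
#' @export
bd_step <- function(state, model, config) {
  stopifnot(inherits(model, "mg_model"))
  dt <- config$dt
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  L <- model$L
  reflect <- function(x) {
    p <- x %% (2 * L)
    ifelse(p <= L, p, 2 * L - p)
  }
  ax <- state$ax; bx <- state$bx
  if (length(ax)) ax <- reflect(ax + stats::rnorm(length(ax), 0, sqrt(2 * model$D_A * dt)))
  if (length(bx)) bx <- reflect(bx + stats::rnorm(length(bx), 0, sqrt(2 * model$D_B * dt)))
  nnew <- stats::rpois(1, model$k1 * dt)
  if (nnew > 0) {
    ax <- c(ax, if (config$source == "uniform_first")
      stats::runif(nnew, 0, model$h_A) else rep(0, nnew))
  }
  if (model$network == "first_order") {
    fire <- stats::runif(length(ax)) < 1 - exp(-model$k2 * dt)
    if (any(fire)) { bx <- c(bx, ax[fire]); ax <- ax[!fire] }
  } else if (length(ax) >= 2) {
    ord <- order(ax)
    pairs <- pair_candidates(ax[ord], model$rho)
    if (nrow(pairs)) {
      pairs <- matrix(ord[pairs], ncol = 2)  # back to original indices
      pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
      pl <- 1 - exp(-model$lambda * dt)
      alive <- rep(TRUE, length(ax))
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (!alive[i] || !alive[j]) next
        if (stats::runif(1) < pl) {
          alive[i] <- alive[j] <- FALSE
          bx <- c(bx, switch(config$product,
                             midpoint = (ax[i] + ax[j]) / 2,
                             first = ax[i], second = ax[j]))
        }
      }
      ax <- ax[alive]
    }
  }
  if (length(bx)) bx <- bx[stats::runif(length(bx)) >= 1 - exp(-model$k3 * dt)]
  list(ax = ax, bx = bx, t = state$t + dt)
}

#' Long-run Brownian-dynamics simulation with binned profiles
#'
#' Runs the compiled particle simulator and returns time-averaged binned
#' concentration estimates on the model's A- and B-grids, total population
#' estimates, and batch-mean standard errors.
#'
#' @param model an `mg_model`.
#' @param config a `bd_config`.
#' @param init optional list with initial position vectors `ax`, `bx`.
#' @return Object of class `bd_result`: per-bin mean counts and
#'   concentrations with SEs, `A_total`/`B_total` with SEs, final
#'   positions, and the configuration.
#' @export
bd_simulate <- function(model, config = bd_config(model = model), init = NULL) {
  stopifnot(inherits(model, "mg_model"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ax <- if (is.null(init)) numeric(0) else init$ax
  bx <- if (is.null(init)) numeric(0) else init$bx
  res <- bd_core(model$L, model$D_A, model$D_B,
                 model$k1, model$k2, model$k3,
                 as.integer(model$network == "dimerization"),
                 if (is.null(model$lambda)) 0 else model$lambda,
                 if (is.null(model$rho)) 0 else model$rho,
                 config$dt, config$t_end, config$burn_in,
                 model$K_A, model$K_B,
                 as.integer(config$source == "uniform_first"),
                 match(config$product, c("midpoint", "first", "second")) - 1L,
                 as.numeric(ax), as.numeric(bx), config$nbatch)
  res$model <- model; res$config <- config
  res$conc_A <- res$mean_counts_A / model$h_A
  res$conc_B <- res$mean_counts_B / model$h_B
  res$conc_A_se <- res$se_counts_A / model$h_A
  res$conc_B_se <- res$se_counts_B / model$h_B
  class(res) <- "bd_result"
  res
}

#' @export
print.bd_result <- function(x, ...) {
  cat(sprintf("<bd_result: %s, t_end = %g, dt = %g>\n",
              x$model$network, x$config$t_end, x$config$dt))
  cat(sprintf("  A_total = %.4g (SE %.2g), B_total = %.4g (SE %.2g)\n",
              x$A_total, x$A_total_se, x$B_total, x$B_total_se))
  invisible(x)
}
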