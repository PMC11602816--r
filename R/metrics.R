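#' Piecewise-constant concentration profile from mean counts
#'
#' Converts a vector of per-compartment mean counts into the step-function
#' concentration `counts[i]/h` on `[(i-1)h, i h)`. The profile integrates
#' exactly to `sum(counts)`.
#'
#' @param counts non-negative numeric vector.
#' @param h compartment size (> 0).
#' @return Object of class `mg_profile`: list with `counts`, `h`, `breaks`,
#'   `values` (concentrations) and `L`.
#' @export
piecewise_profile <- function(counts, h) {
  if (h <= 0) stop("'h' must be positive", call. = FALSE)
  if (any(counts < 0)) stop("'counts' must be non-negative", call. = FALSE)
  K <- length(counts)
  structure(list(counts = as.numeric(counts), h = h,
                 breaks = (0:K) * h, values = as.numeric(counts) / h,
                 L = K * h),
            class = "mg_profile")
}

#' Evaluate a piecewise profile at positions
#' @param profile an `mg_profile`.
#' @param x positions in `[0, L]`.
#' @return Concentrations at `x` (right endpoint maps to the last bin).
#' @export
profile_at <- function(profile, x) {
  i <- pmin(pmax(floor(x / profile$h) + 1, 1), length(profile$values))
  profile$values[i]
}

#' Bin a profile or function back onto a grid
#' @param f an `mg_profile` or a concentration function.
#' @param K number of bins on `[0, L]`.
#' @param L domain length.
#' @return Counts per bin (integral of the concentration over each bin).
#' @export
bin_profile <- function(f, K, L) {
  h <- L / K
  vapply(seq_len(K), function(i) {
    lo <- (i - 1) * h; hi <- i * h
    if (inherits(f, "mg_profile")) {
      br <- sort(unique(c(lo, hi, f$breaks[f$breaks > lo & f$breaks < hi])))
      sum(profile_at(f, (br[-1] + br[-length(br)]) / 2) * diff(br))
    } else {
      stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
    }
  }, numeric(1))
}

#' L1 distance between a reference and an approximate concentration profile
#'
#' Computes `int_0^L |reference(x) - approx(x)| dx`. A piecewise reference
#' is integrated exactly on the merged breakpoint grid; a smooth (analytic
#' or interpolated) reference is integrated per compartment with adaptive
#' quadrature, splitting at sign changes of the difference so the absolute
#' value never crosses zero inside a quadrature panel.
#'
#' @param reference an `mg_profile` or a vectorized concentration function
#'   on `[0, L]`.
#' @param approx an `mg_profile`.
#' @param rel_tol quadrature relative tolerance (function reference).
#' @return The L1 error (same units as counts: molecules).
#' @export
l1_error <- function(reference, approx, rel_tol = 1e-8) {
  stopifnot(inherits(approx, "mg_profile"))
  if (inherits(reference, "mg_profile")) {
    if (abs(reference$L - approx$L) > 1e-9 * max(reference$L, approx$L))
      stop("profiles are defined on different domains", call. = FALSE)
    br <- sort(unique(c(reference$breaks, approx$breaks)))
    mid <- (br[-1] + br[-length(br)]) / 2
    return(sum(abs(profile_at(reference, mid) - profile_at(approx, mid)) * diff(br)))
  }
  if (!is.function(reference))
    stop("'reference' must be an mg_profile or a function", call. = FALSE)
  total <- 0
  for (i in seq_along(approx$values)) {
    lo <- approx$breaks[i]; hi <- approx$breaks[i + 1]
    ci <- approx$values[i]
    g <- function(x) reference(x) - ci
    # locate sign changes on a fine scan, then integrate |g| piecewise
    xs <- seq(lo, hi, length.out = 17)
    gs <- g(xs)
    cuts <- lo
    for (q in seq_len(length(xs) - 1)) {
      if (gs[q] == 0 || gs[q] * gs[q + 1] < 0) {
        r <- tryCatch(stats::uniroot(g, c(xs[q], xs[q + 1]), tol = 1e-14)$root,
                      error = function(e) NULL)
        if (!is.null(r)) cuts <- c(cuts, r)
      }
    }
    cuts <- sort(unique(pmin(pmax(c(cuts, hi), lo), hi)))
    for (q in seq_len(length(cuts) - 1)) {
      if (cuts[q + 1] - cuts[q] < 1e-15) next
      v <- stats::integrate(g, cuts[q], cuts[q + 1], rel.tol = rel_tol,
                            subdivisions = 200L)$value
      total <- total + abs(v)
    }
  }
  total
}

#' Total-count error against a reference concentration
#'
#' `|sum(counts) - int_0^L reference(x) dx|`: the discrepancy in the total
#' population, a diagnostic that is identically zero for the first-order
#' network but not for dimerization.
#'
#' @param reference concentration function or `mg_profile` on `[0, L]`.
#' @param approx an `mg_profile`.
#' @return Absolute total-count error.
#' @export
err_total <- function(reference, approx) {
  stopifnot(inherits(approx, "mg_profile"))
  ref_int <- if (inherits(reference, "mg_profile")) sum(reference$counts)
  else stats::integrate(reference, 0, approx$L, rel.tol = 1e-8)$value
  abs(sum(approx$counts) - ref_int)
}

#' Propensity-based simulation cost (first-order network)
#'
#' Closed-form total event rate at stationarity,
#' `c(K_B, gamma) = 3 k1 + 2 (D_A/h_A^2) k1/k2 + 2 (D_B/h_B^2) k1/k3`,
#' which the Gillespie iteration count per unit time scales with.
#'
#' @param model an `mg_model` with `network = "first_order"`.
#' @return The cost (events per unit time).
#' @export
cost_first_order <- function(model) {
  stopifnot(inherits(model, "mg_model"))
  if (model$network != "first_order")
    stop("use cost_dimerization() for the dimerization network", call. = FALSE)
  3 * model$k1 +
    2 * model$D_A / model$h_A^2 * model$k1 / model$k2 +
    2 * model$D_B / model$h_B^2 * model$k1 / model$k3
}

#' Propensity-based simulation cost (dimerization network)
#'
#' `c = 2 (D_A/h_A^2) A_total + 2 (D_B/h_B^2) B_total + k1 +
#' k2 A_total (A_total - 1) + k3 B_total`, quadratic in the A population.
#' The totals have no closed form for this network and must be estimated
#' from long-run simulation.
#'
#' @param model an `mg_model` with `network = "dimerization"`.
#' @param A_total,B_total estimated steady-state population totals (>= 0).
#' @return The cost (events per unit time).
#' @export
cost_dimerization <- function(model, A_total, B_total) {
  stopifnot(inherits(model, "mg_model"))
  if (model$network != "dimerization")
    stop("use cost_first_order() for the first-order network", call. = FALSE)
  if (A_total < 0 || B_total < 0) stop("totals must be non-negative", call. = FALSE)
  2 * model$D_A / model$h_A^2 * A_total +
    2 * model$D_B / model$h_B^2 * B_total +
    model$k1 + model$k2 * A_total * (A_total - 1) + model$k3 * B_total
}

#' Error/cost sweep over design points (first-order network)
#'
#' For each `(K_B, gamma)` design point, solves the stationary lattice
#' system, forms the piecewise B-concentration, and records its L1 error
#' against the analytic stationary profile together with the closed-form
#' cost. `gamma = 1` rows are tagged `"standard"`, others `"multigrid"`.
#'
#' @param design data frame with columns `K_B` and `gamma` (each `gamma`
#'   must divide its `K_B`).
#' @param L,D_A,D_B,k1,k2,k3 model parameters.
#' @return Data frame of records: `K_B`, `gamma`, `K_A`, `err`, `cost`,
#'   `method`.
#' @export
sweep_first_order <- function(design, L, D_A, D_B, k1, k2, k3) {
  stopifnot(is.data.frame(design), all(c("K_B", "gamma") %in% names(design)))
  ref <- NULL
  out <- lapply(seq_len(nrow(design)), function(r) {
    KB <- design$K_B[r]; g <- design$gamma[r]
    KA <- KB / g
    if (abs(KA - round(KA)) > 1e-9)
      stop(sprintf("gamma = %g does not divide K_B = %d", g, KB), call. = FALSE)
    model <- mg_model(L = L, K_A = round(KA), K_B = KB, D_A = D_A, D_B = D_B,
                      k1 = k1, k2 = k2, k3 = k3)
    sol <- solve_stationary_means(model)
    bh <- piecewise_profile(sol$Bbar, model$h_B)
    fB <- function(x) analytic_steady_state(model, "B", x, warn_domain = FALSE)
    data.frame(K_B = KB, gamma = g, K_A = round(KA),
               err = l1_error(fB, bh),
               cost = cost_first_order(model),
               method = if (g == 1) "standard" else "multigrid")
  })
  do.call(rbind, out)
}

#' Error/cost sweep for the dimerization network (simulation-based)
#'
#' For each `K_A`, estimates the steady-state B profile of the lattice model
#' by long-run SSA (averaged over seeds), and records the L1 error against a
#' Brownian-dynamics reference profile plus the propensity cost evaluated at
#' the SSA-estimated totals. The error uncertainty propagates the per-seed
#' spread of the L1 error.
#'
#' @param K_A_values coarse-grid sizes to scan.
#' @param K_B fixed fine-grid size.
#' @param base an `mg_model` template (dimerization) carrying `L`, rates and
#'   diffusion constants.
#' @param reference a `bd_result` (or `mg_profile` for the B species)
#'   serving as ground truth.
#' @param t_end,burn_in SSA horizon and burn-in per run.
#' @param seeds integer vector of seeds (one run each).
#' @return Data frame: `K_B`, `gamma`, `K_A`, `err`, `err_se`, `cost`,
#'   `method`, `A_total`, `B_total`.
#' @export
sweep_dimerization <- function(K_A_values, K_B, base, reference,
                               t_end = 1000, burn_in = 50,
                               seeds = 1:3) {
  stopifnot(inherits(base, "mg_model"), base$network == "dimerization")
  ref_profile <- if (inherits(reference, "bd_result"))
    piecewise_profile(reference$mean_counts_B, reference$model$L / length(reference$mean_counts_B))
  else reference
  out <- lapply(K_A_values, function(KA) {
    model <- mg_model(L = base$L, K_A = KA, K_B = K_B,
                      D_A = base$D_A, D_B = base$D_B,
                      k1 = base$k1, k2 = base$k2, k3 = base$k3,
                      network = "dimerization",
                      lambda = base$lambda, rho = base$rho)
    errs <- numeric(length(seeds)); At <- Bt <- numeric(length(seeds))
    for (s in seq_along(seeds)) {
      traj <- simulate_ssa(model, t_end = t_end, seed = seeds[s],
                           burn_in = burn_in)
      errs[s] <- l1_error(ref_profile, piecewise_profile(traj$mean_m, model$h_B))
      At[s] <- sum(traj$mean_n); Bt[s] <- sum(traj$mean_m)
    }
    data.frame(K_B = K_B, gamma = K_B / KA, K_A = KA,
               err = mean(errs),
               err_se = if (length(seeds) > 1) stats::sd(errs) / sqrt(length(seeds)) else NA_real_,
               cost = cost_dimerization(model, mean(At), mean(Bt)),
               method = if (K_B == KA) "standard" else "multigrid",
               A_total = mean(At), B_total = mean(Bt))
  })
  do.call(rbind, out)
}

#' Pareto front of error/cost records
#'
#' Returns the records not strictly dominated: no other record has both
#' `err <= ` and `cost <= ` with at least one strict inequality.
#' Coordinates within `tol` are treated as ties (kept). The front is
#' invariant under reordering and duplication of the input.
#'
#' @param records data frame with columns `err` and `cost`.
#' @param tol tie tolerance.
#' @return The non-dominated subset (rows of `records`).
#' @export
pareto_front <- function(records, tol = 1e-12) {
  stopifnot(is.data.frame(records), all(c("err", "cost") %in% names(records)))
  if (nrow(records) == 0) stop("'records' must be non-empty", call. = FALSE)
  keep <- vapply(seq_len(nrow(records)), function(r) {
    e <- records$err[r]; c0 <- records$cost[r]
    dominated <- (records$err <= e + tol) & (records$cost <= c0 + tol) &
      ((records$err < e - tol) | (records$cost < c0 - tol))
    !any(dominated)
  }, logical(1))
  records[keep, , drop = FALSE]
}
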