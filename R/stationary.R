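#' Discrete diffusion (graph Laplacian) matrix
#'
#' The `K x K` symmetric tridiagonal matrix `S` with off-diagonal entries 1
#' and diagonal entries -1 at the two boundary compartments (jumps only go
#' inward) and -2 in the interior. Every row sums to zero, so diffusion
#' conserves mass. `K = 1` gives the 1x1 zero matrix.
#'
#' @param K number of compartments (integer >= 1).
#' @return A sparse symmetric `Matrix::Matrix`.
#' @export
diffusion_matrix_S <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("'K' must be an integer >= 1", call. = FALSE)
  K <- as.integer(K)
  if (K == 1L) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  d <- c(-1, rep(-2, K - 2L), -1)
  Matrix::bandSparse(K, K, k = c(-1L, 0L, 1L),
                     diagonals = list(rep(1, K - 1L), d, rep(1, K - 1L)),
                     symmetric = FALSE)
}

#' Exact stationary mean copy numbers (first-order network)
#'
#' Solves the two tridiagonal linear systems for the stationary mean counts
#' of the first-order conversion network:
#' `(D_A/h_A^2 S_A - k2 I) Abar = -k1 e1` for the coarse grid, and
#' `(D_B/h_B^2 S_B - k3 I) Bbar = -k2 W Abar` for the fine grid, where `W`
#' is the overlap-weight matrix (for integer gamma this equals the block
#' form `-(k2/gamma) M Abar`). With equal grids the two systems reduce to
#' the single-grid lattice model.
#'
#' The stationary law of this network is a product of independent Poisson
#' distributions with these means, so `Abar`/`Bbar` determine means and
#' variances alike.
#'
#' @param model an `mg_model` with `network = "first_order"`.
#' @return An object of class `mg_stationary`: list with `Abar`, `Bbar`,
#'   `A_total`, `B_total`, and the model.
#' @export
solve_stationary_means <- function(model) {
  stopifnot(inherits(model, "mg_model"))
  if (model$network != "first_order")
    stop("no closed-form stationary system for the dimerization network; ",
         "use simulate_ssa() / truncated_generator()", call. = FALSE)
  KA <- model$K_A; KB <- model$K_B
  dA <- model$D_A / model$h_A^2
  dB <- model$D_B / model$h_B^2
  MA <- dA * diffusion_matrix_S(KA) - model$k2 * Matrix::Diagonal(KA)
  MB <- dB * diffusion_matrix_S(KB) - model$k3 * Matrix::Diagonal(KB)
  rhsA <- c(-model$k1, rep(0, KA - 1L))
  if (model$k2 == 0 && model$D_A == 0)
    stop("singular stationary system: all removal rates for A are zero", call. = FALSE)
  if (model$k2 == 0 || model$k3 == 0)
    stop("singular stationary system: k2 and k3 must be positive", call. = FALSE)
  Abar <- as.numeric(Matrix::solve(MA, rhsA))
  W <- overlap_weights(model)
  Bbar <- as.numeric(Matrix::solve(MB, -model$k2 * (W %*% Abar)))
  resA <- max(abs(as.numeric(MA %*% Abar) - rhsA))
  resB <- max(abs(as.numeric(MB %*% Bbar) + model$k2 * as.numeric(W %*% Abar)))
  scale <- max(model$k1, 1)
  if (resA > 1e-10 * scale || resB > 1e-10 * scale)
    stop(sprintf("stationary solve residual too large (%.3e, %.3e)", resA, resB),
         call. = FALSE)
  structure(list(Abar = Abar, Bbar = Bbar,
                 A_total = sum(Abar), B_total = sum(Bbar),
                 model = model),
            class = "mg_stationary")
}

#' @export
print.mg_stationary <- function(x, ...) {
  cat(sprintf("<mg_stationary: K_A = %d, K_B = %d>\n",
              length(x$Abar), length(x$Bbar)))
  cat(sprintf("  A_total = %.6g, B_total = %.6g\n", x$A_total, x$B_total))
  invisible(x)
}

#' Product-Poisson stationary probability
#'
#' Probability of a lattice state under the stationary law of the first-order
#' network, which factorizes into independent Poissons with means `Abar[j]`
#' and `Bbar[i]`. Computed in log-space.
#'
#' @param solution an `mg_stationary` object.
#' @param n,m non-negative integer count vectors of lengths `K_A`, `K_B`.
#' @param log return the log-probability.
#' @return A single probability (or log-probability).
#' @export
poisson_product_pmf <- function(solution, n, m, log = FALSE) {
  stopifnot(inherits(solution, "mg_stationary"))
  if (length(n) != length(solution$Abar) || length(m) != length(solution$Bbar))
    stop("state dimensions do not match the solution", call. = FALSE)
  if (any(n < 0) || any(m < 0) || any(n != round(n)) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  lp <- sum(stats::dpois(n, solution$Abar, log = TRUE)) +
    sum(stats::dpois(m, solution$Bbar, log = TRUE))
  if (log) lp else exp(lp)
}

#' Analytic stationary concentration profiles (first-order network)
#'
#' Closed-form stationary solution of the macroscopic reaction-diffusion
#' equations with a point source at the origin on an unbounded domain:
#' `abar(x) = k1 / sqrt(D_A k2) * exp(-sqrt(k2/D_A) |x|)` for species A, and
#' for B the two-exponential combination with decay lengths
#' `sqrt(D_A/k2)` and `sqrt(D_B/k3)`. Evaluated with `|x|`, so the half-line
#' convention (reflecting boundary at the source) holds. When
#' `D_A k3 = D_B k2` the generic formula degenerates (equal decay lengths);
#' the confluent limit `k1 (1/alpha + |x|) exp(-alpha |x|) / (2 D_B)` with
#' `alpha = sqrt(k2/D_A)` is used instead.
#'
#' The profiles integrate to `k1/k2` (A) and `k1/k3` (B) over the half-line.
#' A warning is issued when `abar(L)/abar(0) > 1e-3`, i.e. the finite domain
#' is too short for the unbounded-domain approximation to be compared
#' against compartment models on `[0, L]`.
#'
#' @param model an `mg_model` with `network = "first_order"`.
#' @param species `"A"` or `"B"`.
#' @param x positions (>= 0, vectorized).
#' @param warn_domain check the domain-length condition (default TRUE).
#' @return Concentrations (molecules per unit length) at `x`.
#' @export
analytic_steady_state <- function(model, species = c("A", "B"), x,
                                  warn_domain = TRUE) {
  stopifnot(inherits(model, "mg_model"))
  species <- match.arg(species)
  if (model$network != "first_order")
    stop("no closed-form profile for the dimerization network; use bd_simulate()",
         call. = FALSE)
  k1 <- model$k1; k2 <- model$k2; k3 <- model$k3
  DA <- model$D_A; DB <- model$D_B
  alpha <- sqrt(k2 / DA)
  if (warn_domain && exp(-alpha * model$L) > 1e-3)
    warning(sprintf(
      "abar(L)/abar(0) = %.2g > 1e-3: domain may be too short for the unbounded-domain profile",
      exp(-alpha * model$L)))
  x <- abs(x)
  if (species == "A")
    return(k1 / sqrt(DA * k2) * exp(-alpha * x))
  beta <- sqrt(k3 / DB)
  den <- DA * k3 - DB * k2
  if (abs(den) < 1e-9 * max(DA * k3, DB * k2)) {
    # confluent limit, equal decay lengths
    return(k1 * (1 / alpha + x) * exp(-alpha * x) / (2 * DB))
  }
  k1 * sqrt(k2 * DA) / den * exp(-alpha * x) +
    k1 * k2 * sqrt(DB) / (-den * sqrt(k3)) * exp(-beta * x)
}

#' Steady-state propensity totals (first-order network)
#'
#' The total reaction propensity at stationarity is
#' `r_reac = k1 + k2 A_total + k3 B_total = 3 k1` (using the closed-form
#' totals `A_total = k1/k2`, `B_total = k1/k3`). The diffusion propensity is
#' bounded by `2 (D_A/h_A^2) A_total + 2 (D_B/h_B^2) B_total`; the exact
#' value subtracts the boundary compartments, which can only jump inward.
#' These totals set the Gillespie event rate and hence simulation cost.
#'
#' @param model an `mg_model` with `network = "first_order"`.
#' @param solution optionally a precomputed `mg_stationary`.
#' @return List with `r_reac`, `r_diff_bound` and the exact `r_diff`.
#' @export
steady_state_propensities <- function(model, solution = NULL) {
  stopifnot(inherits(model, "mg_model"))
  if (model$network != "first_order")
    stop("closed-form propensities exist for the first-order network only",
         call. = FALSE)
  if (is.null(solution)) solution <- solve_stationary_means(model)
  At <- solution$A_total; Bt <- solution$B_total
  dA <- model$D_A / model$h_A^2; dB <- model$D_B / model$h_B^2
  r_reac <- model$k1 + model$k2 * At + model$k3 * Bt
  r_diff <- dA * (2 * At - solution$Abar[1] - solution$Abar[model$K_A]) +
    dB * (2 * Bt - solution$Bbar[1] - solution$Bbar[model$K_B])
  list(r_reac = r_reac,
       r_diff_bound = 2 * dA * At + 2 * dB * Bt,
       r_diff = r_diff)
}

#' Brute-force stationary law on a truncated state space
#'
#' Test oracle: assembles the full master-equation generator of the lattice
#' model (diffusion jumps, production, conversion or dimerization with the
#' `(k2/h_A) n (n-1)/2` propensity, degradation) on the finite state space
#' `{0..capA}^K_A x {0..capB}^K_B` and solves for its stationary
#' distribution. Truncation is reflecting: transitions that would leave the
#' box are removed (outflow redirected to self), so the generator remains a
#' proper rate matrix. Intended for toy systems only.
#'
#' @param model an `mg_model` (either network).
#' @param cap_A,cap_B per-compartment count caps (scalars, recycled).
#' @return List with the state matrix (`states`, one row per state, columns
#'   the `K_A + K_B` counts), stationary probabilities `pi`, and the
#'   stationary marginal means `mean_n`, `mean_m`.
#' @export
truncated_generator <- function(model, cap_A, cap_B) {
  stopifnot(inherits(model, "mg_model"))
  KA <- model$K_A; KB <- model$K_B
  capA <- rep_len(as.integer(cap_A), KA)
  capB <- rep_len(as.integer(cap_B), KB)
  dims <- c(capA + 1L, capB + 1L)
  nstate <- prod(dims)
  if (nstate > 1e6) stop("truncated state space too large (> 1e6 states)", call. = FALSE)

  # enumerate states: column q of `states` cycles fastest for q = 1
  states <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
  colnames(states) <- NULL
  strides <- cumprod(c(1L, dims[-length(dims)]))
  dimer <- model$network == "dimerization"
  dA <- model$D_A / model$h_A^2
  dB <- model$D_B / model$h_B^2
  c2 <- if (dimer) model$k2 / (2 * model$h_A) else model$k2
  W <- overlap_weights(model)

  ii <- list(); jj <- list(); xx <- list(); nb <- 0L
  add <- function(from, to, rate) {
    keep <- rate > 0
    if (!any(keep)) return(invisible())
    nb <<- nb + 1L
    ii[[nb]] <<- to[keep]; jj[[nb]] <<- from[keep]; xx[[nb]] <<- rate[keep]
  }
  idx_all <- seq_len(nstate)

  # production into A-compartment 1
  ok <- states[, 1] < capA[1]
  add(idx_all[ok], idx_all[ok] + strides[1], rep(model$k1, sum(ok)))

  # A diffusion
  if (KA > 1) for (j in seq_len(KA - 1L)) {
    for (d in c(1L, -1L)) { # j <-> j+1
      src <- if (d == 1L) j else j + 1L
      dst <- if (d == 1L) j + 1L else j
      ok <- states[, src] > 0 & states[, dst] < capA[dst]
      add(idx_all[ok],
          idx_all[ok] - strides[src] + strides[dst],
          dA * states[ok, src])
    }
  }
  # B diffusion
  if (KB > 1) for (i in seq_len(KB - 1L)) {
    for (d in c(1L, -1L)) {
      src <- KA + (if (d == 1L) i else i + 1L)
      dst <- KA + (if (d == 1L) i + 1L else i)
      ok <- states[, src] > 0 & states[, dst] < capB[dst - KA]
      add(idx_all[ok],
          idx_all[ok] - strides[src] + strides[dst],
          dB * states[ok, src])
    }
  }
  # conversion / dimerization A_j -> B_i
  for (j in seq_len(KA)) for (i in seq_len(KB)) {
    w <- W[i, j]
    if (w <= 0) next
    if (dimer) {
      ok <- states[, j] >= 2 & states[, KA + i] < capB[i]
      rate <- c2 * w * pmax(states[ok, j] * (states[ok, j] - 1), 0)
      add(idx_all[ok], idx_all[ok] - 2L * strides[j] + strides[KA + i], rate)
    } else {
      ok <- states[, j] > 0 & states[, KA + i] < capB[i]
      add(idx_all[ok], idx_all[ok] - strides[j] + strides[KA + i],
          c2 * w * states[ok, j])
    }
  }
  # degradation
  for (i in seq_len(KB)) {
    ok <- states[, KA + i] > 0
    add(idx_all[ok], idx_all[ok] - strides[KA + i],
        model$k3 * states[ok, KA + i])
  }

  if (nb == 0L) {
    # all rates zero: stationary law is the point mass at the initial state;
    # return the uniform-in-support convention: identity dynamics
    pi <- rep(0, nstate); pi[1] <- 1
    return(list(states = states, pi = pi,
                mean_n = states[1, seq_len(KA)],
                mean_m = states[1, KA + seq_len(KB)],
                note = "zero generator: any point mass is stationary; initial state returned"))
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nstate, nstate))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  # Q[i, j] = rate j -> i (columns sum to 0); stationary law solves Q pi = 0.
  # Pin pi[ref] = 1 at (approximately) the modal state and drop the ref-th
  # balance equation: this keeps the system sparse (a sum-to-one replacement
  # row would be dense and cause catastrophic LU fill-in) and keeps the
  # unnormalized solution <= O(1), avoiding overflow. The mode is located
  # with a short uniformized power iteration.
  if (nstate == 1L) {
    pi <- 1
  } else {
    lam <- 1.01 * max(abs(Matrix::diag(Q))) + 1e-12
    v <- rep(1 / nstate, nstate)
    if (nstate <= 5000L) {
      # short power burn-in to locate the modal state, then exact LU solve
      for (it in 1:200) {
        v <- v + as.numeric(Q %*% v) / lam
        v[v < 0] <- 0
        v <- v / sum(v)
      }
      ref <- which.max(v)
      A <- Q[-ref, -ref, drop = FALSE]
      b <- -as.numeric(Q[-ref, ref, drop = FALSE])
      pi_rest <- as.numeric(Matrix::solve(A, b))
      pi <- append(pi_rest, 1, after = ref - 1L)
      pi[pi < 0 & pi > -1e-9] <- 0
      pi <- pi / sum(pi)
    } else {
      # sparse LU fill-in is prohibitive on large multi-compartment lattices;
      # iterate the uniformized chain pi <- pi (I + Q/lam) to stationarity
      it <- 0L
      repeat {
        for (k in 1:100) {
          v <- v + as.numeric(Q %*% v) / lam
          v[v < 0] <- 0
        }
        v <- v / sum(v)
        it <- it + 100L
        res <- sum(abs(as.numeric(Q %*% v))) / lam
        if (res < 1e-12 || it >= 2e5) break
      }
      if (res >= 1e-12)
        warning(sprintf("power iteration stopped at residual %.2e", res))
      pi <- v
    }
  }
  mean_n <- as.numeric(crossprod(states[, seq_len(KA), drop = FALSE], pi))
  mean_m <- as.numeric(crossprod(states[, KA + seq_len(KB), drop = FALSE], pi))
  list(states = states, pi = pi, mean_n = mean_n, mean_m = mean_m)
}

#' Export a stationary solution as CSV / JSON summary
#'
#' Writes a per-compartment table (index, interval, mean count, piecewise
#' concentration) for each species and, optionally, a JSON summary with the
#' totals and steady-state propensities.
#'
#' @param solution an `mg_stationary`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return Invisibly, the exported data frame.
#' @export
export_stationary <- function(solution, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(solution, "mg_stationary"))
  model <- solution$model
  tabA <- compartment_intervals(model, "A")
  tabA$species <- "A"; tabA$mean_count <- solution$Abar
  tabA$concentration <- solution$Abar / model$h_A
  tabB <- compartment_intervals(model, "B")
  tabB$species <- "B"; tabB$mean_count <- solution$Bbar
  tabB$concentration <- solution$Bbar / model$h_B
  tab <- rbind(tabA, tabB)[, c("species", "index", "lo", "hi",
                               "mean_count", "concentration")]
  names(tab)[3:4] <- c("x_lo", "x_hi")
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    pr <- steady_state_propensities(model, solution)
    jsonlite::write_json(
      list(A_total = solution$A_total, B_total = solution$B_total,
           r_reac = pr$r_reac, r_diff_bound = pr$r_diff_bound),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
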