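test_that("diffusion matrix has the lattice Laplacian structure", {
  S3 <- as.matrix(diffusion_matrix_S(3))
  expect_equal(unname(S3),
               rbind(c(-1, 1, 0), c(1, -2, 1), c(0, 1, -1)))
  for (K in c(1, 2, 7, 40)) {
    S <- diffusion_matrix_S(K)
    expect_equal(as.numeric(Matrix::rowSums(S)), rep(0, K))  # mass conservation
    expect_equal(as.matrix(S), t(as.matrix(S)))
  }
  expect_equal(as.matrix(diffusion_matrix_S(1)), matrix(0, 1, 1))
  expect_error(diffusion_matrix_S(0))
})

test_that("stationary totals equal k1/k2 and k1/k3 for any grid pair", {
  for (dims in list(c(40L, 40L), c(10L, 40L), c(15L, 60L), c(7L, 19L))) {
    sol <- solve_stationary_means(fig1_model(dims[1], dims[2]))
    expect_equal(sol$A_total, 50, tolerance = 1e-10)
    expect_equal(sol$B_total, 100, tolerance = 1e-10)
    expect_true(all(sol$Abar >= 0) && all(sol$Bbar >= 0))
  }
  expect_error(solve_stationary_means(fig6_model()), "dimerization")
})

test_that("gamma = 1 multi-grid solution equals the single-grid solution", {
  # the generalized right-hand side -k2 W Abar reduces to -k2 Abar when W = I
  sol <- solve_stationary_means(fig1_model(40L, 40L))
  m <- fig1_model(40L, 40L)
  dB <- m$D_B / m$h_B^2
  MB <- dB * as.matrix(diffusion_matrix_S(40)) - m$k3 * diag(40)
  expect_equal(as.numeric(solve(MB, -m$k2 * sol$Abar)), sol$Bbar,
               tolerance = 1e-9)
})

test_that("coarse-graining error in Bbar grows monotonically with gamma", {
  B1 <- solve_stationary_means(fig1_model(60L, 60L))$Bbar
  KA <- c(30L, 20L, 15L, 12L, 10L, 6L, 4L, 3L)
  dif <- vapply(KA, function(k)
    sum(abs(B1 - solve_stationary_means(fig1_model(k, 60L))$Bbar)),
    numeric(1))
  expect_true(all(diff(dif) > 0))
})

test_that("product-Poisson pmf normalizes and matches dpois factorization", {
  sol <- solve_stationary_means(toy_model())
  expect_equal(poisson_product_pmf(sol, 0L, 0L),
               exp(-(sol$A_total + sol$B_total)))
  # normalization over a truncated space covering > 8 SDs
  capA <- ceiling(sol$A_total + 10 * sqrt(sol$A_total))
  capB <- ceiling(sol$B_total + 10 * sqrt(sol$B_total))
  grid <- expand.grid(n = 0:capA, m = 0:capB)
  tot <- sum(mapply(function(n, m) poisson_product_pmf(sol, n, m),
                    grid$n, grid$m))
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_error(poisson_product_pmf(sol, -1L, 0L), "non-negative")
})

test_that("analytic profiles integrate to the closed-form totals", {
  m <- fig1_model()
  fA <- function(x) analytic_steady_state(m, "A", x)
  fB <- function(x) analytic_steady_state(m, "B", x)
  expect_equal(stats::integrate(fA, 0, Inf, rel.tol = 1e-8)$value, 50,
               tolerance = 1e-6)
  expect_equal(stats::integrate(fB, 0, Inf, rel.tol = 1e-8)$value, 100,
               tolerance = 1e-6)
  expect_equal(analytic_steady_state(m, "A", 0),
               m$k1 / sqrt(m$D_A * m$k2))  # = 176.777
  expect_equal(analytic_steady_state(m, "A", 0), 176.777, tolerance = 1e-5)
  # decay to zero far from the source
  expect_lt(fB(50), 1e-10)
  # degenerate equal-decay-length branch still integrates to k1/k3
  md <- mg_model(L = 2, K_A = 10, K_B = 10, D_A = 0.16, D_B = 0.04,
                 k1 = 100, k2 = 2, k3 = 0.5)  # D_A k3 = 0.08 = D_B k2
  fBd <- function(x) analytic_steady_state(md, "B", x, warn_domain = FALSE)
  expect_equal(stats::integrate(fBd, 0, Inf, rel.tol = 1e-8)$value,
               md$k1 / md$k3, tolerance = 1e-6)
})

test_that("analytic A profile solves the stationary two-point ODE", {
  # independent oracle: solve D_A a'' - k2 a = 0 on [x0, X] as a BVP with
  # boundary values from the formula, via a second-order finite-difference
  # scheme, and compare in the interior
  m <- fig1_model()
  x0 <- 0.1; X <- 2; N <- 4000
  x <- seq(x0, X, length.out = N)
  hh <- x[2] - x[1]
  A <- Matrix::bandSparse(N - 2, N - 2, k = c(-1L, 0L, 1L), diagonals = list(
    rep(m$D_A / hh^2, N - 3),
    rep(-2 * m$D_A / hh^2 - m$k2, N - 2),
    rep(m$D_A / hh^2, N - 3)))
  fA <- function(xx) analytic_steady_state(m, "A", xx)
  rhs <- numeric(N - 2)
  rhs[1] <- -m$D_A / hh^2 * fA(x0)
  rhs[N - 2] <- -m$D_A / hh^2 * fA(X)
  sol <- as.numeric(Matrix::solve(A, rhs))
  expect_equal(sol, fA(x[2:(N - 1)]), tolerance = 1e-5)
})

test_that("steady-state propensities match the closed forms", {
  m <- fig1_model()
  pr <- steady_state_propensities(m)
  expect_equal(pr$r_reac, 3 * m$k1)
  expect_equal(pr$r_diff_bound, 2 * 64 * 50 + 2 * 4 * 100)
  expect_lte(pr$r_diff, pr$r_diff_bound)
  m0 <- mg_model(L = 2, K_A = 10, K_B = 10, D_A = 0, D_B = 0,
                 k1 = 100, k2 = 2, k3 = 1)
  expect_equal(steady_state_propensities(m0)$r_diff_bound, 0)
})

test_that("truncated generator reproduces the first-order stationary law", {
  m <- toy_model()  # K_A = K_B = 1, means 4 and 8
  sol <- solve_stationary_means(m)
  gen <- truncated_generator(m, cap_A = 4 + 10 * 2, cap_B = 8 + 10 * 3)
  expect_equal(gen$mean_n, sol$A_total, tolerance = 1e-6)
  expect_equal(gen$mean_m, sol$B_total, tolerance = 1e-6)
  # total-variation distance to the product-Poisson law
  pp <- mapply(function(n, mm) poisson_product_pmf(sol, n, mm),
               gen$states[, 1], gen$states[, 2])
  expect_lt(sum(abs(gen$pi - pp)) / 2, 1e-6)
})

test_that("truncated generator handles degenerate and multi-box cases", {
  m0 <- mg_model(L = 1, K_A = 1, K_B = 1, D_A = 0, D_B = 0,
                 k1 = 0, k2 = 0, k3 = 0)
  gen <- truncated_generator(m0, 3, 3)
  expect_equal(sum(gen$pi), 1)
  expect_equal(gen$pi[1], 1)  # point mass at the empty initial state

  # multi-compartment first-order toy agrees with the linear system
  m2 <- mg_model(L = 1, K_A = 2, K_B = 2, D_A = 0.3, D_B = 0.1,
                 k1 = 2, k2 = 1, k3 = 1)
  sol2 <- solve_stationary_means(m2)
  gen2 <- truncated_generator(m2, cap_A = 12, cap_B = 12)
  expect_equal(gen2$mean_n, sol2$Abar, tolerance = 1e-4)
  expect_equal(gen2$mean_m, sol2$Bbar, tolerance = 1e-4)
})

test_that("dimerization generator satisfies flux balance: mean B = k1/(2 k3)", {
  m <- mg_model(L = 1, K_A = 1, K_B = 1, D_A = 0.1, D_B = 0.1,
                k1 = 6, k3 = 2, network = "dimerization",
                lambda = 5, rho = 0.02)
  gen <- truncated_generator(m, cap_A = 30, cap_B = 15)
  expect_equal(gen$mean_m, m$k1 / (2 * m$k3), tolerance = 1e-3)
  # stationarity also fixes E[n(n-1)]: (k2/(2 h_A)) E[n(n-1)] = k1/2
  enn <- sum(gen$states[, 1] * (gen$states[, 1] - 1) * gen$pi)
  expect_equal(enn, m$k1 * m$h_A / m$k2, tolerance = 1e-3)
})

test_that("stationary solutions export as CSV with concentrations", {
  sol <- solve_stationary_means(fig1_model(10L, 20L))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  tab <- export_stationary(sol, csv_path = csv, json_path = js)
  expect_true(file.exists(csv) && file.exists(js))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 30L)
  expect_equal(sum(back$mean_count[back$species == "B"]), 100, tolerance = 1e-8)
  expect_equal(jsonlite::read_json(js)$r_reac, 300)
})
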