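# canonical parameter sets used across the suite
fig1_model <- function(K_A = 40L, K_B = K_A) {
  mg_model(L = 2, K_A = K_A, K_B = K_B, D_A = 0.16, D_B = 0.01,
           k1 = 100, k2 = 2, k3 = 1)
}

fig6_model <- function(K_A = 15L, K_B = 60L) {
  mg_model(L = 1, K_A = K_A, K_B = K_B, D_A = 0.16, D_B = 0.01,
           k1 = 50, k3 = 2, network = "dimerization", lambda = 5, rho = 0.02)
}

# small first-order toy (modest copy numbers keep truncated state spaces tiny)
toy_model <- function(K_A = 1L, K_B = 1L) {
  mg_model(L = 1, K_A = K_A, K_B = K_B, D_A = 0.1, D_B = 0.05,
           k1 = 8, k2 = 2, k3 = 1)
}
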