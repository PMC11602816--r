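#' Built-in model configurations
#'
#' Ready-made configurations for the two reference parameter sets and the
#' sweep grids used throughout the package:
#'
#' * `first_order_fig1`: first-order network, `k1 = 100, k2 = 2, k3 = 1,
#'   D_A = 0.16, D_B = 0.01` on `L = 2` with `K_A = K_B = 40` (so
#'   `h = 0.05`, jump rates `D_A/h^2 = 64`, `D_B/h^2 = 4`).
#' * `dimerization_fig6`: dimerization network, `k1 = 50, lambda = 5,
#'   rho = 0.02` (hence `k2 = 0.2`), `k3 = 2`, same diffusion constants, on
#'   `L = 1` with `K_A = 15`, `K_B = 60`.
#' * `sweep_fig3`: the first-order configuration with `K_B = 60` and the
#'   coarse-grid scan `K_A in {60,30,20,15,12,10,6,4,3}`.
#' * `sweep_fig5`: the first-order error/cost design grid,
#'   `K_B in {60, 120}` with every divisor ratio `gamma` up to 10.
#' * `sweep_fig7`: the dimerization error/cost scan, `K_B = 60`,
#'   `K_A in {60,30,20,15,12,10,6,5,4,3}`.
#'
#' @param name fixture name.
#' @param path optional file path; when given the configuration is written
#'   as JSON and the path returned invisibly.
#' @return The configuration as a nested list (sections `domain`,
#'   `diffusion`, `rates`, `network`, plus `sweep` for the sweep fixtures);
#'   pass it to [make_model()].
#' @export
fixture <- function(name = c("first_order_fig1", "dimerization_fig6",
                             "sweep_fig3", "sweep_fig5", "sweep_fig7"),
                    path = NULL) {
  name <- match.arg(name)
  first_order <- list(
    domain = list(L = 2, K_A = 40L, K_B = 40L),
    diffusion = list(D_A = 0.16, D_B = 0.01),
    rates = list(k1 = 100, k2 = 2, k3 = 1),
    network = "first_order")
  dimer <- list(
    domain = list(L = 1, K_A = 15L, K_B = 60L),
    diffusion = list(D_A = 0.16, D_B = 0.01),
    rates = list(k1 = 50, lambda = 5, rho = 0.02, k3 = 2),
    network = "dimerization")
  cfg <- switch(name,
    first_order_fig1 = first_order,
    dimerization_fig6 = dimer,
    sweep_fig3 = {
      x <- first_order
      x$domain$K_B <- 60L
      x$sweep <- list(K_B = 60L, K_A = c(60L, 30L, 20L, 15L, 12L, 10L, 6L, 4L, 3L))
      x
    },
    sweep_fig5 = {
      x <- first_order
      grid <- do.call(rbind, lapply(c(60L, 120L), function(KB) {
        g <- Filter(function(v) KB %% v == 0, 1:10)
        data.frame(K_B = KB, gamma = g)
      }))
      x$sweep <- list(design = grid)
      x
    },
    sweep_fig7 = {
      x <- dimer
      x$sweep <- list(K_B = 60L,
                      K_A = c(60L, 30L, 20L, 15L, 12L, 10L, 6L, 5L, 4L, 3L))
      x
    })
  if (!is.null(path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  cfg
}

#' Read a JSON model configuration
#' @param path file path.
#' @return Configuration list (as produced by [fixture()]).
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
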