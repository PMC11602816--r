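#' Construct a multi-grid reaction-diffusion model
#'
#' Defines a two-species reaction-diffusion system on the interval `[0, L]`
#' with species-specific lattices: signalling molecules A live on a coarse
#' grid of `K_A` compartments of size `h_A = L/K_A`, morphogen molecules B on
#' a fine grid of `K_B` compartments of size `h_B = L/K_B`. The resolution
#' ratio `gamma = K_B/K_A = h_A/h_B` need not be an integer; cross-grid
#' reactions distribute products over overlapping compartments (see
#' [overlap_weights()]).
#'
#' Two reaction networks are supported:
#' * `"first_order"`: localized production `0 -> A` (rate `k1` in the first
#'   A-compartment), conversion `A -> B` (rate `k2`, units 1/time) and
#'   degradation `B -> 0` (rate `k3`).
#' * `"dimerization"`: the conversion is replaced by `A + A -> B` with
#'   bimolecular rate constant `k2` (units length/time). When the Doi
#'   (lambda-rho) particle-model parameters are supplied instead of `k2`,
#'   the one-dimensional rate bridge `k2 = 2 * rho * lambda` is applied.
#'
#' @param L domain length (> 0).
#' @param K_A,K_B compartment counts for species A and B; `K_B >= K_A >= 1`.
#' @param D_A,D_B diffusion constants (length^2/time, >= 0).
#' @param k1 production rate (1/time).
#' @param k2 conversion rate (1/time) or dimerization rate constant
#'   (length/time). For the dimerization network it may be omitted when
#'   `lambda` and `rho` are given.
#' @param k3 degradation rate (1/time).
#' @param network `"first_order"` or `"dimerization"`.
#' @param lambda,rho Doi-model reaction rate (1/time) and radius (length);
#'   dimerization network only.
#' @return An object of class `mg_model`: a validated list with the supplied
#'   fields plus the derived `h_A`, `h_B` and `gamma`.
#' @examples
#' m <- mg_model(L = 2, K_A = 40, K_B = 40, D_A = 0.16, D_B = 0.01,
#'               k1 = 100, k2 = 2, k3 = 1)
#' m$gamma  # 1
#' d <- mg_model(L = 1, K_A = 15, K_B = 60, D_A = 0.16, D_B = 0.01,
#'               k1 = 50, k3 = 2, network = "dimerization",
#'               lambda = 5, rho = 0.02)
#' d$k2  # 0.2
#' @export
mg_model <- function(L, K_A, K_B = K_A, D_A, D_B, k1, k2 = NULL, k3,
                     network = c("first_order", "dimerization"),
                     lambda = NULL, rho = NULL) {
  network <- match.arg(network)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  L <- num1(L, "L")
  if (L <= 0) stop("domain length 'L' must be positive", call. = FALSE)
  K_A <- num1(K_A, "K_A"); K_B <- num1(K_B, "K_B")
  if (K_A < 1 || K_A != round(K_A)) stop("'K_A' must be an integer >= 1", call. = FALSE)
  if (K_B < 1 || K_B != round(K_B)) stop("'K_B' must be an integer >= 1", call. = FALSE)
  if (K_B < K_A)
    stop("'K_B' must be >= 'K_A' (the B-grid is the finer one)", call. = FALSE)
  for (nm in c("D_A", "D_B", "k1", "k3")) {
    v <- num1(get(nm), nm)
    if (v < 0) stop(sprintf("'%s' must be non-negative", nm), call. = FALSE)
    assign(nm, v)
  }
  if (network == "dimerization") {
    if (is.null(k2)) {
      if (is.null(lambda) || is.null(rho))
        stop("dimerization network needs either 'k2' or both 'lambda' and 'rho'",
             call. = FALSE)
      lambda <- num1(lambda, "lambda"); rho <- num1(rho, "rho")
      if (lambda < 0 || rho < 0) stop("'lambda' and 'rho' must be non-negative", call. = FALSE)
      k2 <- 2 * rho * lambda  # d = 1 Doi bridge: k2 = lambda * |B_rho|
    } else {
      k2 <- num1(k2, "k2")
      if (!is.null(lambda)) lambda <- num1(lambda, "lambda")
      if (!is.null(rho)) rho <- num1(rho, "rho")
    }
  } else {
    if (is.null(k2)) stop("first-order network requires 'k2'", call. = FALSE)
    k2 <- num1(k2, "k2")
  }
  if (k2 < 0) stop("'k2' must be non-negative", call. = FALSE)

  structure(list(
    L = L, K_A = as.integer(K_A), K_B = as.integer(K_B),
    h_A = L / K_A, h_B = L / K_B, gamma = K_B / K_A,
    D_A = D_A, D_B = D_B, k1 = k1, k2 = k2, k3 = k3,
    network = network, lambda = lambda, rho = rho
  ), class = "mg_model")
}

#' Build a model from a configuration mapping
#'
#' Accepts the nested configuration layout used by the command-line tools
#' (sections `domain`, `diffusion`, `rates`, top-level `network`) or a flat
#' list of `mg_model()` arguments.
#'
#' @param config a named list, e.g. as read from a JSON config file.
#' @return An `mg_model` object.
#' @seealso [fixture()] for ready-made configurations.
#' @export
make_model <- function(config) {
  if (!is.list(config)) stop("'config' must be a list", call. = FALSE)
  flat <- config
  if (any(c("domain", "rates", "diffusion") %in% names(config))) {
    flat <- c(config$domain, config$diffusion, config$rates,
              config[setdiff(names(config), c("domain", "diffusion", "rates"))])
  }
  args <- flat[intersect(names(flat),
                         c("L", "K_A", "K_B", "D_A", "D_B",
                           "k1", "k2", "k3", "network", "lambda", "rho"))]
  missing <- setdiff(c("L", "K_A", "D_A", "D_B", "k1", "k3"), names(args))
  if (length(missing))
    stop("config is missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(mg_model, args)
}

#' @export
print.mg_model <- function(x, ...) {
  cat(sprintf("<mg_model: %s network on [0, %g]>\n", x$network, x$L))
  cat(sprintf("  grids : K_A = %d (h_A = %g), K_B = %d (h_B = %g), gamma = %g\n",
              x$K_A, x$h_A, x$K_B, x$h_B, x$gamma))
  cat(sprintf("  rates : k1 = %g, k2 = %g, k3 = %g\n", x$k1, x$k2, x$k3))
  cat(sprintf("  diff. : D_A = %g, D_B = %g\n", x$D_A, x$D_B))
  if (!is.null(x$lambda))
    cat(sprintf("  Doi   : lambda = %g, rho = %g\n", x$lambda, x$rho))
  invisible(x)
}

#' Compartment intervals of one species' grid
#'
#' Compartments are half-open `[(i-1)h, i h)`, 1-based, and tile `[0, L)`.
#'
#' @param model an `mg_model`.
#' @param species `"A"` or `"B"`.
#' @return A data frame with columns `index`, `lo`, `hi`.
#' @export
compartment_intervals <- function(model, species = c("A", "B")) {
  stopifnot(inherits(model, "mg_model"))
  species <- match.arg(species)
  K <- if (species == "A") model$K_A else model$K_B
  h <- if (species == "A") model$h_A else model$h_B
  data.frame(index = seq_len(K), lo = (seq_len(K) - 1) * h, hi = seq_len(K) * h)
}

#' Overlap-weight matrix between the two grids
#'
#' Entry `W[i, j]` is the fraction of the j-th (coarse) A-compartment covered
#' by the i-th (fine) B-compartment,
#' `|C_i^(B) intersect C_j^(A)| / |C_j^(A)|`. A cross-grid reaction firing in
#' A-compartment j places its product in B-compartment i with probability
#' `W[i, j]`; the total rate out of an A-compartment is therefore shared
#' among overlapping targets. Every column sums to 1. For integer
#' `gamma = K_B/K_A` the matrix has entries `1/gamma` in rows
#' `(j-1)*gamma + 1, ..., j*gamma` of column j; non-integer ratios produce
#' fractional boundary overlaps.
#'
#' @param model an `mg_model`.
#' @return A dense `K_B x K_A` matrix with unit column sums.
#' @examples
#' m <- mg_model(L = 1, K_A = 2, K_B = 3, D_A = 1, D_B = 1,
#'               k1 = 1, k2 = 1, k3 = 1)
#' overlap_weights(m)  # columns (2/3, 1/3, 0) and (0, 1/3, 2/3)
#' @export
overlap_weights <- function(model) {
  stopifnot(inherits(model, "mg_model"))
  hA <- model$h_A; hB <- model$h_B
  KA <- model$K_A; KB <- model$K_B
  tol <- 1e-12 * hA
  W <- matrix(0, nrow = KB, ncol = KA)
  for (j in seq_len(KA)) {
    lo <- (j - 1) * hA; hi <- j * hA
    i0 <- max(1L, floor(lo / hB + 1e-12) + 1L)
    i1 <- min(KB, ceiling(hi / hB - 1e-12))
    for (i in i0:i1) {
      ov <- min(hi, i * hB) - max(lo, (i - 1) * hB)
      if (ov > tol) W[i, j] <- ov / hA
    }
    W[, j] <- W[, j] / sum(W[, j])  # exact unit column sum
  }
  W
}
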