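#' Gamma distribution from a mean and a std-percentage
#'
#' Moment-matched gamma distribution for an uncertain material parameter:
#' given the mean and the standard deviation expressed as a percentage of
#' the mean, the shape is `(mean/sd)^2` and the scale `sd^2/mean`, so that
#' `shape * scale = mean` and `shape * scale^2 = sd^2`.
#'
#' @param mean Parameter mean (its physical units), > 0.
#' @param std_pct Standard deviation as percent of the mean, > 0.
#' @return An object of class `"gamma_spec"`: `mean`, `std_pct`, `sd`,
#'   `shape`, `scale`.
#' @export
#' @examples
#' gamma_from_mean_stdpct(200, 49.61)  # shape ~ 4.063, scale ~ 49.22 kPa
gamma_from_mean_stdpct <- function(mean, std_pct) {
  if (mean <= 0) stop("mean must be > 0")
  if (std_pct <= 0) stop("std_pct must be > 0")
  sd <- mean * std_pct / 100
  structure(list(mean = mean, std_pct = std_pct, sd = sd,
                 shape = (mean / sd)^2, scale = sd^2 / mean),
            class = "gamma_spec")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf("Gamma spec: mean %g, sd %g (%g%%), shape %.6g, scale %.6g\n",
              x$mean, x$sd, x$std_pct, x$shape, x$scale))
  invisible(x)
}

#' Standard deviation as a percentage of the mean
#'
#' Reporting convention used by the arterial-layer variability table:
#' `100 * std / mean`, rounded to two decimals.
#'
#' @param mean Mean value, > 0.
#' @param std Standard deviation, >= 0.
#' @return Percentage, rounded to 2 decimals.
#' @export
#' @examples
#' std_pct_from_layer_stats(1.27, 0.63)  # 49.61
std_pct_from_layer_stats <- function(mean, std) {
  if (any(mean <= 0)) stop("mean must be > 0")
  round(100 * std / mean, 2)
}

#' Default gamma specifications for the five uncertain HGO parameters
#'
#' Combines the published baseline means (c, k1, k2, gamma, kappa) with the
#' media-layer std-percentages (per-parameter columns of
#' [media_layer_stats()]) into the five [gamma_from_mean_stdpct()] specs
#' driving the sensitivity analysis.
#'
#' @return Named list of `gamma_spec` objects
#'   (`c`, `k1`, `k2`, `gamma`, `kappa`).
#' @export
default_gamma_specs <- function() {
  base <- baseline_materials()$rvot
  tab <- media_layer_stats()
  pct <- stats::setNames(tab$percentage, tab$parameter)
  list(
    c = gamma_from_mean_stdpct(base$c, pct[["c"]]),
    k1 = gamma_from_mean_stdpct(base$k1, pct[["k1"]]),
    k2 = gamma_from_mean_stdpct(base$k2, pct[["k2"]]),
    gamma = gamma_from_mean_stdpct(base$gamma, pct[["gamma"]]),
    kappa = gamma_from_mean_stdpct(base$kappa, pct[["kappa"]])
  )
}

# ---- orthonormal polynomials for the gamma measure -----------------------
#
# For X ~ Gamma(shape k, scale theta), t = X/theta has weight
# t^(k-1) e^-t / Gamma(k): the (monic) generalized Laguerre family with
# alpha = k - 1 obeys p_{n+1} = (t - a_n) p_n - b_n p_{n-1} with
# a_n = 2n + alpha + 1, b_n = n (n + alpha); squared norms h_n = h_{n-1} b_n
# under the normalized weight (h_0 = 1).

laguerre_recurrence <- function(order, alpha) {
  n <- 0:(order - 1)
  list(a = 2 * n + alpha + 1, b = n * (n + alpha))  # b[1] unused (n = 0)
}

# evaluate orthonormal polynomials phi_0..phi_order at x (physical units)
eval_orthonormal <- function(x, order, shape, scale) {
  t <- x / scale
  alpha <- shape - 1
  rec <- laguerre_recurrence(order + 1, alpha)
  P <- matrix(0, length(t), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- t - rec$a[1]
  if (order >= 2)
    for (n in 1:(order - 1))
      P[, n + 2] <- (t - rec$a[n + 1]) * P[, n + 1] - rec$b[n + 1] * P[, n]
  h <- cumprod(c(1, rec$b[-1]))[seq_len(order + 1)]
  sweep(P, 2, sqrt(h), "/")
}

#' Gauss quadrature for the gamma measure
#'
#' Golub-Welsch nodes and weights for the normalized Gamma(shape, scale)
#' weight (generalized Gauss-Laguerre), exact for polynomials up to degree
#' `2n - 1`. Used for the orthonormality checks and the quadrature
#' projection oracle.
#'
#' @param n Number of nodes.
#' @param shape,scale Gamma parameters.
#' @return List with `nodes` (physical units) and `weights` (sum 1).
#' @export
gauss_gamma <- function(n, shape, scale = 1) {
  alpha <- shape - 1
  rec <- laguerre_recurrence(n, alpha)
  J <- diag(rec$a)
  if (n > 1) {
    off <- sqrt(rec$b[-1])
    J[cbind(1:(n - 1), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1))] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values * scale, weights = e$vectors[1, ]^2)
}

# total-degree multi-index set |alpha| <= order in d dimensions
multi_index_set <- function(d, order) {
  grid <- as.matrix(expand.grid(rep(list(0:order), d)))[, d:1, drop = FALSE]
  grid <- grid[rowSums(grid) <= order, , drop = FALSE]
  grid[order(rowSums(grid), apply(grid, 1, paste, collapse = ",")), ,
       drop = FALSE]
}

#' Sampling design for the PCE study
#'
#' Draws `M = C(d + order, order) + oversample` independent samples from
#' the product gamma measure of the parameter specs (`M = 136` for the
#' order-4, five-parameter study with the default oversampling of 10).
#' Draws of `kappa` exceeding the admissible dispersion limit 1/3 are
#' rejected and redrawn (set `kappa_rule = "clip"` to clip instead).
#'
#' @param specs Named list of [gamma_from_mean_stdpct()] specs (the name
#'   `kappa`, if present, triggers the constraint handling).
#' @param order Total polynomial degree (default 4).
#' @param oversample Extra rows beyond the basis size (default 10).
#' @param seed RNG seed.
#' @param kappa_rule `"reject"` (default) or `"clip"`.
#' @return `M x d` matrix of parameter draws in physical units, columns
#'   named after the specs.
#' @export
pce_design <- function(specs, order = 4, oversample = 10, seed = 1,
                       kappa_rule = c("reject", "clip")) {
  stopifnot(order >= 1)
  if (oversample < 0) stop("oversample must be >= 0")
  kappa_rule <- match.arg(kappa_rule)
  d <- length(specs)
  M <- choose(d + order, order) + oversample
  sample_gamma_product(specs, M, seed, kappa_rule)
}

# seeded draws from the product gamma measure with the kappa constraint
sample_gamma_product <- function(specs, n, seed,
                                 kappa_rule = c("reject", "clip")) {
  kappa_rule <- match.arg(kappa_rule)
  d <- length(specs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- matrix(0, n, d, dimnames = list(NULL, names(specs)))
  for (j in seq_len(d)) {
    s <- specs[[j]]
    x <- stats::rgamma(n, shape = s$shape, scale = s$scale)
    if (identical(names(specs)[j], "kappa")) {
      if (kappa_rule == "reject") {
        bad <- which(x > 1 / 3)
        while (length(bad)) {
          x[bad] <- stats::rgamma(length(bad), shape = s$shape,
                                  scale = s$scale)
          bad <- bad[x[bad] > 1 / 3]
        }
      } else x <- pmin(x, 1 / 3)
    }
    X[, j] <- x
  }
  X
}

#' Fit a polynomial chaos expansion emulator
#'
#' Least-squares fit of a total-degree polynomial chaos expansion on the
#' basis of products of generalized-Laguerre polynomials orthonormal with
#' respect to each parameter's gamma measure. Rows with missing outputs
#' (failed model evaluations) are dropped before the fit; the expansion
#' reproduces any polynomial of total degree `<= order` exactly.
#'
#' @param samples `M x d` design matrix (physical units), as from
#'   [pce_design()].
#' @param outputs Length-`M` response vector; `NA` marks failed runs.
#' @param specs Named list of [gamma_from_mean_stdpct()] specs, one per
#'   column.
#' @param order Total degree (default 4).
#' @return An object of class `"pce"`: `coefficients` (named by
#'   multi-index), `indices` (multi-index matrix), `specs`, `order`,
#'   `n_used`, `n_failed`, `condition` (design-matrix condition number),
#'   `residual_sd`.
#' @seealso [sobol_indices()], [query_emulator()], [predict.pce()]
#' @export
pce <- function(samples, outputs, specs, order = 4) {
  samples <- as.matrix(samples)
  d <- ncol(samples)
  stopifnot(length(specs) == d, length(outputs) == nrow(samples))
  keep <- which(!is.na(outputs))
  idx <- multi_index_set(d, order)
  P <- nrow(idx)
  if (length(keep) < P)
    stop(sprintf("under-determined PCE fit: %d usable runs < %d basis terms",
                 length(keep), P))
  Phi <- pce_basis_matrix(samples[keep, , drop = FALSE], idx, specs, order)
  qr_fit <- qr(Phi)
  coef <- qr.coef(qr_fit, outputs[keep])
  fitted <- drop(Phi %*% coef)
  names(coef) <- apply(idx, 1, paste, collapse = ",")
  structure(list(coefficients = coef, indices = idx, specs = specs,
                 order = order, n_used = length(keep),
                 n_failed = length(outputs) - length(keep),
                 condition = kappa(qr_fit$qr, exact = FALSE),
                 residual_sd = stats::sd(outputs[keep] - fitted)),
            class = "pce")
}

# design matrix of orthonormal basis products
pce_basis_matrix <- function(samples, idx, specs, order) {
  d <- ncol(samples)
  uni <- lapply(seq_len(d), function(j)
    eval_orthonormal(samples[, j], order, specs[[j]]$shape,
                     specs[[j]]$scale))
  Phi <- matrix(1, nrow(samples), nrow(idx))
  for (k in seq_len(nrow(idx)))
    for (j in seq_len(d))
      if (idx[k, j] > 0) Phi[, k] <- Phi[, k] * uni[[j]][, idx[k, j] + 1]
  Phi
}

#' @export
print.pce <- function(x, ...) {
  cat(sprintf("PCE emulator: order %d, %d parameters, %d terms\n",
              x$order, ncol(x$indices), length(x$coefficients)))
  cat(sprintf("  fitted on %d runs (%d failed/dropped), design condition %.3g\n",
              x$n_used, x$n_failed, x$condition))
  cat(sprintf("  mean %.6g, sd %.6g\n", x$coefficients[1],
              sqrt(sum(x$coefficients[-1]^2))))
  invisible(x)
}

#' @export
coef.pce <- function(object, ...) object$coefficients

#' @export
predict.pce <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Phi <- pce_basis_matrix(newdata, object$indices, object$specs,
                          object$order)
  drop(Phi %*% object$coefficients)
}

#' @export
summary.pce <- function(object, ...) {
  out <- list(model = object, sobol = sobol_indices(object))
  class(out) <- "summary.pce"
  out
}

#' @export
print.summary.pce <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$sobol)
  invisible(x)
}

#' @export
plot.pce <- function(x, ...) {
  s <- sobol_indices(x)
  graphics::barplot(rbind(s$table$S_total, s$table$S_first), beside = TRUE,
                    names.arg = s$table$parameter,
                    legend.text = c("total-order", "first-order"),
                    ylab = "Sobol index", ...)
  invisible(x)
}

#' Sobol sensitivity indices of a PCE emulator
#'
#' Variance-based first- and total-order indices read off the orthonormal
#' PCE coefficients: the model variance is the sum of squared non-constant
#' coefficients; the first-order index of parameter `i` sums the terms
#' involving only `i`, the total-order index all terms involving `i`.
#'
#' @param model A fitted [pce()] emulator.
#' @return An object of class `"sobol_result"`: `table` (data frame with
#'   `parameter`, `S_first`, `S_total`), `variance`, `mean`.
#' @export
sobol_indices <- function(model) {
  stopifnot(inherits(model, "pce"))
  a <- model$coefficients
  idx <- model$indices
  nz <- rowSums(idx) > 0
  V <- sum(a[nz]^2)
  # a numerically constant response has no variance to decompose
  if (V <= 1e-24 * (a[1]^2 + V)) V <- 0
  d <- ncol(idx)
  S1 <- ST <- numeric(d)
  if (V > 0) {
    for (j in seq_len(d)) {
      only_j <- nz & idx[, j] > 0 & rowSums(idx[, -j, drop = FALSE]) == 0
      any_j <- idx[, j] > 0
      S1[j] <- sum(a[only_j]^2) / V
      ST[j] <- sum(a[any_j]^2) / V
    }
  }
  nms <- names(model$specs)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  structure(list(table = data.frame(parameter = nms, S_first = S1,
                                    S_total = ST),
                 variance = V, mean = unname(a[1])),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol indices (model variance %.6g)\n", x$variance))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Query the PCE emulator with random parameter combinations
#'
#' Draws `n` seeded samples from the product gamma measure (with the same
#' kappa constraint rule as the design) and evaluates the emulator,
#' returning the distribution summary used by the raincloud plots:
#' minimum, maximum, median and quartiles, plus the raw sample.
#'
#' @param model A fitted [pce()] emulator.
#' @param n Number of queries (default 1000).
#' @param seed RNG seed.
#' @param kappa_rule Passed to [pce_design()].
#' @return An object of class `"pce_sample"`: `summary` (named vector
#'   `min`, `q25`, `median`, `q75`, `max`), `values`, `inputs`.
#' @export
query_emulator <- function(model, n = 1000, seed = 1,
                           kappa_rule = "reject") {
  stopifnot(inherits(model, "pce"))
  X <- sample_gamma_product(model$specs, n, seed, kappa_rule)
  y <- predict(model, X)
  s <- stats::quantile(y, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  structure(list(summary = c(min = s[1], q25 = s[2], median = s[3],
                             q75 = s[4], max = s[5]),
                 values = y, inputs = X),
            class = "pce_sample")
}

#' @export
print.pce_sample <- function(x, ...) {
  cat(sprintf("Emulator sample (n = %d)\n", length(x$values)))
  print(round(x$summary, 6))
  invisible(x)
}
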