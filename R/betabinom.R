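#' Beta-binomial probability mass function
#'
#' Probability of observing `k` positive nodes among `n` examined when the
#' per-node positivity probability is itself Beta(alpha, beta) distributed:
#' `C(n,k) * B(alpha+k, beta+n-k) / B(alpha, beta)`.  Evaluated in log space
#' via log-gamma differences for numerical stability.
#'
#' @param k integer vector, number of positive nodes (0 <= k <= n).
#' @param n integer vector, number of examined nodes (n >= 1).
#' @param alpha,beta positive shape parameters of the mixing Beta.
#' @param log logical; return log probabilities?
#' @return numeric vector of (log-)probabilities.
#' @examples
#' dbetabinom(0, 1, 2, 3)        # beta/(alpha+beta) = 0.6
#' sum(dbetabinom(0:2, 2, 1, 1)) # uniform case, sums to 1
#' @export
dbetabinom <- function(k, n, alpha, beta, log = FALSE) {
  stopifnot(alpha > 0, beta > 0, n >= 1)
  if (any(k < 0 | k > n))
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  lp <- lchoose(n, k) + lbeta(alpha + k, beta + n - k) - lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' Probability of missing nodal disease given examined-node count
#'
#' The false-negative probability for a truly node-positive patient whose
#' `n` examined nodes are all negative: `B(alpha, beta+n) / B(alpha, beta)`,
#' the zero class of the beta-binomial.  Equals 1 at `n = 0`, is strictly
#' decreasing in `n`, and decays like `n^(-alpha)`.
#'
#' Computed via log-gamma differences; the equivalent running product
#' `prod((beta+k)/(alpha+beta+k), k = 0..n-1)` is used as an independent
#' cross-check in the test suite.
#'
#' @param alpha,beta positive shape parameters (stage-specific).
#' @param n integer vector of examined-node counts (n >= 0).
#' @return numeric vector of probabilities in (0, 1].
#' @examples
#' fn_probability(0.0694, 1.888, 0:5)
#' @export
fn_probability <- function(alpha, beta, n) {
  stopifnot(alpha > 0, beta > 0, all(n >= 0))
  exp(lbeta(alpha, beta + n) - lbeta(alpha, beta))
}

#' Zero-truncated beta-binomial log-likelihood
#'
#' Log-likelihood of stage-specific (alpha, beta) given node-positive
#' observations, conditioning on at least one positive node:
#' `sum log[ pmf(k_i; n_i) / (1 - pmf(0; n_i)) ]`.  The fitting sample is
#' defined by `k >= 1`, so the truncated form is the default likelihood;
#' set `truncated = FALSE` for the untruncated sensitivity variant.
#'
#' @param alpha,beta positive shape parameters.
#' @param n integer vector of examined-node counts.
#' @param k integer vector of positive-node counts (k >= 1 when truncated).
#' @param weights optional non-negative case weights (default all 1).
#' @param truncated condition on k >= 1 (default TRUE).
#' @return scalar log-likelihood.
#' @export
truncated_loglik <- function(alpha, beta, n, k, weights = NULL,
                             truncated = TRUE) {
  stopifnot(length(n) == length(k))
  if (is.null(weights)) weights <- rep.int(1, length(n))
  if (truncated && any(k < 1))
    stop("zero-truncated likelihood requires k >= 1 for every observation",
         call. = FALSE)
  lp <- dbetabinom(k, n, alpha, beta, log = TRUE)
  if (truncated) {
    lp0 <- dbetabinom(0L, n, alpha, beta, log = TRUE)
    lp <- lp - log1p(-exp(lp0))
  }
  sum(weights * lp)
}

# method-of-moments starting values from k/n fractions; clamped to a sane box
.bb_moment_start <- function(n, k) {
  x <- k / n
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) v <- m * (1 - m) / 4 + 1e-4
  s <- m * (1 - m) / v - 1
  a <- m * s
  b <- (1 - m) * s
  c(alpha = min(max(a, 1e-3), 1e3), beta = min(max(b, 1e-3), 1e3))
}

#' Fit stage-specific beta-binomial parameters by maximum likelihood
#'
#' Maximizes the zero-truncated beta-binomial likelihood over
#' `(log alpha, log beta)` with [stats::optim()] (Nelder-Mead), starting from
#' method-of-moments values plus jittered restarts under a fixed internal
#' seed.  Observations are aggregated to unique `(n, k)` pairs with weights
#' before optimization.
#'
#' @param n,k integer vectors of examined and positive node counts for
#'   node-positive patients (`k >= 1` when `truncated`).
#' @param t_stage optional stage label stored in the result.
#' @param truncated use the zero-truncated likelihood (default TRUE).
#' @param n_starts number of optimizer starts (1 = method-of-moments only).
#' @param reltol convergence tolerance passed to `optim`.
#' @return object of class `bb_params`: list with `t_stage`, `alpha`, `beta`,
#'   `loglik`, `convergence` (TRUE/FALSE), `degenerate` (boundary-drift
#'   flag), `n_used`, and NULL CI slots to be filled by [bootstrap_params()].
#' @examples
#' set.seed(1)
#' nn <- sample(5:40, 300, replace = TRUE)
#' p <- rbeta(300, 0.8, 0.9)
#' kk <- rbinom(300, nn, p)
#' keep <- kk >= 1
#' fit_beta_binomial(nn[keep], kk[keep])
#' @export
fit_beta_binomial <- function(n, k, t_stage = NA_character_, truncated = TRUE,
                              n_starts = 5, reltol = 1e-10) {
  stopifnot(length(n) == length(k), length(n) >= 2)
  if (truncated && any(k < 1))
    stop("fitting sample must be node-positive (k >= 1)", call. = FALSE)
  if (all(k == n)) {
    # likelihood pushes alpha to +Inf; report the boundary honestly
    return(structure(list(t_stage = t_stage, alpha = Inf, beta = NA_real_,
                          alpha_ci = NULL, beta_ci = NULL,
                          loglik = 0, convergence = FALSE, degenerate = TRUE,
                          n_used = length(n)), class = "bb_params"))
  }
  agg <- stats::aggregate(list(w = rep.int(1L, length(n))),
                          by = list(n = n, k = k), FUN = sum)
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    ll <- truncated_loglik(a, b, agg$n, agg$k, weights = agg$w,
                           truncated = truncated)
    if (!is.finite(ll)) 1e10 else -ll
  }
  mom <- .bb_moment_start(n, k)
  starts <- matrix(log(mom), nrow = 1)
  if (n_starts > 1) {
    jit <- withr_seed_matrix(n_starts - 1L)
    starts <- rbind(starts, sweep(jit, 2, log(mom), `+`))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  alpha <- exp(best$par[1]); beta <- exp(best$par[2])
  degenerate <- alpha > 1e6 || alpha < 1e-8 || beta > 1e6 || beta < 1e-8
  structure(list(t_stage = t_stage, alpha = alpha, beta = beta,
                 alpha_ci = NULL, beta_ci = NULL,
                 loglik = -best$value,
                 convergence = best$convergence == 0,
                 degenerate = degenerate,
                 n_used = length(n)),
            class = "bb_params")
}

# deterministic jitter offsets for the extra optimizer starts; isolated from
# the caller's RNG state
withr_seed_matrix <- function(m) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20220922L)
  matrix(stats::runif(2L * m, -1.5, 1.5), ncol = 2L)
}

#' @export
print.bb_params <- function(x, ...) {
  cat(sprintf("Beta-binomial fit%s: alpha = %.7g, beta = %.7g (n = %d, logLik = %.4f)\n",
              if (is.na(x$t_stage)) "" else paste0(" [", x$t_stage, "]"),
              x$alpha, x$beta, x$n_used, x$loglik))
  if (!is.null(x$alpha_ci))
    cat(sprintf("  95%% CI alpha: (%.7g, %.7g)  beta: (%.7g, %.7g)\n",
                x$alpha_ci[1], x$alpha_ci[2], x$beta_ci[1], x$beta_ci[2]))
  if (x$degenerate) cat("  WARNING: degenerate fit (boundary drift)\n")
  invisible(x)
}

#' Export / import fitted parameters as JSON
#'
#' The JSON layout (`t_stage`, `alpha`, `beta`, optional CIs, `loglik`,
#' `n_used`) matches published parameter tables so reference values can be
#' loaded directly as fixtures.
#'
#' @param params a `bb_params` object or list of them.
#' @param path output / input file path.
#' @return `read_bb_params` returns a named list of `bb_params` keyed by stage.
#' @export
write_bb_params <- function(params, path) {
  if (inherits(params, "bb_params")) params <- list(params)
  out <- lapply(params, function(p)
    list(t_stage = p$t_stage, alpha = p$alpha, beta = p$beta,
         alpha_ci = p$alpha_ci, beta_ci = p$beta_ci,
         loglik = p$loglik, n_used = p$n_used))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bb_params
#' @export
read_bb_params <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(p) {
    structure(list(t_stage = p$t_stage %||% NA_character_,
                   alpha = p$alpha, beta = p$beta,
                   alpha_ci = if (!is.null(p$alpha_ci)) unlist(p$alpha_ci),
                   beta_ci = if (!is.null(p$beta_ci)) unlist(p$beta_ci),
                   loglik = p$loglik %||% NA_real_,
                   convergence = NA, degenerate = FALSE,
                   n_used = p$n_used %||% NA_integer_),
              class = "bb_params")
  })
  names(out) <- vapply(out, function(p) as.character(p$t_stage), "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
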