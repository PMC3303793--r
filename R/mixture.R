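# Gaussian mixtures over per-nucleus photoconverted intensity: EM fitting,
# BIC model selection, an optional geometric-halving constraint
# (mu_k = mu0 * 2^-d_k, the label-dilution model), population assignment
# and intensity -> division-count mapping.

new_mixture <- function(K, weights, means, sds, loglik, n, constrained =
                          FALSE, mu0 = NULL, division_indices = NULL,
                        loglik_trace = numeric(0)) {
  ord <- order(means, decreasing = TRUE)
  n_par <- if (constrained) 2 * K else 3 * K - 1
  # constrained: mu0 + K sds + (K-1) weights = 2K free parameters
  structure(list(K = as.integer(K), weights = weights[ord],
                 means = means[ord], sds = sds[ord], log_likelihood = loglik,
                 bic = -2 * loglik + n_par * log(n),
                 aic = -2 * loglik + 2 * n_par,
                 n = as.integer(n), constrained = constrained, mu0 = mu0,
                 division_indices = if (is.null(division_indices)) NULL
                 else division_indices[ord],
                 loglik_trace = loglik_trace),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K=%d%s logL=%.3f BIC=%.3f n=%d\n", x$K,
              if (x$constrained) " (halving-constrained)" else "",
              x$log_likelihood, x$bic, x$n))
  tab <- data.frame(weight = x$weights, mean = x$means, sd = x$sds)
  if (!is.null(x$division_indices)) tab$divisions <- x$division_indices
  print(tab, row.names = FALSE)
  invisible(x)
}

# per-observation log joint densities log(w_k) + log N(x | mu_k, sd_k)
mixture_logdens <- function(x, w, mu, sd) {
  lg <- vapply(seq_along(w), function(k)
    log(w[k]) + stats::dnorm(x, mu[k], sd[k], log = TRUE),
    numeric(length(x)))
  matrix(lg, nrow = length(x))
}

mixture_loglik <- function(x, w, mu, sd)
  sum(logsumexp_rows(mixture_logdens(x, w, mu, sd)))

# responsibilities (n x K)
mixture_posteriors <- function(x, w, mu, sd) {
  lg <- mixture_logdens(x, w, mu, sd)
  p <- exp(lg - logsumexp_rows(lg))
  p / rowSums(p)
}

check_mixture_sample <- function(x, K, sigma_floor) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    pl_stop("division_mixture", "sample contains non-finite values")
  if (length(x) < 3 * K)
    pl_stop("division_mixture", "need at least 3K observations (n = ",
            length(x), ", K = ", K, ")")
  if (K > 1L && stats::sd(x) == 0)
    pl_stop("division_mixture", "degenerate sample: all values equal; ",
            "variance would collapse to sigma_floor = ", sigma_floor)
  x
}

#' Fit a K-component Gaussian mixture by EM
#'
#' Maximum-likelihood EM on linear intensities with seeded random restarts.
#' Each restart initialises the means at jittered sample quantiles, the
#' variances at the sample variance, and equal weights; the best
#' log-likelihood over restarts is kept.  Convergence when the
#' log-likelihood gain drops below `1e-8` or after 500 iterations.
#' Components are reported sorted by descending mean;
#' `bic = -2 logL + (3K - 1) log n`.
#'
#' @param x numeric intensity sample, `length(x) >= 3K`.
#' @param K number of components (>= 1).
#' @param restarts number of random initialisations.
#' @param seed integer seed for the restart draws.
#' @param sigma_floor lower bound on component standard deviations; default
#'   `1e-6 * sd(x)`.
#' @return a `mixture_model`: weights, means, sds (sorted by descending
#'   mean), `log_likelihood`, `bic`, `aic`, and the per-iteration
#'   `loglik_trace` of the winning restart.
#' @export
fit_mixture <- function(x, K, restarts = 20L, seed = 0L,
                        sigma_floor = NULL) {
  sigma_floor <- sigma_floor %||% (1e-6 * stats::sd(x))
  x <- check_mixture_sample(x, K, sigma_floor)
  if (K == 1L) {
    # closed-form MLE; restarts irrelevant
    mu <- mean(x)
    sd1 <- max(sqrt(mean((x - mu)^2)), sigma_floor, .Machine$double.xmin)
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(new_mixture(1L, 1, mu, sd1, ll, length(x),
                       loglik_trace = ll))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
      mu <- qs + stats::rnorm(K, 0, stats::sd(x) / (4 * K))
      fit <- em_gaussian(x, rep(1 / K, K), mu, rep(stats::sd(x), K),
                         sigma_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  new_mixture(K, best$w, best$mu, best$sd, best$loglik, length(x),
              loglik_trace = best$trace)
}

em_gaussian <- function(x, w, mu, sd, sigma_floor, max_iter = 500L,
                        tol = 1e-8) {
  n <- length(x)
  trace <- numeric(max_iter)
  ll_old <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    lg <- mixture_logdens(x, w, mu, sd)
    ls <- logsumexp_rows(lg)
    ll <- sum(ls)                      # likelihood at current parameters
    g <- exp(lg - ls)
    g <- g / rowSums(g)
    nk <- pmax(colSums(g), 1e-12)
    w <- nk / n
    mu <- colSums(g * x) / nk
    sd <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / nk)
    sd <- pmax(sd, sigma_floor, .Machine$double.xmin)
    trace[it] <- ll
    if (it > 1L && ll - ll_old < tol) break
    ll_old <- ll
  }
  # final evaluation so the reported logL matches the reported parameters
  ll <- mixture_loglik(x, w, mu, sd)
  trace <- c(trace[seq_len(it)], ll)
  list(w = w, mu = mu, sd = sd, loglik = ll, trace = trace)
}

#' Select the number of mixture components by BIC
#'
#' Fits every K in `k_min..k_max` and returns the BIC-minimising model
#' together with the full score table.  Ties break toward smaller K;
#' degenerate K are skipped with a warning provided at least one fit
#' succeeds.
#'
#' @inheritParams fit_mixture
#' @param k_min,k_max range of component counts.
#' @return `list(model, table)`; `table` has columns `K`, `log_likelihood`,
#'   `bic`, `aic`, `error`.
#' @export
select_K <- function(x, k_min = 1L, k_max = 6L, restarts = 20L, seed = 0L,
                     sigma_floor = NULL) {
  if (k_min > k_max) pl_stop("division_mixture", "k_min must be <= k_max")
  if (k_min < 1L) pl_stop("division_mixture", "k_min must be >= 1")
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  errs <- rep(NA_character_, length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- tryCatch(fit_mixture(x, ks[i], restarts, seed + ks[i],
                                      sigma_floor),
                          error = function(e) {
                            errs[i] <<- conditionMessage(e)
                            NULL
                          })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    pl_stop("division_mixture", "every K failed: ",
            paste(unique(stats::na.omit(errs)), collapse = "; "))
  if (any(!ok))
    warning("skipped degenerate K: ", paste(ks[!ok], collapse = ", "))
  tab <- data.frame(K = ks,
                    log_likelihood = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$log_likelihood,
                      numeric(1)),
                    bic = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$bic, numeric(1)),
                    aic = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$aic, numeric(1)),
                    error = errs)
  best_i <- which(ok)[which.min(tab$bic[ok])]  # which.min takes first tie
  list(model = fits[[best_i]], table = tab)
}

#' Fit a halving-constrained Gaussian mixture
#'
#' EM in which the component means are tied to a single undivided-intensity
#' mean through the dilution model, `mu_k = mu0 * 2^(-d_k)` for the given
#' division counts `d_k`; only `mu0`, the per-component standard deviations
#' and the weights are free.
#'
#' @inheritParams fit_mixture
#' @param division_set distinct nonnegative integers, one per component.
#' @return a constrained `mixture_model` with `mu0` and `division_indices`.
#' @export
fit_halving_constrained <- function(x, division_set, restarts = 20L,
                                    seed = 0L, sigma_floor = NULL) {
  division_set <- sort(unique(as.integer(division_set)))
  if (any(division_set < 0L))
    pl_stop("division_mixture", "division_set must be nonnegative integers")
  K <- length(division_set)
  sigma_floor <- sigma_floor %||% (1e-6 * stats::sd(x))
  x <- check_mixture_sample(x, K, sigma_floor)
  ck <- 2^(-division_set)
  if (K == 1L && division_set[1L] == 0L) {
    f <- fit_mixture(x, 1L)
    return(new_mixture(1L, 1, f$means, f$sds, f$log_likelihood, length(x),
                       constrained = TRUE, mu0 = f$means,
                       division_indices = 0L, loglik_trace = f$loglik_trace))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      mu0 <- stats::quantile(x, 0.98, names = FALSE) *
        stats::runif(1, 0.8, 1.2)
      w <- rep(1 / K, K)
      sd <- rep(stats::sd(x) / 2, K)
      fit <- em_halving(x, w, mu0, sd, ck, sigma_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  new_mixture(K, best$w, best$mu0 * ck, best$sd, best$loglik, length(x),
              constrained = TRUE, mu0 = best$mu0,
              division_indices = division_set, loglik_trace = best$trace)
}

em_halving <- function(x, w, mu0, sd, ck, sigma_floor, max_iter = 500L,
                       tol = 1e-8) {
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mu <- mu0 * ck
    g <- mixture_posteriors(x, w, mu, sd)
    nk <- pmax(colSums(g), 1e-12)
    w <- nk / n
    # weighted least squares for the shared scale mu0
    num <- sum(vapply(seq_along(ck), function(k)
      ck[k] / sd[k]^2 * sum(g[, k] * x), numeric(1)))
    den <- sum(vapply(seq_along(ck), function(k)
      ck[k]^2 / sd[k]^2 * nk[k], numeric(1)))
    mu0 <- num / den
    mu <- mu0 * ck
    sd <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / nk)
    sd <- pmax(sd, sigma_floor, .Machine$double.xmin)
    ll <- mixture_loglik(x, w, mu, sd)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
  }
  list(w = w, mu0 = mu0, sd = sd, loglik = ll, trace = trace)
}

#' Assign nuclei to mixture populations
#'
#' Maximum-posterior component per nucleus with posteriors by Bayes rule
#' over the fitted mixture.  The estimated division count is the
#' component's `d_k` for constrained models, else the 0-based rank of the
#' component by descending mean (0 = brightest = fewest divisions).
#'
#' @param model a fitted `mixture_model`.
#' @param x intensity vector, or a [measure_nuclei()] table (then `column`
#'   names the intensity column).
#' @param column intensity column used when `x` is a records table.
#' @return data frame of class `population_assignment`: `component`
#'   (1-based index into the sorted components), `posterior`,
#'   `division_estimate`, plus `label` when records are supplied.
#' @export
assign_populations <- function(model, x,
                               column = "bgsub_mean_nuclear_converted") {
  labels <- NULL
  if (is.data.frame(x)) {
    labels <- x$label
    x <- x[[column]] %||% pl_stop("division_mixture", "no column '", column,
                                  "' in records")
  }
  p <- mixture_posteriors(x, model$weights, model$means, model$sds)
  comp <- max.col(p, ties.method = "first")
  est <- if (model$constrained) model$division_indices[comp] else comp - 1L
  out <- data.frame(component = comp,
                    posterior = p[cbind(seq_along(comp), comp)],
                    division_estimate = as.integer(est))
  if (!is.null(labels)) out <- cbind(label = labels, out)
  attr(out, "posterior_matrix") <- p
  class(out) <- c("population_assignment", "data.frame")
  out
}

#' Map an intensity to a division count under the halving model
#'
#' `round(log2(mu0 / intensity))`, clamped at 0: each division halves the
#' converted label.
#'
#' @param intensity positive intensity value(s).
#' @param mu0 undivided-population mean intensity (> 0).
#' @return integer division estimate(s).
#' @export
estimate_divisions <- function(intensity, mu0) {
  if (any(intensity <= 0) || mu0 <= 0)
    pl_stop("division_mixture", "intensity and mu0 must be > 0")
  as.integer(pmax(0, round(log2(mu0 / intensity))))
}
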