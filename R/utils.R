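# Internal helpers shared across modules.

#' @useDynLib photolineage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Stage logging to stderr: reproducibility audit trail (stage, seed, params).
pl_log <- function(stage, ..., verbose = getOption("photolineage.verbose", TRUE)) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(sprintf("[photolineage:%s] %s", stage, paste0(..., collapse = "")))
  invisible(NULL)
}

pl_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(..., collapse = "")), call. = FALSE)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the prior
# RNG state afterwards so simulations never perturb the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# log(sum(exp(m[i, ]))) per row, numerically stable
logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

# Separable Gaussian blur of a 2D matrix (y, x), replicate-padded edges.
# Kernel truncated at 3 sigma and renormalised.
gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(mm, along_rows) {
    n <- if (along_rows) nrow(mm) else ncol(mm)
    out <- 0 * mm
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * (if (along_rows) mm[idx, , drop = FALSE]
                           else mm[, idx, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

# Truncated-normal draw on (lo, hi) by rejection; mean mu, sd sd.
rtrunc_norm <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(mu, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mu, sd)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expression-variability multiplier: mean 1, coefficient of variation cv,
# symmetric (truncated normal) so intensity classes stay Gaussian-shaped.
rexpr_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  rtrunc_norm(n, 1, cv, 0, 2)
}
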