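# internal numerical helpers

# Gauss error function; erf(z/sqrt(2)) = 2*pnorm(z) - 1
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# n draws from Dirichlet(alpha) as an n x m matrix of rows on the simplex
rdirichlet <- function(n, alpha) {
  m <- length(alpha)
  g <- matrix(stats::rgamma(n * m, shape = rep(alpha, each = n)), nrow = n, ncol = m)
  sw <- rowSums(g)
  # guard against all-zero rows (possible for tiny alpha)
  bad <- sw == 0
  if (any(bad)) {
    g[bad, ] <- 1
    sw[bad] <- m
  }
  g / sw
}

stop_spec <- function(msg, ..., class = "isomix_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_spec("`%s` must be numeric and non-missing", name)
  if (any(x > hi) || any(x < lo) || (open_lo && any(x == lo))) {
    stop_spec("`%s` must lie in %s%s, %s]", name, if (open_lo) "(" else "[",
              format(lo), format(hi), class = "isomix_domain_error")
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_spec("`%s` must be finite and numeric", name)
  }
  invisible(x)
}

# recycle a scalar across n signatures, or check length
recycle_sig <- function(x, n, name) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) != n) {
    stop_spec("`%s` has length %d but %d signature(s) are in use", name, length(x), n)
  }
  as.numeric(x)
}
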