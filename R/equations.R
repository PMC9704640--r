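# Model-equation objects.
#
# An equation object evaluates proposals in bulk: `mu_fun(f, r, P, S, ctx)`
# takes an N x m fraction matrix, an N x q auxiliary-variable matrix, a named
# list of N x n parameter-draw matrices and the m x n source-mean matrix, and
# returns the N x n matrix of predicted compositions. `coef_fun` returns, for
# each signature, the N x m matrix of sensitivities d mu_i / d S_{j,i} used to
# propagate point-source sd (in quadrature) and range-source half-widths
# (linearly, as the spread).

new_equation <- function(kind, name, mu_fun, coef_fun, n_vars, param_slots,
                         min_sources = 1L, max_sources = Inf) {
  structure(
    list(kind = kind, name = name, mu_fun = mu_fun, coef_fun = coef_fun,
         n_vars = n_vars, param_slots = param_slots,
         min_sources = min_sources, max_sources = max_sources),
    class = "isomix_equation"
  )
}

#' @export
print.isomix_equation <- function(x, ...) {
  cat(sprintf("<isomix equation: %s (%s); %d auxiliary variable(s); params: %s>\n",
              x$name, x$kind, x$n_vars,
              if (length(x$param_slots)) paste(x$param_slots, collapse = ", ")
              else "none"))
  invisible(x)
}

mix_mu_bulk <- function(f, S) f %*% S

coef_fractions <- function(f, n) {
  lapply(seq_len(n), function(i) f)
}

builtin_equations <- function() {
  list(
    mixing = new_equation(
      "builtin", "mixing",
      mu_fun = function(f, r, P, S, ctx) mix_mu_bulk(f, S),
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 0L, param_slots = character()
    ),
    open_system = new_equation(
      "builtin", "open_system",
      mu_fun = function(f, r, P, S, ctx) {
        mu <- mix_mu_bulk(f, S)
        mu - P[["A"]] * (1 - r[, 1])
      },
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 1L, param_slots = "A"
    ),
    open_system_reduced = new_equation(
      "builtin", "open_system_reduced",
      mu_fun = function(f, r, P, S, ctx) {
        mix_mu_bulk(f, S) - P[["E"]] * r[, 1]
      },
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 1L, param_slots = "E"
    ),
    rayleigh = new_equation(
      "builtin", "rayleigh",
      mu_fun = function(f, r, P, S, ctx) {
        mix_mu_bulk(f, S) + P[["A"]] * log(r[, 1])
      },
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 1L, param_slots = "A"
    ),
    rayleigh_source1 = new_equation(
      "builtin", "rayleigh_source1",
      mu_fun = function(f, r, P, S, ctx) {
        mix_mu_bulk(f, S) + (f[, 1] * log(r[, 1])) * P[["A"]]
      },
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 1L, param_slots = "A"
    ),
    equilibrium = new_equation(
      "builtin", "equilibrium",
      mu_fun = function(f, r, P, S, ctx) {
        w <- r[, 1] * ctx$multiplier_matrix(P, nrow(f))
        mix_mu_bulk(f, S) * (1 - w) + P[["E"]] * w
      },
      coef_fun = function(f, r, P, S, ctx) {
        w <- r[, 1] * ctx$multiplier_matrix(P, nrow(f))
        lapply(seq_len(ncol(S)), function(i) f * (1 - w[, i]))
      },
      n_vars = 1L, param_slots = c("E", "mult")
    ),
    craig_gordon = new_equation(
      "builtin", "craig_gordon",
      mu_fun = function(f, r, P, S, ctx) {
        denom <- r[, 1] * P[["A"]] + 1
        (r[, 1] * P[["A"]] * P[["D"]] +
           matrix(S[1, ], nrow(f), ncol(S), byrow = TRUE)) / denom
      },
      coef_fun = function(f, r, P, S, ctx) {
        denom <- r[, 1] * P[["A"]] + 1
        lapply(seq_len(ncol(S)), function(i) matrix(1 / denom[, i], ncol = 1))
      },
      n_vars = 1L, param_slots = c("A", "D"),
      min_sources = 1L, max_sources = 1L
    ),
    nitrite = new_equation(
      "builtin", "nitrite",
      mu_fun = function(f, r, P, S, ctx) {
        C <- P[["C"]]
        (mix_mu_bulk(f, S) - 0.7 * P[["A"]] - 0.3 * P[["B"]]) * (1 - C) +
          ctx$equil_value * C
      },
      coef_fun = function(f, r, P, S, ctx) {
        C <- P[["C"]]
        lapply(seq_len(ncol(S)), function(i) f * (1 - C[, i]))
      },
      n_vars = 0L, param_slots = c("A", "B", "C")
    ),
    n2o = new_equation(
      "builtin", "n2o",
      mu_fun = function(f, r, P, S, ctx) {
        mix_mu_bulk(f, S) + P[["A"]] * log(r[, 1])
      },
      coef_fun = function(f, r, P, S, ctx) coef_fractions(f, ncol(S)),
      n_vars = 1L, param_slots = "A"
    )
  )
}

#' Names of the built-in model equations
#'
#' @return Character vector of equation names accepted by [iso_model()].
#' @export
builtin_equation_names <- function() names(builtin_equations())

get_builtin_equation <- function(name) {
  eqs <- builtin_equations()
  if (!name %in% names(eqs)) {
    stop_spec("unknown builtin equation '%s'; available: %s", name,
              paste(names(eqs), collapse = ", "))
  }
  eqs[[name]]
}

# ---- user expressions ------------------------------------------------------

allowed_calls <- c("+", "-", "*", "/", "^", "(", "ln", "log", "exp", "sqrt")

walk_expr_symbols <- function(e, allowed_syms) {
  if (is.numeric(e) || is.integer(e)) return(invisible(NULL))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% allowed_syms) {
      stop_spec("unknown symbol '%s' in model expression", nm,
                class = "isomix_parse_error")
    }
    return(invisible(NULL))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% allowed_calls) {
      stop_spec("disallowed token '%s' in model expression", fn,
                class = "isomix_parse_error")
    }
    for (k in seq_along(e)[-1]) walk_expr_symbols(e[[k]], allowed_syms)
    return(invisible(NULL))
  }
  stop_spec("unsupported construct in model expression",
            class = "isomix_parse_error")
}

#' Build a model equation from a user expression
#'
#' Parses an arithmetic expression over the mixing fractions `f1..fm`, the
#' per-signature source values `S1..Sm`, declared auxiliary parameters and
#' declared auxiliary variables. `ln` is accepted as an alias for the natural
#' logarithm; the only other functions allowed are `log`, `exp` and `sqrt`.
#' The expression is evaluated independently for each signature, with `Sj`
#' bound to that signature's source mean and each parameter bound to its
#' (possibly redrawn) per-signature value. Source sensitivities for
#' uncertainty and spread propagation are obtained by central finite
#' differences with a relative step of 1e-6.
#'
#' @param text Expression text, e.g. `"f1*S1 + f2*S2 + A*ln(r)"`.
#' @param m Number of sources.
#' @param params Character vector of auxiliary-parameter names the expression
#'   may reference.
#' @param vars Character vector of auxiliary-variable names (each sampled
#'   uniformly within its prior bounds).
#' @return An equation object usable as the `equation` argument of
#'   [iso_model()].
#' @examples
#' eq <- parse_model_equation("f1*S1 + f2*S2", m = 2)
#' @export
parse_model_equation <- function(text, m, params = character(),
                                 vars = character()) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text), error = function(err) {
    stop_spec("cannot parse model expression: %s", conditionMessage(err),
              class = "isomix_parse_error")
  })
  f_syms <- paste0("f", seq_len(m))
  s_syms <- paste0("S", seq_len(m))
  walk_expr_symbols(e, c(f_syms, s_syms, params, vars))

  eval_sig <- function(e, f, r, P, S, i, s_override = NULL) {
    env <- new.env(parent = baseenv())
    assign("ln", log, envir = env)
    for (j in seq_len(m)) {
      assign(f_syms[j], f[, j], envir = env)
      assign(s_syms[j],
             if (is.null(s_override)) S[j, i] else s_override[j], envir = env)
    }
    for (p in params) assign(p, P[[p]][, i], envir = env)
    for (k in seq_along(vars)) assign(vars[k], r[, k], envir = env)
    eval(e, env)
  }

  mu_fun <- function(f, r, P, S, ctx) {
    n <- ncol(S)
    out <- matrix(0, nrow(f), n)
    for (i in seq_len(n)) out[, i] <- eval_sig(e, f, r, P, S, i)
    out
  }
  coef_fun <- function(f, r, P, S, ctx) {
    n <- ncol(S)
    lapply(seq_len(n), function(i) {
      cf <- matrix(0, nrow(f), m)
      for (j in seq_len(m)) {
        h <- 1e-6 * max(1, abs(S[j, i]))
        sp <- sm <- S[, i]
        sp[j] <- sp[j] + h
        sm[j] <- sm[j] - h
        cf[, j] <- (eval_sig(e, f, r, P, S, i, s_override = sp) -
                      eval_sig(e, f, r, P, S, i, s_override = sm)) / (2 * h)
      }
      cf
    })
  }

  new_equation("expression", text, mu_fun, coef_fun,
               n_vars = length(vars), param_slots = params)
}
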