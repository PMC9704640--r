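# Threshold Metropolis-Hastings sampling over (fractions, process variables).

#' Draw independent proposal states
#'
#' Proposals are independent of the chain state: fractions come from a
#' Dirichlet distribution on the simplex (flat by default) and each auxiliary
#' variable from a uniform distribution within its prior bounds.
#'
#' @param model An [iso_model()].
#' @param n Number of proposals.
#' @param alpha Dirichlet concentration: scalar or length-m vector (default
#'   all ones, i.e. uniform on the simplex).
#' @return A tibble with columns `f_<source>` and `r_<var>`.
#' @export
propose_states <- function(model, n, alpha = 1) {
  stopifnot(inherits(model, "iso_model"))
  m <- nrow(model$S)
  if (length(alpha) == 1L) alpha <- rep(alpha, m)
  if (length(alpha) != m || any(alpha <= 0)) {
    stop_spec("`alpha` must be positive with one value per source")
  }
  f <- rdirichlet(n, alpha)
  out <- tibble::as_tibble(as.data.frame(f, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- paste0("f_", model$source_names)
  if (nrow(model$vars) > 0) {
    for (k in seq_len(nrow(model$vars))) {
      out[[paste0("r_", model$vars$name[k])]] <-
        stats::runif(n, model$vars$lo[k], model$vars$hi[k])
    }
  }
  out
}

#' Threshold acceptance rule
#'
#' The acceptance step of the sampler: a candidate with likelihood `L` is
#' accepted when `L >= alpha * T`, where `T` is the running likelihood
#' threshold (initialised at 0, so the first positive-likelihood candidate is
#' always accepted) and `alpha` is a fresh uniform draw on `[0, 1]`. On
#' acceptance the threshold is set to `L`; on rejection it is unchanged.
#' Zero-likelihood candidates are never accepted, so a measurement the model
#' cannot reach leaves the chain empty (and [run_chain()] raises an error)
#' instead of filling it with impossible states.
#' Because proposals are independent, this is the acceptance rule of an
#' independence Metropolis sampler, `P(accept) = min(1, L / T)`.
#'
#' @param L Candidate likelihood (>= 0).
#' @param T Current threshold (>= 0).
#' @param alpha Uniform draw in `[0, 1]`.
#' @return A list with elements `accepted` (logical) and `T` (updated
#'   threshold).
#' @export
threshold_accept <- function(L, T, alpha) {
  if (!is.finite(L) || L < 0) {
    stop_spec("likelihood must be finite and non-negative (got %s)", format(L))
  }
  if (L > 0 && L >= alpha * T) list(accepted = TRUE, T = L)
  else list(accepted = FALSE, T = T)
}

# Sequential scan of the threshold rule over a block of likelihoods.
# Returns accepted indices (in order) and the final threshold.
threshold_scan <- function(L, alpha, T0) {
  keep <- integer(length(L))
  k <- 0L
  T <- T0
  for (i in seq_along(L)) {
    if (L[i] > 0 && L[i] >= alpha[i] * T) {
      T <- L[i]
      k <- k + 1L
      keep[k] <- i
    }
  }
  list(idx = keep[seq_len(k)], T = T)
}

# Standard independence-Metropolis scan (validation mode): the chain advances
# every iteration, repeating the current state on rejection. Returns, per
# iteration, the index of the newly accepted proposal (0 on rejection) and
# the final current likelihood.
metropolis_scan <- function(L, alpha, cur_L) {
  out <- integer(length(L))
  acc <- 0L
  for (i in seq_along(L)) {
    if ((cur_L <= 0 && L[i] > 0) || (cur_L > 0 && alpha[i] <= L[i] / cur_L)) {
      cur_L <- L[i]
      acc <- acc + 1L
      out[i] <- i
    }
  }
  list(new_idx = out, cur_L = cur_L, accepted = acc)
}

#' Run the sampler for one measurement
#'
#' Draws independent proposals (Dirichlet fractions, uniform auxiliary
#' variables, Gaussian redraws of auxiliary parameters), evaluates the model
#' likelihood in blocks, and applies the threshold acceptance rule until
#' `chain_length` post-burn-in entries are collected or `max_iterations`
#' proposals are exhausted. Burn-in is counted in accepted entries. With
#' `method = "metropolis"` a textbook independence-Metropolis chain (which
#' repeats the current state on rejection) is produced instead; its
#' stationary distribution is exactly the Bayesian posterior under the
#' proposal prior and it is provided for cross-validation.
#'
#' @param model An [iso_model()].
#' @param sample An [iso_measurement()] or a one-row samples data frame
#'   (columns `id`, `<sig>`, `<sig>_sd`).
#' @param chain_length Target number of post-burn-in entries.
#' @param burn_in Accepted entries discarded before recording.
#' @param max_iterations Hard cap on proposal draws.
#' @param alpha Dirichlet concentration for the fraction proposals.
#' @param seed Optional RNG seed; identical inputs and seed give bit-identical
#'   chains.
#' @param method `"threshold"` (default) or `"metropolis"` (validation mode).
#' @param likelihood_mode `"auto"` (erf form on signatures reached by range
#'   sources, Gaussian elsewhere), `"point"` or `"range"`.
#' @param block_size Proposals evaluated per vectorised block.
#' @return An object of class `iso_chain`: a list with `entries` (tibble of
#'   accepted states, predictions and likelihoods), `burn_in`, acceptance
#'   statistics and the inputs. Use [tidy()] / [posterior_summary()] for
#'   summaries and [autoplot()] for diagnostics.
#' @export
run_chain <- function(model, sample, chain_length = 10000, burn_in = 1000,
                      max_iterations = 2e6, alpha = 1, seed = NULL,
                      method = c("threshold", "metropolis"),
                      likelihood_mode = c("auto", "point", "range"),
                      block_size = 200000L) {
  stopifnot(inherits(model, "iso_model"))
  method <- match.arg(method)
  likelihood_mode <- match.arg(likelihood_mode)
  meas <- as_measurement(sample, model)
  if (chain_length < 1 || burn_in < 0) {
    stop_spec("chain_length must be >= 1 and burn_in >= 0")
  }
  if (max_iterations <= chain_length) {
    stop_spec("max_iterations must exceed chain_length")
  }
  if (!is.null(seed)) set.seed(seed)

  m <- nrow(model$S)
  n <- length(model$signatures)
  nv <- nrow(model$vars)
  if (length(alpha) == 1L) alpha_vec <- rep(alpha, m) else alpha_vec <- alpha
  if (length(alpha_vec) != m || any(alpha_vec <= 0)) {
    stop_spec("`alpha` must be positive with one value per source")
  }

  needed <- chain_length + burn_in
  chunks <- list()
  total_kept <- 0L
  iters <- 0L
  accepted_total <- 0L
  T <- 0
  cur_L <- 0       # metropolis mode: current likelihood ...
  cur_row <- NULL  # ... and the row recorded for the current state

  while (total_kept < needed && iters < max_iterations) {
    nb <- as.integer(min(block_size, max_iterations - iters))
    f <- rdirichlet(nb, alpha_vec)
    r <- matrix(0, nb, max(nv, 0L))
    if (nv > 0) {
      for (k in seq_len(nv)) {
        r[, k] <- stats::runif(nb, model$vars$lo[k], model$vars$hi[k])
      }
    }
    P <- draw_params(model, nb)
    bl <- block_likelihood(model, meas, f, r, P, mode = likelihood_mode)
    a <- stats::runif(nb)
    block_rows <- function(keep) {
      cbind(iteration = iters + keep, f[keep, , drop = FALSE],
            r[keep, , drop = FALSE][, seq_len(nv), drop = FALSE],
            bl$mu[keep, , drop = FALSE],
            bl$spread[keep, , drop = FALSE],
            likelihood = bl$L[keep])
    }

    if (method == "threshold") {
      sc <- threshold_scan(bl$L, a, T)
      T <- sc$T
      accepted_total <- accepted_total + length(sc$idx)
      if (length(sc$idx) > 0) {
        keep <- utils::head(sc$idx, needed - total_kept)
        chunks[[length(chunks) + 1L]] <- block_rows(keep)
        total_kept <- total_kept + length(keep)
      }
    } else {
      sc <- metropolis_scan(bl$L, a, cur_L)
      cur_L <- sc$cur_L
      accepted_total <- accepted_total + sc$accepted
      # per iteration, index of the most recently accepted proposal in this
      # block (0 = still at the carried-in state)
      src <- cummax(sc$new_idx)
      if (is.null(cur_row) && any(src > 0L)) {
        drop_n <- which(src > 0L)[1] - 1L
        if (drop_n > 0L) src <- src[-seq_len(drop_n)]
      } else if (is.null(cur_row)) {
        src <- integer(0)
      }
      if (length(src) > 0) {
        src <- utils::head(src, needed - total_kept)
        uniq <- unique(src[src > 0L])
        rows_new <- block_rows(uniq)
        lookup <- match(src, uniq)  # NA where src == 0 (carried-in state)
        rows <- matrix(0, length(src), ncol(rows_new))
        if (any(src == 0L)) {
          rows[src == 0L, ] <- matrix(cur_row, sum(src == 0L),
                                      ncol(rows_new), byrow = TRUE)
        }
        rows[src > 0L, ] <- rows_new[lookup[src > 0L], , drop = FALSE]
        colnames(rows) <- colnames(rows_new)
        chunks[[length(chunks) + 1L]] <- rows
        total_kept <- total_kept + nrow(rows)
        cur_row <- rows[nrow(rows), ]
      }
    }
    iters <- iters + nb
  }

  if (total_kept == 0L) {
    stop_spec(paste0("the model cannot reach the measurement '%s': no ",
                     "proposal was accepted in %d iterations; inspect the ",
                     "z-score diagnostic of a wider model"),
              meas$id, iters, class = "isomix_unreachable_error")
  }

  entries <- do.call(rbind, chunks)
  colnames(entries) <- c("iteration", paste0("f_", model$source_names),
                         if (nv > 0) paste0("r_", model$vars$name),
                         paste0("mu_", model$signatures),
                         paste0("spread_", model$signatures), "likelihood")
  entries <- tibble::as_tibble(as.data.frame(entries))

  exhausted <- total_kept < needed
  if (exhausted) {
    rlang::warn(sprintf(
      "sampler stopped after %d iterations with %d of %d requested entries",
      iters, total_kept, needed))
  }

  structure(
    list(entries = entries, burn_in = min(burn_in, max(total_kept - 1L, 0L)),
         chain_length = chain_length, iterations = iters,
         accepted = accepted_total,
         acceptance_rate = accepted_total / iters,
         exhausted = exhausted, method = method,
         likelihood_mode = likelihood_mode,
         model = model, measurement = meas, seed = seed),
    class = "iso_chain"
  )
}

#' @export
print.iso_chain <- function(x, ...) {
  cat(sprintf(
    "<iso_chain '%s': %d entries (+%d burn-in), %d iterations, acc. rate %.3f%s>\n",
    x$measurement$id, nrow(x$entries) - x$burn_in, x$burn_in, x$iterations,
    x$acceptance_rate, if (x$exhausted) ", EXHAUSTED" else ""))
  invisible(x)
}

# post-burn-in entries
chain_entries <- function(chain) {
  stopifnot(inherits(chain, "iso_chain"))
  if (chain$burn_in > 0L) {
    chain$entries[-seq_len(chain$burn_in), , drop = FALSE]
  } else {
    chain$entries
  }
}

# names of the sampled variables (fractions + aux variables)
chain_variables <- function(chain) {
  grep("^(f|r)_", names(chain$entries), value = TRUE)
}

#' Run the sampler for several samples
#'
#' Runs [run_chain()] for each row of a samples table under a shared model.
#' Per-sample seeds are derived deterministically from `seed` and the row
#' index, so a batch is reproducible and each sample's chain is independent.
#' Errors are captured per sample rather than aborting the batch.
#'
#' @param model An [iso_model()].
#' @param samples Data frame with one row per sample (`id`, `<sig>`,
#'   `<sig>_sd`).
#' @param seed Base seed; sample `i` uses `seed + 10007 * (i - 1)`.
#' @param ... Passed on to [run_chain()].
#' @return A named list of `iso_chain` objects (or `error` conditions) keyed
#'   by sample id.
#' @export
run_batch <- function(model, samples, seed = NULL, ...) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) return(stats::setNames(list(), character()))
  ids <- as.character(samples$id %||% seq_len(nrow(samples)))
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    si <- if (is.null(seed)) NULL else as.integer((seed + 10007 * (i - 1)) %%
                                                    .Machine$integer.max)
    out[[i]] <- tryCatch(
      run_chain(model, samples[i, , drop = FALSE], seed = si, ...),
      error = function(e) e)
  }
  stats::setNames(out, ids)
}
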