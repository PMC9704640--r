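# Diagnostic plots (static ggplot2 versions of the usual MCMC views).

#' Trace plot of the sampled variables
#'
#' Accepted entries against their acceptance order, burn-in shaded. A
#' healthy chain looks like stationary noise around a stable level.
#'
#' @param chain An `iso_chain` object.
#' @return A ggplot object.
#' @export
plot_trace <- function(chain) {
  ent <- chain$entries
  ent$entry <- seq_len(nrow(ent))
  long <- tidyr::pivot_longer(ent[c("entry", chain_variables(chain))],
                              -"entry", names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$entry, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = chain$burn_in, linetype = "dashed") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "accepted entry", y = "value",
                  title = sprintf("Markov chain, sample '%s'",
                                  chain$measurement$id)) +
    ggplot2::theme_minimal()
}

#' Posterior histograms
#'
#' @param chain An `iso_chain` object.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_posterior <- function(chain, bins = 60) {
  ent <- chain_entries(chain)
  long <- tidyr::pivot_longer(ent[chain_variables(chain)],
                              dplyr::everything(), names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = "value", y = "entries",
                  title = sprintf("Posterior distributions, sample '%s'",
                                  chain$measurement$id)) +
    ggplot2::theme_minimal()
}

#' Pairwise scatter of sampled variables
#'
#' Scatter plots for every variable pair (thinned), the usual corner-style
#' view for inspecting correlations and multi-modality.
#'
#' @param chain An `iso_chain` object.
#' @param max_points Points drawn per panel.
#' @return A ggplot object.
#' @export
plot_pairs <- function(chain, max_points = 3000) {
  ent <- chain_entries(chain)
  vars <- chain_variables(chain)
  if (length(vars) < 2) stop_spec("pairs plot needs at least two variables")
  if (nrow(ent) > max_points) {
    ent <- ent[seq(1, nrow(ent), length.out = max_points), ]
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(panel = paste(p[1], "vs", p[2]),
                   xv = ent[[p[1]]], yv = ent[[p[2]]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$xv, y = .data$yv)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Variable correlations, sample '%s'",
                                  chain$measurement$id)) +
    ggplot2::theme_minimal()
}

#' Optimization path in signature space
#'
#' Chain predictions plotted in the plane of two signatures together with
#' the measurement and the source boxes (range half-widths or 1-sd boxes).
#' By construction the cloud of predicted values cannot leave the polygon
#' spanned by the source centres unless a fractionation term moves it.
#'
#' @param chain An `iso_chain` object.
#' @param signatures Two signature labels (default: the first two).
#' @param max_points Points drawn.
#' @return A ggplot object.
#' @export
plot_path <- function(chain, signatures = NULL, max_points = 2000) {
  model <- chain$model
  sigs <- signatures %||% utils::head(model$signatures, 2)
  if (length(sigs) != 2 || !all(sigs %in% model$signatures)) {
    stop_spec("need two valid signature labels for the path plot")
  }
  ent <- chain_entries(chain)
  if (nrow(ent) > max_points) {
    ent <- ent[seq(1, nrow(ent), length.out = max_points), ]
  }
  half <- pmax(delta_eff(model), sigma_eff(model))
  boxes <- tibble::tibble(
    name = model$source_names,
    xmin = model$S[, sigs[1]] - half[, sigs[1]],
    xmax = model$S[, sigs[1]] + half[, sigs[1]],
    ymin = model$S[, sigs[2]] - half[, sigs[2]],
    ymax = model$S[, sigs[2]] + half[, sigs[2]])
  xi <- match(sigs, model$signatures)
  meas <- tibble::tibble(x = chain$measurement$x[xi[1]],
                         y = chain$measurement$x[xi[2]])
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = boxes,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = "grey80", colour = "grey40", alpha = 0.6) +
    ggplot2::geom_path(data = tibble::tibble(
      x = ent[[paste0("mu_", sigs[1])]], y = ent[[paste0("mu_", sigs[2])]]),
      ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.2, colour = "steelblue") +
    ggplot2::geom_point(data = meas, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::labs(x = sigs[1], y = sigs[2],
                  title = sprintf("Optimization path, sample '%s'",
                                  chain$measurement$id)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trace
#' @param object An `iso_chain` object.
#' @param type One of `"trace"`, `"posterior"`, `"pairs"`, `"path"`.
#' @param ... Passed to the corresponding `plot_*()` function.
#' @method autoplot iso_chain
#' @export
autoplot.iso_chain <- function(object,
                               type = c("trace", "posterior", "pairs",
                                        "path"), ...) {
  type <- match.arg(type)
  switch(type,
         trace = plot_trace(object, ...),
         posterior = plot_posterior(object, ...),
         pairs = plot_pairs(object, ...),
         path = plot_path(object, ...))
}
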