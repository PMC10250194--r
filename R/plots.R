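# ggplot2 diagnostics for fitted models and FSC curves.

#' Plot an FSC curve
#'
#' @param curve an `fsc_curve` from [fsc()] (or several, as a named list).
#' @param thresholds horizontal reference lines (default 0.5 and 0.143).
#' @return A ggplot object.
#' @export
plot_fsc <- function(curve, thresholds = c(0.5, 0.143)) {
  if (inherits(curve, "fsc_curve")) curve <- list(fsc = curve)
  df <- do.call(rbind, lapply(names(curve), function(nm) {
    d <- as.data.frame(curve[[nm]]); d$which <- nm; d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$fsc,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "spatial frequency (1/Å)",
                  y = "Fourier shell correlation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the training loss trace
#'
#' @param fit a `flex_fit`.
#' @return A ggplot object with per-epoch data, rigidity and total energies.
#' @export
plot_loss_trace <- function(fit) {
  tr <- fit$loss_trace
  df <- rbind(
    data.frame(epoch = tr$epoch, energy = tr$E_data, term = "E_data"),
    data.frame(epoch = tr$epoch, energy = tr$E_rigid, term = "E_rigid"),
    data.frame(epoch = tr$epoch, energy = tr$total, term = "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "energy") +
    ggplot2::theme_minimal()
}

#' Plot the latent embedding
#'
#' @param fit a `flex_fit`.
#' @param dims which two latent dimensions to show (1-D fits are shown as a
#'   histogram).
#' @return A ggplot object.
#' @export
plot_latents <- function(fit, dims = c(1, 2)) {
  z <- as.data.frame(fit$latents)
  names(z) <- paste0("z", seq_len(ncol(z)))
  if (ncol(z) == 1) {
    return(ggplot2::ggplot(z, ggplot2::aes(x = .data$z1)) +
             ggplot2::geom_histogram(bins = 40) +
             ggplot2::labs(x = "latent coordinate") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(z, ggplot2::aes(x = .data[[paste0("z", dims[1])]],
                                  y = .data[[paste0("z", dims[2])]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = paste0("z", dims[1]), y = paste0("z", dims[2])) +
    ggplot2::theme_minimal()
}
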