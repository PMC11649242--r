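#' Scatter of binary soma responses with the fitted Heaviside step
#'
#' Reproduces the standard threshold figure: each point is one astrocyte
#' (fraction of active domains vs soma active yes/no), with the fitted step
#' overlaid and the threshold marked.
#'
#' @param fit a [fit_heaviside()] result.
#' @param responses the data.frame it was fitted to.
#' @return invisibly NULL; draws on the current device.
#' @export
plot_threshold_fit <- function(fit, responses) {
  stopifnot(inherits(fit, "threshold_fit"), !isTRUE(fit$degenerate))
  plot(responses$a, responses$soma_active, pch = 16, cex = 0.6,
       col = grDevices::adjustcolor("firebrick", 0.5),
       xlab = "fraction of active domains (a)",
       ylab = "soma active S(a)", yaxt = "n",
       main = sprintf("spatial threshold a_T = %.1f%% (R^2 = %.2f, n = %d)",
                      100 * fit$a_T, fit$r_squared, fit$n_cells))
  axis(2, at = c(0, 1))
  xs <- seq(0, 1, length.out = 400)
  lines(xs, heaviside(xs, fit$a_T), col = "steelblue", lwd = 2, lty = 2)
  abline(v = fit$a_T, col = "steelblue", lty = 3)
  invisible(NULL)
}

#' Temporal map of one astrocyte's domain onsets
#'
#' Colours each domain of a segmented astrocyte by its event onset relative
#' to soma activation (negative = pre-soma, positive = post-soma), the
#' standard visualisation of the centripetal-then-centrifugal surge.
#'
#' @param seg a `segmentation` object for the astrocyte.
#' @param onsets a classified onset table containing this astrocyte.
#' @return invisibly NULL; draws on the current device.
#' @export
plot_temporal_map <- function(seg, onsets) {
  stopifnot(inherits(seg, "segmentation"), seg$ok)
  id_rows <- onsets[onsets$astrocyte_id == onsets$astrocyte_id[1], ]
  rel <- id_rows$onset_rel_soma_s
  if (all(is.na(rel))) rel <- id_rows$onset_s
  lab <- seg$domain_label
  img <- matrix(NA_real_, nrow(lab), ncol(lab))
  for (i in seq_len(nrow(id_rows))) {
    k <- match(id_rows$domain_id[i], seg$domains$domain_id)
    if (is.na(k)) next
    img[lab == seg$domains$domain_index[k]] <- rel[i]
  }
  img[seg$soma_mask] <- 0
  graphics::image(t(img[rev(seq_len(nrow(img))), ]),
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  axes = FALSE, asp = 1,
                  main = "domain onset relative to soma (s)")
  invisible(NULL)
}
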