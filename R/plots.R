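#' Consensus heatmap (patients ordered by final labels)
#'
#' Displays the consensus matrix with patients grouped by their final
#' cluster; stable structure shows as dark blocks on the diagonal.
#'
#' @param run a `consensus_run`.
#' @param main plot title.
#' @export
plot_consensus_heatmap <- function(run, main = NULL) {
  stopifnot(inherits(run, "consensus_run"))
  ord <- order(run$final_labels)
  M <- run$consensus[ord, ord]
  n <- nrow(M)
  pal <- grDevices::colorRampPalette(c("white", "#c6dbef", "#2171b5",
                                       "#08306b"))(100)
  graphics::image(seq_len(n), seq_len(n), M[, rev(seq_len(n))],
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "",
                  main = if (is.null(main))
                    paste0("Consensus matrix (k = ", run$k, ")") else main)
  sizes <- cumsum(tabulate(run$final_labels[ord], run$k))
  graphics::abline(v = sizes[-length(sizes)] + 0.5,
                   h = n - sizes[-length(sizes)] + 0.5, col = "grey40")
  invisible(run)
}

#' Consensus CDF curves, one per k
#' @param sweep a `consensus_sweep`.
#' @export
plot_consensus_cdf <- function(sweep) {
  stopifnot(inherits(sweep, "consensus_sweep"))
  ks <- sweep$k_range
  cols <- grDevices::hcl.colors(length(ks), "Dark 3")
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF",
                 main = "Consensus CDF by k")
  for (i in seq_along(ks)) {
    F <- consensus_cdf(sweep$runs[[i]])
    x <- seq(0, 1, by = 0.005)
    graphics::lines(x, F(x), col = cols[i], lwd = 1.5)
  }
  graphics::legend("bottomright", legend = paste0("k=", ks), col = cols,
                   lwd = 1.5, cex = 0.7, bty = "n")
  invisible(sweep)
}

#' PAC-versus-k curve with the selected k marked
#' @param profile a `pac_profile`.
#' @export
plot_pac <- function(profile) {
  stopifnot(inherits(profile, "pac_profile"))
  graphics::plot(profile$profile$k, profile$profile$pac, type = "b",
                 pch = 19, xlab = "k", ylab = "PAC",
                 ylim = c(0, max(1, profile$profile$pac)),
                 main = "Proportion of ambiguous clustering")
  graphics::abline(v = profile$selected_k, lty = 2, col = "red")
  invisible(profile)
}

#' Delta-area diagnostic plot
#' @param da a [delta_area()] data.frame.
#' @export
plot_delta_area <- function(da) {
  graphics::plot(da$k, da$delta, type = "b", pch = 19, xlab = "k",
                 ylab = "relative change in CDF area",
                 main = "Delta area under consensus CDF")
  invisible(da)
}

#' Item-consensus box plots per cluster
#' @param ic an [item_consensus()] result.
#' @export
plot_item_consensus <- function(ic) {
  stopifnot(inherits(ic, "item_consensus"))
  keep <- !is.na(ic$cluster)
  graphics::boxplot(value ~ cluster, data = ic[keep, ],
                    xlab = "cluster", ylab = "item consensus",
                    ylim = c(0, 1), col = "#c6dbef",
                    main = "Item consensus by cluster")
  invisible(ic)
}
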