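#' Plot a radial distribution function
#'
#' @param g [rdf] object.
#' @param reference optional second [rdf] drawn for comparison.
#' @return a ggplot object.
#' @export
plot_rdf <- function(g, reference = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- data.frame(r = g$r, g = g$g, which = g$pair)
  if (!is.null(reference))
    d <- rbind(d, data.frame(r = reference$r, g = reference$g,
                             which = paste0(reference$pair, " (reference)")))
  ggplot2::ggplot(d, ggplot2::aes(r, g, colour = which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r", y = "g(r)", colour = NULL)
}

#' Plot a pair potential
#'
#' @param pot `knot_potential`, `ckdg_params` or `potential_table`.
#' @param dr evaluation grid spacing (non-table inputs).
#' @return a ggplot object.
#' @export
plot_potential <- function(pot, dr = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- if (inherits(pot, "potential_table")) pot
         else tabulate_potential(pot, dr = if (is.null(dr)) {
           if (inherits(pot, "knot_potential")) pot$dr / 4 else pot$r_c / 400
         } else dr)
  d <- data.frame(r = tab$r, u = tab$u)
  d <- d[is.finite(d$u) & d$u < 10 * max(1, abs(min(d$u, na.rm = TRUE))), ]
  ggplot2::ggplot(d, ggplot2::aes(r, u)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r", y = "u(r)")
}
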