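#' Plot a free-energy profile
#'
#' Line plot of dG against z (distance along the bilayer normal), with the
#' leaflet planes marked and, when present, a per-bin standard-deviation
#' ribbon from [replicate_statistics()]. An optional second profile (e.g.
#' one read with [read_external_profile()]) is overlaid for comparison.
#'
#' @param x an `fe_profile`.
#' @param compare optional second `fe_profile` to overlay.
#' @param half_thickness leaflet-plane distance to mark (Angstrom; NULL to
#'   omit).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fe_profile <- function(x, compare = NULL, half_thickness = 20, ...) {
  ok <- !is.na(x$dg)
  ylim <- range(x$dg[ok],
                if (!is.null(compare)) compare$dg, na.rm = TRUE)
  if (!is.null(x$sd)) {
    ylim <- range(ylim, x$dg[ok] + x$sd[ok], x$dg[ok] - x$sd[ok],
                  na.rm = TRUE)
  }
  graphics::plot(x$z[ok], x$dg[ok], type = "l", lwd = 2, col = "firebrick",
                 xlab = "z [Å]", ylab = expression(Delta * G ~
                   "[kcal/mol]"), ylim = ylim, ...)
  if (!is.null(x$sd)) {
    up <- x$dg[ok] + x$sd[ok]
    lo <- x$dg[ok] - x$sd[ok]
    good <- !is.na(up) & !is.na(lo)
    graphics::polygon(c(x$z[ok][good], rev(x$z[ok][good])),
                      c(up[good], rev(lo[good])),
                      col = grDevices::adjustcolor("firebrick", 0.15),
                      border = NA)
  }
  if (!is.null(compare)) {
    okc <- !is.na(compare$dg)
    graphics::lines(compare$z[okc], compare$dg[okc], lwd = 2,
                    col = "black")
    graphics::legend("topleft", legend = c("engine", "external"),
                     col = c("firebrick", "black"), lwd = 2, bty = "n")
  }
  if (!is.null(half_thickness))
    graphics::abline(v = c(-half_thickness, half_thickness), lty = 3,
                     col = "grey40")
  graphics::abline(h = 0, lty = 3, col = "grey40")
  invisible(x)
}

#' Plot an agent trajectory
#'
#' The agent's height above the bilayer center against time, with the
#' leaflet planes marked.
#'
#' @param x a `trajectory`.
#' @param half_thickness leaflet-plane distance (Angstrom; NULL to omit).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory <- function(x, half_thickness = 20, ...) {
  graphics::plot(x$time * 1e12, x$z, type = "l", col = "steelblue",
                 xlab = "time [ps]", ylab = "z [Å]", ...)
  if (!is.null(half_thickness))
    graphics::abline(h = c(-half_thickness, 0, half_thickness), lty = 3,
                     col = "grey40")
  invisible(x)
}
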