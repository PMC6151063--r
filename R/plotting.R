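# Shaded orientation sectors of the standard single-angle plots (degrees).
SECTOR_BANDS <- list(
  ATR = list(c(0, 30), c(150, 180)),   # blue
  WTR = list(c(60, 120)),              # red
  oblique = list(c(30, 60), c(120, 150)) # unshaded
)

GRAPH_KINDS <- c("TIA", "SIA", "DV", "CI")

radial_limit <- function(r, kind) {
  top <- max(r, 0)
  if (kind == "CI") {
    # CI units: 0.5, 1, 2, 4, ... (doubling)
    lim <- 0.5
    while (lim < top) lim <- lim * 2
  } else {
    # diopters: 0.5 D steps
    lim <- max(0.5, ceiling(top / 0.5) * 0.5)
  }
  lim
}

#' Build the drawing specification for one standard graph
#'
#' Extracts the per-eye quantity for the requested graph -- the TIA, SIA or
#' DV vector, or the CI value placed at the eye's TIA axis (the intended
#' treatment meridian) -- computes the matching population summary, and
#' chooses a radial limit that covers every point (multiples of 0.5 D for
#' the vector graphs; 0.5, 1, 2, 4, ... for the CI graph). Eyes with an
#' undefined CI are excluded from the CI graph only.
#'
#' @param results An `astig_results` tibble from [analyze_eyes()].
#' @param kind One of `"TIA"`, `"SIA"`, `"DV"`, `"CI"`.
#' @return A list of class `astig_plot_spec` with elements `kind`, `points`
#'   (tibble `radius`/`axis`), `summary` (cohort summary, or CI summary for
#'   the CI graph), `radial_max`, and `title`.
#' @export
build_plot_spec <- function(results, kind = GRAPH_KINDS) {
  kind <- match.arg(kind)
  if (nrow(results) == 0L) stop("no eye results to plot")
  if (kind == "CI") {
    keep <- !is.na(results$ci)
    points <- tibble::tibble(radius = results$ci[keep],
                             axis = results$tia_axis[keep])
    summary <- summarize_ci(results$ci)
  } else {
    mag_col <- paste0(tolower(kind), "_mag")
    axis_col <- paste0(tolower(kind), "_axis")
    points <- tibble::tibble(radius = results[[mag_col]],
                             axis = results[[axis_col]])
    summary <- summarize_vectors(points$radius, points$axis)
  }
  spec <- list(
    kind = kind,
    points = points,
    summary = summary,
    radial_max = radial_limit(points$radius, kind),
    title = sprintf("%s (n = %d)", kind, nrow(points))
  )
  class(spec) <- "astig_plot_spec"
  spec
}

#' @export
print.astig_plot_spec <- function(x, ...) {
  cat(sprintf("Plot spec: %s, %d point(s), radial limit %g\n",
              x$kind, nrow(x$points), x$radial_max))
  invisible(x)
}

sector_wedge <- function(from, to, r, fill) {
  th <- seq(from, to, length.out = 60) * pi / 180
  ggplot2::annotate("polygon",
                    x = c(0, r * cos(th)), y = c(0, r * sin(th)),
                    fill = fill, alpha = 0.25, colour = NA)
}

callout_text <- function(spec) {
  s <- spec$summary
  if (spec$kind == "CI") {
    txt <- sprintf("geometric mean CI = %.2f\nn = %d", s$geometric_mean, s$n_defined)
    if (s$n_excluded > 0) {
      txt <- paste0(txt, sprintf("\nexcluded (undefined CI): %d", s$n_excluded))
    }
    txt
  } else {
    sprintf("X: %.2f ± %.2f D\nY: %.2f ± %.2f D\nvector mean: %.2f D @ %.0f°",
            s$mean_x, s$sd_x, s$mean_y, s$sd_y,
            s$vector_mean$magnitude, s$vector_mean$axis)
  }
}

#' Render one standard single-angle polar graph
#'
#' Draws the upper semicircle (axes run 0 degrees at the right to 180 at
#' the left, the full domain of single-angle astigmatism data) with the
#' standard fixed styling: blue shaded against-the-rule sectors (0--30 and
#' 150--180 degrees), a red with-the-rule sector (60--120), unshaded
#' oblique bands; each eye as a black radial line ending in a blue circle
#' marker; a red diamond at the vector mean on the TIA, SIA and DV graphs
#' (omitted on the CI graph, per reporting standards); a call-out box with
#' the X/Y means and standard deviations (or the geometric-mean CI); and a
#' numeric radial scale beneath the graph. Styling is fixed by design so
#' figures are comparable across studies.
#'
#' @param spec An `astig_plot_spec` from [build_plot_spec()].
#' @return A ggplot object.
#' @export
render_single_angle_plot <- function(spec) {
  stopifnot(inherits(spec, "astig_plot_spec"))
  if (any(spec$points$radius > spec$radial_max)) {
    stop("plot spec has points beyond its radial limit")
  }
  rmax <- spec$radial_max
  pts <- spec$points
  th <- pts$axis * pi / 180
  pts_xy <- tibble::tibble(x = pts$radius * cos(th), y = pts$radius * sin(th))

  ticks <- seq(0, rmax, length.out = 5)[-1]
  arc <- seq(0, pi, length.out = 181)
  spokes <- seq(0, 180, by = 30)

  p <- ggplot2::ggplot() +
    sector_wedge(0, 30, rmax, "blue") +
    sector_wedge(150, 180, rmax, "blue") +
    sector_wedge(60, 120, rmax, "red")
  # radial gridlines (concentric semicircles) and spokes
  for (r in ticks) {
    p <- p + ggplot2::annotate("path", x = r * cos(arc), y = r * sin(arc),
                               colour = "grey70", linewidth = 0.3)
  }
  for (s in spokes) {
    a <- s * pi / 180
    p <- p + ggplot2::annotate("segment", x = 0, y = 0,
                               xend = rmax * cos(a), yend = rmax * sin(a),
                               colour = "grey70", linewidth = 0.3)
  }
  # degree labels around the rim
  p <- p + ggplot2::annotate("text", x = 1.1 * rmax * cos(spokes * pi / 180),
                             y = 1.1 * rmax * sin(spokes * pi / 180),
                             label = paste0(spokes, "°"), size = 3.2)
  # per-eye vectors: black line, blue circle marker
  p <- p + ggplot2::annotate("segment", x = 0, y = 0,
                             xend = pts_xy$x, yend = pts_xy$y,
                             colour = "black", linewidth = 0.35) +
    ggplot2::annotate("point", x = pts_xy$x, y = pts_xy$y,
                      colour = "blue", size = 2, shape = 16)
  # vector mean as red diamond (never on the CI graph)
  if (spec$kind != "CI") {
    vm <- spec$summary$vector_mean
    a <- vm$axis * pi / 180
    p <- p + ggplot2::annotate("point", x = vm$magnitude * cos(a),
                               y = vm$magnitude * sin(a),
                               colour = "red", size = 4, shape = 18)
  }
  # radial scale beneath the graph
  unit_lab <- if (spec$kind == "CI") "" else " D"
  p <- p +
    ggplot2::annotate("text", x = ticks, y = -0.06 * rmax,
                      label = sprintf("%g%s", ticks, unit_lab), size = 3) +
    ggplot2::annotate("label", x = -1.24 * rmax, y = 1.24 * rmax,
                      label = callout_text(spec), hjust = 0, vjust = 1,
                      size = 3, label.size = 0.2) +
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25) * rmax,
                         ylim = c(-0.15, 1.25) * rmax, expand = FALSE) +
    ggplot2::labs(title = spec$title) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5, size = 12))
  p
}

#' Export rendered graphs as TIFF images
#'
#' Writes one TIFF per figure into a directory named after the data file's
#' stem, next to the data file (mirroring the convention of saving figures
#' into a folder with the same name and location as the source file), or
#' into `out_dir` if given. File names are deterministic (`TIA.tif`,
#' `SIA.tif`, ...); re-export overwrites in place.
#'
#' @param figures Named list of ggplot objects; names should be graph kinds.
#' @param source_path Path of the analyzed data file (used to derive the
#'   default output directory).
#' @param out_dir Optional output directory override.
#' @param dpi Raster resolution (default 300, high-resolution print
#'   quality).
#' @return Character vector of written file paths.
#' @export
export_figures <- function(figures, source_path, out_dir = NULL, dpi = 300) {
  if (length(figures) == 0L) stop("no figures to export")
  if (is.null(names(figures)) || any(names(figures) == "")) {
    stop("figures must be a named list (names become file stems)")
  }
  dir <- out_dir %||% file.path(dirname(source_path),
                                tools::file_path_sans_ext(basename(source_path)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create figure directory: ", dir)
  paths <- character(0)
  for (nm in names(figures)) {
    path <- file.path(dir, paste0(nm, ".tif"))
    ggplot2::ggsave(path, figures[[nm]], device = "tiff", dpi = dpi,
                    width = 6, height = 4.2, units = "in", bg = "white")
    paths <- c(paths, path)
  }
  paths
}
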