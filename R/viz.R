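#' Build a root-plot specification
#'
#' A root plot is a stacked bar chart arranged like the seedling itself:
#' one downward bar per root, one upward bar for the shoot, each bar stacked
#' as day-0 mean length plus the mean change over day 0-1 and day 1-2 (so
#' the stack height equals the day-2 mean). Bars follow anatomical order --
#' roots 2 and 3 flank root 1 and emerge first, later roots sit outermost --
#' with the shoot drawn upward at the centre.
#'
#' The spec is pure data (no graphics objects), so tests can assert geometry
#' without image comparison; render with [render_figure()].
#'
#' @param compiled a `compiled_condition`.
#' @param include_root6,root6_threshold root-6 rule controls.
#' @param order bar order, left to right (default anatomical:
#'   `root4, root2, root1, root3, root5, root6`).
#' @return an object of class `root_plot_spec`: list with `segments` (a
#'   data.frame of structure, x_position, direction, segment, value_mm,
#'   negative), `order`, `condition` and `genotype`.
#' @export
build_root_plot_spec <- function(compiled, include_root6 = NULL,
                                 root6_threshold = 3L, order = NULL) {
  stopifnot(inherits(compiled, "compiled_condition"))
  structures <- analysis_structures(compiled, compiled, include_root6,
                                    root6_threshold)
  roots <- setdiff(structures, "shoot")
  if (is.null(order)) {
    order <- intersect(c("root4", "root2", "root1", "root3", "root5", "root6"),
                       roots)
  }
  shoot_x <- match("root1", order)
  if (is.na(shoot_x)) shoot_x <- (length(order) + 1) / 2

  seg_names <- c("day0", "day0_1", "day1_2")
  rows <- list()
  for (s in structures) {
    means <- vapply(0:2, function(d) structure_mean(compiled, s, d)$mean_mm, 0)
    segs <- c(means[1L], diff(means))
    is_shoot <- s == "shoot"
    rows[[s]] <- data.frame(
      structure = s,
      x_position = if (is_shoot) shoot_x else match(s, order),
      direction = if (is_shoot) 1 else -1,
      segment = seg_names,
      value_mm = segs,
      negative = !is.na(segs) & segs < 0,
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    segments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    order = order,
    condition = compiled$condition[1L],
    genotype = compiled$genotype[1L]
  )
  class(out) <- "root_plot_spec"
  out
}

#' @export
print.root_plot_spec <- function(x, ...) {
  cat(sprintf("<root_plot_spec> %s %s: %d bars (%d roots down, shoot up)\n",
              x$genotype, x$condition,
              length(unique(x$segments$structure)), length(x$order)))
  invisible(x)
}

#' Build a difference-plot specification
#'
#' One facet per structure; within a facet, the WS - WW estimate at each day
#' with an error bar of plus/minus one standard error of the contrast.
#' Points are black where the contrast is significant at the table's alpha
#' and gray otherwise.
#'
#' @param diffs a `difference_table` from [summary_ws_vs_ww()].
#' @return an object of class `diff_plot_spec`: list with `points` (a
#'   data.frame of structure, day, estimate_mm, se_mm, significant, color)
#'   and `alpha`.
#' @export
build_difference_plot_spec <- function(diffs) {
  stopifnot(inherits(diffs, "difference_table"))
  pts <- data.frame(
    structure = diffs$structure, day = diffs$day,
    estimate_mm = diffs$estimate_mm, se_mm = diffs$se_mm,
    significant = diffs$significant,
    color = ifelse(diffs$significant, "black", "gray60"),
    stringsAsFactors = FALSE
  )
  out <- list(points = pts, alpha = attr(diffs, "alpha"))
  class(out) <- "diff_plot_spec"
  out
}

#' @export
print.diff_plot_spec <- function(x, ...) {
  cat(sprintf("<diff_plot_spec> %d facets, alpha = %g, %d significant point(s)\n",
              length(unique(x$points$structure)), x$alpha,
              sum(x$points$significant)))
  invisible(x)
}

# ggplot for a root_plot_spec; stacked signed bars built from explicit rects
# so negative increments can be drawn as marked overlays instead of being
# swallowed by position_stack
plot_root_spec <- function(spec) {
  seg <- spec$segments
  seg <- seg[!is.na(seg$value_mm), ]
  if (nrow(seg) == 0L) stop("empty root plot spec", call. = FALSE)
  seg$segment <- factor(seg$segment, levels = c("day0", "day0_1", "day1_2"))
  parts <- split(seg, seg$structure)
  rects <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$segment), ]
    top <- cumsum(d$value_mm)
    base <- c(0, top[-length(top)])
    d$ymin <- pmin(base, top) * d$direction
    d$ymax <- pmax(base, top) * d$direction
    d
  }))
  labels <- c(day0 = "day 0", day0_1 = "day 0-1", day1_2 = "day 1-2")
  ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = x_position - 0.4, xmax = x_position + 0.4,
      ymin = ymin, ymax = ymax, fill = segment
    ), colour = "grey25", linewidth = 0.2) +
    ggplot2::geom_rect(
      data = rects[rects$negative, , drop = FALSE],
      ggplot2::aes(xmin = x_position - 0.4,
                   xmax = x_position + 0.4,
                   ymin = ymin, ymax = ymax),
      fill = NA, colour = "red", linewidth = 0.5, linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(spec$order), labels = spec$order
    ) +
    ggplot2::scale_fill_manual(
      values = c(day0 = "#bdd7e7", day0_1 = "#6baed6", day1_2 = "#2171b5"),
      labels = labels, name = "growth"
    ) +
    ggplot2::labs(
      title = sprintf("%s (%s)", spec$condition, spec$genotype),
      x = NULL, y = "length (mm); roots down, shoot up"
    ) +
    ggplot2::theme_minimal()
}

plot_diff_spec <- function(spec) {
  pts <- spec$points[!is.na(spec$points$estimate_mm), , drop = FALSE]
  if (nrow(pts) == 0L) stop("empty difference plot spec", call. = FALSE)
  pts$structure <- factor(pts$structure,
                          levels = unique(spec$points$structure))
  ggplot2::ggplot(pts, ggplot2::aes(x = day, y = estimate_mm)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = estimate_mm - se_mm,
      ymax = estimate_mm + se_mm
    ), width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = color), size = 2.5) +
    ggplot2::scale_colour_identity() +
    ggplot2::facet_wrap(~structure) +
    ggplot2::scale_x_continuous(breaks = 0:2) +
    ggplot2::labs(
      title = sprintf("WS - WW length difference (black: p < %g)", spec$alpha),
      x = "day", y = "WS - WW (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Render a plot specification to a figure file
#'
#' @param spec a `root_plot_spec` or `diff_plot_spec`.
#' @param path output file path.
#' @param format `"pdf"` (vector, default) or `"png"`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_figure <- function(spec, path, format = c("pdf", "png"),
                          width = 7, height = 5) {
  format <- match.arg(format)
  p <- if (inherits(spec, "root_plot_spec")) {
    plot_root_spec(spec)
  } else if (inherits(spec, "diff_plot_spec")) {
    plot_diff_spec(spec)
  } else {
    stop("spec must be a root_plot_spec or diff_plot_spec", call. = FALSE)
  }
  write_figure(p, path, format, width, height)
}

#' Render the combined three-panel report figure
#'
#' Lays out the WW root plot (A), WS root plot (B) and the difference plot
#' (C) on a single labelled vector page, the bundle a full analysis exports.
#'
#' @param ww_spec,ws_spec `root_plot_spec`s for the two conditions.
#' @param diff_spec a `diff_plot_spec`.
#' @param path output file path.
#' @param format `"pdf"` or `"png"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(ww_spec, ws_spec, diff_spec, path,
                          format = c("pdf", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(ww_spec, "root_plot_spec"),
            inherits(ws_spec, "root_plot_spec"),
            inherits(diff_spec, "diff_plot_spec"))
  top <- patchwork::wrap_plots(plot_root_spec(ww_spec),
                               plot_root_spec(ws_spec), ncol = 2)
  p <- patchwork::wrap_plots(top, plot_diff_spec(diff_spec), ncol = 1) +
    patchwork::plot_annotation(tag_levels = "A")
  write_figure(p, path, format, width = 10, height = 9)
}

write_figure <- function(p, path, format, width, height) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    if (format == "pdf") {
      grDevices::pdf(path, width = width, height = height,
                     useDingbats = FALSE, onefile = TRUE)
    } else {
      grDevices::png(path, width = width * 100, height = height * 100,
                     res = 100)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
    TRUE
  }, error = function(e) {
    stop("failed to render figure to ", sQuote(path), ": ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}
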