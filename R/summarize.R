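#' Summarize a results table by pathway group
#'
#' Computes each protein's extremum change, assigns proteins to every
#' pathway group listing them (overlap members contribute to all their
#' groups), and calls each group activated when the mean extremum change
#' exceeds +`call_threshold` percentage points, inactivated below
#' −`call_threshold`, and mixed otherwise. The default threshold reuses the
#' 5-point minimal-change bound.
#'
#' @param results Results data.frame (see [profile_experiment()]).
#' @param registry A `panel_registry`.
#' @param call_threshold Activation-call threshold, percentage points.
#' @return Data.frame `(group, n_members, mean_extremum_delta, call)` in
#'   category order, with per-group member deltas in the `members`
#'   attribute. Unresolvable result proteins are reported as an error.
#' @export
group_profile <- function(results, registry, call_threshold = 5) {
  stopifnot(inherits(registry, "panel_registry"))
  if (nrow(results) == 0L) stop("empty results table")
  unresolved <- setdiff(unique(results$protein), registry$records$name)
  if (length(unresolved)) {
    stop("protein(s) not in the registry: ",
         paste(unresolved, collapse = ", "))
  }
  ext <- extremum_table(results, registry)
  members <- list()
  rows <- lapply(names(registry$pathway_groups), function(g) {
    m <- intersect(registry$pathway_groups[[g]], ext$protein)
    if (length(m) == 0L) return(NULL)
    deltas <- ext$delta_percent[match(m, ext$protein)]
    members[[g]] <<- setNames(deltas, m)
    mean_d <- mean(deltas)
    call <- if (mean_d > call_threshold) "activated"
            else if (mean_d < -call_threshold) "inactivated" else "mixed"
    data.frame(group = g, n_members = length(m),
               mean_extremum_delta = mean_d, call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Build a star-plot specification
#'
#' Collects the per-protein series to draw on a circular (radar) plot: one
#' radial axis per protein, ordered by pathway group then registry order,
#' the untreated-control reference ring fixed at 100%, and either one
#' closed polygon per timepoint (default) or a single extremum-only
#' series. Proteins with undefined ratios at a timepoint are dropped with
#' a message.
#'
#' @param results Results data.frame.
#' @param registry A `panel_registry`.
#' @param proteins Proteins to include; default the representative subset.
#' @param mode `"timepoints"` (one series per timepoint) or `"extremum"`
#'   (single series of 100 + extremum delta).
#' @return A `star_plot_spec`: list with `labels`, `values` (matrix,
#'   proteins × series), `series`, `reference` (100) and `rmax` (radial
#'   maximum, 10% above the largest value).
#' @export
star_plot_spec <- function(results, registry,
                           proteins = representative_proteins(registry),
                           mode = c("timepoints", "extremum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "panel_registry"))
  present <- intersect(proteins, unique(results$protein))
  dropped <- setdiff(proteins, present)
  if (length(dropped)) {
    message("star plot: dropping ", length(dropped),
            " protein(s) without profiled ratios")
  }
  if (length(present) < 3L) {
    stop("a star plot needs >= 3 proteins (have ", length(present), ")")
  }
  # order: pathway group, then registry order within group, once per protein
  ordered <- character(0)
  for (g in names(registry$pathway_groups)) {
    m <- intersect(registry$pathway_groups[[g]], present)
    ordered <- c(ordered, setdiff(m, ordered))
  }
  ordered <- c(ordered, setdiff(present, ordered))

  if (mode == "timepoints") {
    series <- sort(unique(results$timepoint_h))
    values <- vapply(series, function(tp) {
      idx <- match(paste(ordered, tp),
                   paste(results$protein, results$timepoint_h))
      results$ratio_percent[idx]
    }, numeric(length(ordered)))
    colnames(values) <- paste0(series, " h")
  } else {
    ext <- extremum_table(results[results$protein %in% ordered, ], registry)
    values <- matrix(100 + ext$delta_percent[match(ordered, ext$protein)],
                     ncol = 1, dimnames = list(NULL, "extremum"))
  }
  keep <- stats::complete.cases(values)
  if (any(!keep)) {
    message("star plot: dropping ", sum(!keep),
            " protein(s) with missing timepoints")
    ordered <- ordered[keep]
    values <- values[keep, , drop = FALSE]
  }
  if (any(values <= 0)) stop("star-plot values must be > 0")
  structure(list(labels = ordered, values = values,
                 series = colnames(values), reference = 100,
                 rmax = 1.1 * max(values, 100)),
            class = "star_plot_spec")
}

# shared deterministic theme for both figure styles
iphplc_theme <- function() {
  ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "bottom",
                   panel.grid.minor = ggplot2::element_blank())
}

save_plot <- function(plot, path, width, height, meta) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    stop("unsupported plot format '", ext, "' (use .svg or .png)")
  }
  on.exit(grDevices::dev.off())
  print(plot)
  # sidecar metadata for structural inspection without parsing the image
  writeLines(sprintf("%s: %s", names(meta),
                     vapply(meta, paste, character(1), collapse = ",")),
             paste0(path, ".meta.txt"))
  invisible(path)
}

#' Render a per-group expression line graph
#'
#' One polyline per protein against culture time (hours), percent ratio on
#' the y axis, and the untreated-control reference line at 100%. When
#' batch-rendering several groups pass a common `ylim` so all graphs share
#' one scale; [render_line_graphs()] does this automatically.
#'
#' @param results Results data.frame, typically filtered to one group.
#' @param path Output `.svg` or `.png`; a `<path>.meta.txt` sidecar records
#'   the series count and y-limits.
#' @param title Plot title.
#' @param ylim Optional shared y-range, percent.
#' @return The ggplot object, invisibly; the file and sidecar are written.
#' @export
render_line_graph <- function(results, path, title = NULL, ylim = NULL) {
  if (nrow(results) == 0L) stop("no rows to plot")
  df <- data.frame(protein = results$protein,
                   timepoint_h = results$timepoint_h,
                   ratio = results$ratio_percent)
  ylim <- ylim %||% range(c(df$ratio, 100))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_h,
                                        y = .data$ratio,
                                        colour = .data$protein)) +
    ggplot2::geom_hline(yintercept = 100, linewidth = 0.8,
                        colour = "black") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$timepoint_h))) +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(x = "culture time (h)", y = "expression ratio (%)",
                  title = title, colour = NULL) +
    iphplc_theme()
  save_plot(p, path, width = 5, height = 4,
            meta = list(kind = "line", n_series = length(unique(df$protein)),
                        ylim_lo = format(ylim[1]), ylim_hi = format(ylim[2])))
  invisible(p)
}

#' Batch-render line graphs for several groups on one shared scale
#'
#' @param results Results data.frame.
#' @param registry A `panel_registry`.
#' @param dir Output directory.
#' @param groups Pathway groups to render; default all with profiled
#'   members.
#' @param format `"svg"` or `"png"`.
#' @return Named character vector of written paths, invisibly.
#' @export
render_line_graphs <- function(results, registry, dir,
                               groups = names(registry$pathway_groups),
                               format = c("svg", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ylim <- range(c(results$ratio_percent, 100))
  paths <- character(0)
  for (g in groups) {
    sub <- results[results$protein %in% registry$pathway_groups[[g]], ]
    if (nrow(sub) == 0L) next
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(g))
    path <- file.path(dir, paste0(slug, ".", format))
    render_line_graph(sub, path, title = g, ylim = ylim)
    paths[g] <- path
  }
  invisible(paths)
}

#' Render a circular star plot
#'
#' Radial axes in registry order (grouped by pathway), one closed polygon
#' per series, and the untreated-control reference ring at 100%; values
#' below 100 fall inside the ring. The radial scale is linear in percent
#' with its maximum 10% above the largest plotted value, recorded in the
#' sidecar metadata.
#'
#' @param spec A [star_plot_spec()].
#' @param path Output `.svg` or `.png`.
#' @param title Plot title.
#' @return The ggplot object, invisibly.
#' @export
render_star_plot <- function(spec, path, title = NULL) {
  stopifnot(inherits(spec, "star_plot_spec"))
  n <- length(spec$labels)
  if (n < 3L) stop("a star plot needs >= 3 proteins")
  long <- do.call(rbind, lapply(seq_along(spec$series), function(j) {
    data.frame(axis = seq_len(n), protein = spec$labels,
               series = spec$series[j], value = spec$values[, j])
  }))
  # close the polygons by repeating the first axis at position n + 1
  first <- long[long$axis == 1L, ]
  first$axis <- n + 1L
  long <- rbind(long, first)
  ring <- data.frame(axis = c(seq_len(n), n + 1L), value = spec$reference)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$axis, y = .data$value,
                                          colour = .data$series,
                                          group = .data$series)) +
    ggplot2::geom_line(data = ring,
                       ggplot2::aes(x = .data$axis, y = .data$value),
                       inherit.aes = FALSE, colour = "black",
                       linewidth = 0.9) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_continuous(breaks = seq_len(n), labels = spec$labels,
                                limits = c(1, n + 1L)) +
    ggplot2::scale_y_continuous(limits = c(0, spec$rmax)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::labs(x = NULL, y = "expression ratio (%)", title = title,
                  colour = NULL) +
    iphplc_theme() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 4))
  save_plot(p, path, width = 8, height = 8,
            meta = list(kind = "star", n_axes = n,
                        series = spec$series,
                        reference = format(spec$reference),
                        rmax = format(spec$rmax)))
  invisible(p)
}
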