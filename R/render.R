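#' Run and graphics options
#'
#' Central option set governing the pipeline and figure geometry. Option
#' names follow the command-line surface (see [cli_main()]); each value
#' here is the default used when the corresponding flag is absent.
#'
#' Window sizing: exactly one of `scale_factor` (fixed window length in
#' bp) and `auto_scale_factor` (maximum picture height in px from which
#' the window length is derived) governs the window size. If both are
#' given `scale_factor` wins with a warning; if neither, windows are
#' auto-sized for a 1000 px high picture.
#'
#' @param ... Named options overriding the defaults below.
#' @return Named list of options.
#' @section Options:
#' \describe{
#'   \item{input}{GFF path(s).}
#'   \item{region_file}{optional BED of regions to plot.}
#'   \item{output_img_name}{output basename; writes `<name>.svg` and
#'     `<name>.csv`.}
#'   \item{type_to_draw}{type spec string, e.g.
#'     `"gene = both = 4;CDS = fused = 10"` (see [parse_type_spec()]).}
#'   \item{colour_scale}{global colour-scale id (default 1).}
#'   \item{scale_factor}{window length in bp.}
#'   \item{auto_scale_factor}{maximum picture height in px for auto
#'     window sizing.}
#'   \item{rounding_method}{`"floor"` (default) or `"ceil"`.}
#'   \item{gc}{colour-scale id for a GC% track (requires sequence in the
#'     GFF `##FASTA` section); `NULL` disables the track.}
#'   \item{title}{picture title.}
#'   \item{win_size}{picture height in px; fixes the drawn height
#'     without changing the window length.}
#'   \item{show_scale}{maximum number of ruler ticks (0 hides the
#'     ruler; default 10).}
#'   \item{strand_width, strand_space, space_chr}{column geometry in px
#'     (defaults 20, 10, 30).}
#'   \item{lmargin, rmargin, tmargin, bmargin}{margins in px (50, 20,
#'     20, 20).}
#'   \item{background}{background colour, name or hex (default white).}
#'   \item{label_strand_rotation}{track-label rotation in degrees.}
#'   \item{ft_family, ft_size}{font family and size (Helvetica, 12).}
#'   \item{legend}{draw a legend block per colour scale used (default
#'     TRUE).}
#'   \item{scale_file}{optional user colour-scale definition file.}
#'   \item{force}{skip the interactive picture-size confirmation.}
#'   \item{verbose}{per-stage progress logging.}
#' }
#' @export
dm_options <- function(...) {
  opts <- list(
    input = NULL, region_file = NULL, output_img_name = NULL,
    type_to_draw = NULL,
    colour_scale = 1L, scale_factor = NULL, auto_scale_factor = NULL,
    rounding_method = "floor", gc = NULL,
    title = NULL, win_size = NULL, show_scale = 10L,
    strand_width = 20, strand_space = 10, space_chr = 30,
    lmargin = 50, rmargin = 20, tmargin = 20, bmargin = 20,
    background = "white", label_strand_rotation = 0,
    ft_family = "Helvetica", ft_size = 12,
    legend = TRUE, scale_file = NULL, force = FALSE, verbose = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(opts))
  if (length(unknown)) {
    cd_stop("unknown option(s): ", paste(unknown, collapse = ", "))
  }
  opts[names(over)] <- over
  opts
}

# fixed vertical space around the density columns
vertical_chrome <- function(opts) {
  title_h <- if (!is.null(opts$title) && nzchar(opts$title))
    2 * opts$ft_size else 0
  seqid_h <- opts$ft_size + 8
  label_h <- 70
  opts$tmargin + opts$bmargin + title_h + seqid_h + label_h
}

#' Ruler tick positions for a chromosome scale
#'
#' Tick spacing is the smallest value in the 1-2-5 decade series
#' (1, 2, 5, 10, 20, 50, ... bp) giving at most `max_ticks` ticks,
#' starting at 0. Labels are in Mbp.
#'
#' @param seq_length Span to graduate, in bp.
#' @param max_ticks Maximum number of ticks (>= 2).
#' @return Data frame with columns `bp`, `label`.
#' @examples
#' ruler_ticks(1e7, 6)
#' @export
ruler_ticks <- function(seq_length, max_ticks) {
  if (max_ticks < 2) cd_stop("show_scale needs at least 2 ticks")
  series <- as.vector(outer(c(1, 2, 5), 10^(0:12)))
  s <- series[which(floor(seq_length / series) + 1 <= max_ticks)[1L]]
  bp <- seq(0, seq_length, by = s)
  if (length(bp) < 2) {
    # spacing overshot the span; keep 0 plus the largest round position
    bp <- c(0, max(series[series <= seq_length]))
  }
  data.frame(bp = bp, label = fmt_px(bp / 1e6))
}

#' Compute the figure geometry
#'
#' Pure function of the tracks and options: chromosomes are drawn as
#' vertical columns laid out left to right, one sub-column of
#' `strand_width` px per density track (separated by `strand_space` px,
#' chromosomes by `space_chr` px), windows stacked top to bottom with the
#' scale in Mbp. When `win_size` is set the cell height is chosen so the
#' tallest chromosome fills the available height; otherwise each window
#' is 1 px tall.
#'
#' @param tracks List of `density_track`s (all sharing one nominal window
#'   size).
#' @param opts Options from [dm_options()].
#' @param window_size Nominal window length in bp.
#' @return A layout list: image dimensions, cell geometry, per-track
#'   rectangles (`rects`), ruler ticks, title/legend anchors.
#' @export
compute_layout <- function(tracks, opts = dm_options(),
                           window_size = NULL) {
  if (!length(tracks)) cd_stop("no density tracks to lay out")
  window_size <- window_size %||%
    max(vapply(tracks, function(t) t$windows$span[1L], numeric(1)))

  unit <- vapply(tracks, function(t) t$unit %||% t$seqid, "")
  units <- unique(unit)

  spans <- vapply(tracks, function(t) sum(t$windows$span), numeric(1))
  max_span <- max(spans)
  max_cells <- max_span / window_size  # fractional cells allowed

  title_h <- if (!is.null(opts$title) && nzchar(opts$title))
    2 * opts$ft_size else 0
  seqid_h <- opts$ft_size + 8
  label_h <- 70

  if (!is.null(opts$win_size)) {
    avail <- opts$win_size - vertical_chrome(opts)
    if (avail <= 0) cd_stop("win_size ", opts$win_size,
                            "px is smaller than the fixed vertical chrome")
    cell_h <- avail / max_cells
  } else {
    cell_h <- 1
  }
  px_per_bp <- cell_h / window_size

  show_ruler <- !is.null(opts$show_scale) && opts$show_scale >= 2
  ruler_w <- if (show_ruler) 45 else 0
  y0 <- opts$tmargin + title_h + seqid_h

  rects <- vector("list", length(tracks))
  unit_x0 <- numeric(length(units))
  x <- opts$lmargin + ruler_w
  for (ui in seq_along(units)) {
    unit_x0[ui] <- x
    idx <- which(unit == units[ui])
    for (j in seq_along(idx)) {
      t <- tracks[[idx[j]]]
      offset <- t$windows$start[1L] - 1
      rects[[idx[j]]] <- data.frame(
        track_idx = idx[j], unit = units[ui], seqid = t$seqid,
        ftype = t$ftype, track = t$track,
        x = x, y = y0,
        width = opts$strand_width,
        height = (sum(t$windows$span)) * px_per_bp,
        bp_offset = offset,
        stringsAsFactors = FALSE
      )
      x <- x + opts$strand_width +
        if (j < length(idx)) opts$strand_space else 0
    }
    if (ui < length(units)) x <- x + opts$space_chr
  }
  rects <- do.call(rbind, rects)

  legend_w <- if (isTRUE(opts$legend)) 130 else 0
  image_width <- x + legend_w + opts$rmargin
  image_height <- y0 + max_cells * cell_h + label_h + opts$bmargin

  ticks <- NULL
  if (show_ruler) {
    ticks <- ruler_ticks(max_span, opts$show_scale)
    ticks$y <- y0 + ticks$bp * px_per_bp
    ticks <- ticks[ticks$y <= y0 + max_cells * cell_h + 1e-9, , drop = FALSE]
  }

  list(
    image_width = image_width, image_height = image_height,
    margins = list(left = opts$lmargin, right = opts$rmargin,
                   top = opts$tmargin, bottom = opts$bmargin),
    window_size = window_size, cell_height = cell_h,
    px_per_bp = px_per_bp, y0 = y0, title_h = title_h,
    seqid_h = seqid_h, label_h = label_h,
    ruler_x = opts$lmargin + ruler_w - 8, show_ruler = show_ruler,
    units = data.frame(unit = units, x0 = unit_x0,
                       stringsAsFactors = FALSE),
    rects = rects, ticks = ticks,
    legend_x = if (legend_w > 0) x else NA_real_
  )
}

#' Render the density figure as an SVG document
#'
#' Deterministic: byte-identical output for identical tracks, catalog and
#' options. One `<rect class="density-cell">` per (track, window) cell,
#' coloured through the track's colour scale (`scale_id` on the track,
#' falling back to the global `colour_scale`; GC% tracks use the `gc`
#' scale id).
#'
#' @param layout Layout from [compute_layout()].
#' @param tracks The same list of `density_track`s.
#' @param catalog Colour-scale catalog ([load_colour_scales()]).
#' @param opts Options from [dm_options()].
#' @return Character scalar: the SVG document.
#' @export
render_svg <- function(layout, tracks, catalog = load_colour_scales(),
                       opts = dm_options()) {
  bg <- normalize_colour(opts$background)
  ft <- xml_escape(opts$ft_family)
  fs <- opts$ft_size
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "version=\"1.1\" width=\"%s\" height=\"%s\">"),
            fmt_px(layout$image_width), fmt_px(layout$image_height)),
    sprintf("<rect class=\"background\" x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
            fmt_px(layout$image_width), fmt_px(layout$image_height), bg)
  )

  if (layout$title_h > 0) {
    out <- c(out, sprintf(
      "<text class=\"title\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-family=\"%s\" font-size=\"%s\">%s</text>",
      fmt_px(layout$image_width / 2), fmt_px(opts$tmargin + fs * 1.2),
      ft, fmt_px(fs * 1.3), xml_escape(opts$title)))
  }

  # seqid labels above each chromosome group
  r <- layout$rects
  for (u in seq_len(nrow(layout$units))) {
    uu <- layout$units$unit[u]
    ur <- r[r$unit == uu, , drop = FALSE]
    cx <- (min(ur$x) + max(ur$x + ur$width)) / 2
    out <- c(out, sprintf(
      "<text class=\"seqid-label\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-family=\"%s\" font-size=\"%s\">%s</text>",
      fmt_px(cx), fmt_px(layout$y0 - 6), ft, fmt_px(fs),
      xml_escape(uu)))
  }

  scale_cache <- list()
  used_scales <- integer()
  for (i in seq_len(nrow(r))) {
    t <- tracks[[r$track_idx[i]]]
    sid <- t$scale_id
    if (is.na(sid)) sid <- if (t$ftype == "GC%") opts$gc %||%
        opts$colour_scale else opts$colour_scale
    key <- as.character(sid)
    if (is.null(scale_cache[[key]])) {
      scale_cache[[key]] <- get_scale(sid, catalog)
      used_scales <- c(used_scales, as.integer(sid))
    }
    cols <- map_density(t$values, scale_cache[[key]])
    y <- r$y[i] + (t$windows$start - 1 - r$bp_offset[i]) * layout$px_per_bp
    h <- t$windows$span * layout$px_per_bp
    out <- c(out, sprintf("<g class=\"track\" data-seqid=\"%s\" data-ftype=\"%s\" data-strand=\"%s\">",
                          xml_escape(t$seqid), xml_escape(t$ftype),
                          t$track))
    out <- c(out, sprintf(
      "<rect class=\"density-cell\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
      fmt_px(r$x[i]), vapply(y, fmt_px, ""), fmt_px(r$width[i]),
      vapply(h, fmt_px, ""), cols))
    out <- c(out, sprintf(
      "<rect class=\"track-frame\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"none\" stroke=\"#000000\" stroke-width=\"0.5\"/>",
      fmt_px(r$x[i]), fmt_px(r$y[i]), fmt_px(r$width[i]),
      fmt_px(r$height[i])))
    # rotated track label below the column
    lx <- r$x[i] + r$width[i] / 2
    ly <- layout$y0 + max(r$height) + fs + 4
    lab <- paste0(t$ftype, " (", t$track, ")")
    out <- c(out, sprintf(
      "<text class=\"track-label\" x=\"%s\" y=\"%s\" text-anchor=\"start\" font-family=\"%s\" font-size=\"%s\" transform=\"rotate(%s %s %s)\">%s</text>",
      fmt_px(lx), fmt_px(ly), ft, fmt_px(fs * 0.85),
      fmt_px(opts$label_strand_rotation), fmt_px(lx), fmt_px(ly),
      xml_escape(lab)))
    out <- c(out, "</g>")
  }

  if (layout$show_ruler && !is.null(layout$ticks) && nrow(layout$ticks)) {
    tk <- layout$ticks
    rx <- layout$ruler_x
    out <- c(out, sprintf(
      "<line class=\"ruler\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\" stroke-width=\"1\"/>",
      fmt_px(rx), fmt_px(min(tk$y)), fmt_px(rx), fmt_px(max(tk$y))))
    out <- c(out, sprintf(
      "<line class=\"ruler-tick\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\" stroke-width=\"1\"/>",
      fmt_px(rx - 4), vapply(tk$y, fmt_px, ""), fmt_px(rx),
      vapply(tk$y, fmt_px, "")))
    out <- c(out, sprintf(
      "<text class=\"ruler-label\" x=\"%s\" y=\"%s\" text-anchor=\"end\" font-family=\"%s\" font-size=\"%s\">%s</text>",
      fmt_px(rx - 6), vapply(tk$y + fs * 0.35, fmt_px, ""), ft,
      fmt_px(fs * 0.8), tk$label))
    out <- c(out, sprintf(
      "<text class=\"ruler-unit\" x=\"%s\" y=\"%s\" text-anchor=\"end\" font-family=\"%s\" font-size=\"%s\">Mbp</text>",
      fmt_px(rx), fmt_px(layout$y0 - 6), ft, fmt_px(fs * 0.8)))
  }

  if (!is.na(layout$legend_x)) {
    ly <- layout$y0
    for (sid in used_scales) {
      sc <- scale_cache[[as.character(sid)]]
      out <- c(out, sprintf(
        "<text class=\"legend-title\" x=\"%s\" y=\"%s\" font-family=\"%s\" font-size=\"%s\">scale %s: %s</text>",
        fmt_px(layout$legend_x + 4), fmt_px(ly + fs * 0.8), ft,
        fmt_px(fs * 0.8), sid, xml_escape(sc$name)))
      ly <- ly + fs
      for (b in seq_len(nrow(sc$bins))) {
        out <- c(out, sprintf(
          "<rect class=\"legend-swatch\" x=\"%s\" y=\"%s\" width=\"12\" height=\"8\" fill=\"%s\"/>",
          fmt_px(layout$legend_x + 4), fmt_px(ly), sc$bins$colour[b]))
        lab <- if (sc$bins$low[b] == sc$bins$high[b])
          sprintf("%d%%", sc$bins$low[b])
        else sprintf("%d-%d%%", sc$bins$low[b], sc$bins$high[b])
        out <- c(out, sprintf(
          "<text class=\"legend-label\" x=\"%s\" y=\"%s\" font-family=\"%s\" font-size=\"%s\">%s</text>",
          fmt_px(layout$legend_x + 20), fmt_px(ly + 7), ft,
          fmt_px(fs * 0.65), lab))
        ly <- ly + 9
      }
      ly <- ly + fs
    }
  }

  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}
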