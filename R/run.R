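#' Run the full density-map pipeline
#'
#' Orchestrates: GFF parsing and type filtering, optional BED region
#' clipping, per-type/per-strand-track interval merging, window tiling,
#' density computation (plus an optional GC% track), density-table
#' writing, layout computation, picture-size confirmation and SVG
#' writing. Outputs are `<output_img_name>.svg` and
#' `<output_img_name>.csv`.
#'
#' The computed picture size is always reported. In an interactive
#' session the user is asked to confirm it before the image is written
#' (`force = TRUE` auto-answers yes); non-interactive runs proceed after
#' reporting.
#'
#' @param opts Options from [dm_options()]; `input`, `output_img_name`
#'   and `type_to_draw` are mandatory.
#' @return Invisibly, a list with `tracks`, `layout`, `window_size`,
#'   `csv_path` and `svg_path`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(generate_gff_fixture(seed = 1, n_seqs = 1,
#'                                 seq_length = 50000, n_features = 40,
#'                                 types = "gene"), gff)
#' out <- file.path(tempdir(), "example")
#' res <- densitymap_run(dm_options(input = gff, output_img_name = out,
#'                                  type_to_draw = "gene = fused",
#'                                  scale_factor = 5000))
#' res$window_size
#' @export
densitymap_run <- function(opts) {
  for (req in c("input", "output_img_name", "type_to_draw")) {
    if (is.null(opts[[req]])) cd_stop("missing mandatory option: ", req)
  }
  log_v <- function(...) if (isTRUE(opts$verbose)) message("[chromdens] ", ...)

  catalog <- load_colour_scales(opts$scale_file)
  specs <- parse_type_spec(opts$type_to_draw)
  get_scale(opts$colour_scale, catalog)  # validate early
  for (sid in stats::na.omit(specs$scale_id)) get_scale(sid, catalog)
  if (!is.null(opts$gc)) get_scale(opts$gc, catalog)
  if (!(opts$rounding_method %in% c("floor", "ceil"))) {
    cd_stop("rounding_method must be 'floor' or 'ceil', got '",
            opts$rounding_method, "'")
  }

  ann <- read_gff_many(opts$input, types = specs$ftype)
  log_v(nrow(ann$features), " features of ",
        length(unique(ann$features$ftype)), " type(s) on ",
        nrow(ann$sequences), " sequence(s)")

  # plot units: whole chromosomes, or BED regions when given
  if (!is.null(opts$region_file)) {
    reg <- read_bed_regions(opts$region_file)
    unknown <- setdiff(reg$seqid, ann$sequences$seqid)
    if (length(unknown)) {
      cd_stop("region file names sequences absent from the annotation: ",
              paste(unknown, collapse = ", "))
    }
    units <- data.frame(
      seqid = reg$seqid, start = reg$start, end = reg$end,
      label = paste0(reg$seqid, ":", format(reg$start, scientific = FALSE,
                                            trim = TRUE),
                     "-", format(reg$end, scientific = FALSE, trim = TRUE)),
      stringsAsFactors = FALSE)
  } else {
    units <- data.frame(seqid = ann$sequences$seqid, start = 1,
                        end = ann$sequences$length,
                        label = ann$sequences$seqid,
                        stringsAsFactors = FALSE)
  }
  spans <- units$end - units$start + 1

  # window size: fixed (-sc) beats automatic (-a); default: auto, 1000 px
  W <- opts$scale_factor
  if (!is.null(W) && !is.null(opts$auto_scale_factor)) {
    cd_warn("both scale_factor and auto_scale_factor given; ",
            "using the fixed window size ", W)
  }
  if (is.null(W)) {
    max_h <- opts$auto_scale_factor %||% 1000
    W <- auto_window_size(spans, max_h, opts)
  }
  log_v("window size: ", W, " bp")

  tracks <- list()
  for (u in seq_len(nrow(units))) {
    seqrec <- ann$sequences[ann$sequences$seqid == units$seqid[u], ]
    region <- if (units$start[u] == 1 && units$end[u] == seqrec$length)
      NULL else list(start = units$start[u], end = units$end[u])
    windows <- tile_windows(seqrec$length, W, region)
    for (s in seq_len(nrow(specs))) {
      feats <- ann$features[ann$features$seqid == units$seqid[u] &
                              ann$features$ftype == specs$ftype[s], ,
                            drop = FALSE]
      strand_tracks <- split_strand_tracks(feats, specs$mode[s])
      for (trk in names(strand_tracks)) {
        tf <- strand_tracks[[trk]]
        tr <- density_track(merge_intervals(tf$start, tf$end), windows,
                            rounding = opts$rounding_method,
                            seqid = units$seqid[u], ftype = specs$ftype[s],
                            track = trk, scale_id = specs$scale_id[s])
        tr$unit <- units$label[u]
        tracks[[length(tracks) + 1L]] <- tr
        log_v(units$label[u], " ", specs$ftype[s], " [", trk, "]: ",
              nrow(tf), " features, ", nrow(windows), " windows")
      }
    }
    if (!is.null(opts$gc)) {
      tr <- gc_track(seqrec$sequence, windows,
                     rounding = opts$rounding_method,
                     seqid = units$seqid[u], scale_id = opts$gc)
      tr$unit <- units$label[u]
      tracks[[length(tracks) + 1L]] <- tr
      log_v(units$label[u], " GC%: ", nrow(windows), " windows")
    }
  }

  csv_path <- paste0(opts$output_img_name, ".csv")
  write_density_csv(tracks, csv_path, window_size = W)
  log_v("density table: ", csv_path)

  layout <- compute_layout(tracks, opts, window_size = W)
  message("Picture size: ", fmt_px(layout$image_width), " x ",
          fmt_px(layout$image_height), " px")
  if (!isTRUE(opts$force) && interactive()) {
    ans <- readline("Proceed with this picture size? [y/N] ")
    if (!tolower(trimws(ans)) %in% c("y", "yes")) {
      unlink(csv_path)
      cd_stop("aborted at picture-size confirmation")
    }
  }

  svg_path <- paste0(opts$output_img_name, ".svg")
  svg <- render_svg(layout, tracks, catalog, opts)
  con <- file(svg_path, open = "wb")
  writeLines(svg, con, sep = "")
  close(con)
  log_v("image: ", svg_path)

  invisible(list(tracks = tracks, layout = layout, window_size = W,
                 csv_path = csv_path, svg_path = svg_path))
}
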