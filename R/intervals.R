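#' Split features into strand tracks
#'
#' Each strand mode yields a fixed number of density tracks per feature
#' type: `minus` and `plus` one each, `both` two (minus then plus),
#' `fused` one combining both strands, and `all` three (minus, plus,
#' fused). Unstranded features (GFF strand `.`, `?` or empty) contribute
#' only to fused tracks; when a minus/plus/both mode would silently drop
#' them a warning is raised.
#'
#' @param features Data frame with at least a `strand` column
#'   (`"plus"`/`"minus"`/`"unstranded"`), as returned by [read_gff()].
#' @param mode One of `"minus"`, `"plus"`, `"both"`, `"fused"`, `"all"`.
#' @return Named list of feature data frames, one per track, names in
#'   `c("minus", "plus", "fused")`.
#' @examples
#' f <- data.frame(seqid = "chr1", source = "x", ftype = "gene",
#'                 start = c(1, 50), end = c(10, 60),
#'                 strand = c("plus", "minus"))
#' names(split_strand_tracks(f, "all"))
#' @export
split_strand_tracks <- function(features, mode) {
  modes <- c("minus", "plus", "both", "fused", "all")
  if (!(is.character(mode) && length(mode) == 1L && mode %in% modes)) {
    cd_stop("unknown strand mode '", paste(mode, collapse = ","),
            "'; valid modes: ", paste(modes, collapse = ", "))
  }
  if (mode %in% c("minus", "plus", "both") &&
      any(features$strand == "unstranded")) {
    cd_warn(sum(features$strand == "unstranded"),
            " unstranded feature(s) ignored under mode '", mode,
            "' (they contribute only to fused tracks)")
  }
  pick <- function(s) features[features$strand == s, , drop = FALSE]
  switch(mode,
    minus = list(minus = pick("minus")),
    plus = list(plus = pick("plus")),
    both = list(minus = pick("minus"), plus = pick("plus")),
    fused = list(fused = features),
    all = list(minus = pick("minus"), plus = pick("plus"),
               fused = features)
  )
}

#' Merge intervals into their union
#'
#' Intervals are sorted by start and overlapping or book-ended intervals
#' are merged, so the result is the canonical sorted, disjoint
#' representation of the covered base set.
#'
#' @param start,end Integer vectors of 1-based inclusive interval bounds.
#' @return Data frame with columns `start`, `end`, sorted, disjoint.
#' @examples
#' merge_intervals(c(100, 150), c(200, 250))
#' @export
merge_intervals <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  if (!length(start)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Tile a sequence (or region) into non-overlapping windows
#'
#' Windows are `[1, W], [W+1, 2W], ...` covering exactly `[1, seq_length]`
#' (or the region, when given) with no gaps or overlaps; only the final
#' window may be shorter than `W`. A window size exceeding the tiled span
#' degrades to a single whole-span window with a warning.
#'
#' @param seq_length Sequence length in bp.
#' @param window_size Nominal window length `W` in bp (>= 1).
#' @param region Optional list/row with 1-based inclusive `start`, `end`;
#'   windows then tile the region instead of the whole sequence.
#' @return Data frame with columns `start`, `end`, `span`.
#' @examples
#' tile_windows(100, 40)
#' @export
tile_windows <- function(seq_length, window_size, region = NULL) {
  if (window_size < 1) cd_stop("window size must be >= 1, got ", window_size)
  if (seq_length < 1) cd_stop("sequence length must be >= 1")
  lo <- 1
  hi <- seq_length
  if (!is.null(region)) {
    lo <- region$start
    hi <- min(region$end, seq_length)
    if (hi < lo) cd_stop("region ", region$start, "-", region$end,
                         " lies outside the sequence")
  }
  span_total <- hi - lo + 1
  if (window_size > span_total) {
    cd_warn("window size ", window_size, " exceeds the tiled span ",
            span_total, "; using a single window")
    window_size <- span_total
  }
  starts <- seq(lo, hi, by = window_size)
  ends <- pmin(starts + window_size - 1, hi)
  data.frame(start = starts, end = ends, span = ends - starts + 1)
}

#' Bases covered by merged intervals within each window
#'
#' @param merged Data frame of disjoint intervals from [merge_intervals()].
#' @param windows Data frame from [tile_windows()].
#' @return Integer vector, one covered-base count per window.
#' @export
window_coverage <- function(merged, windows) {
  if (!nrow(merged)) return(rep(0L, nrow(windows)))
  upto <- max(windows$end, merged$end)
  cov <- IRanges::coverage(IRanges::IRanges(merged$start, merged$end),
                           width = upto)
  v <- IRanges::Views(cov, start = windows$start, end = windows$end)
  as.integer(IRanges::viewSums(v))
}

#' Round raw density percentages down or up to integers
#' @noRd
round_density <- function(raw, rounding = c("floor", "ceil")) {
  rounding <- match.arg(rounding)
  if (rounding == "floor") as.integer(floor(raw)) else as.integer(ceiling(raw))
}

#' Compute a density track over tiled windows
#'
#' Density of a window is `100 * covered / span`, where `covered` is the
#' number of window bases covered by at least one merged interval and
#' `span` is the actual window length (the final window of a chromosome
#' may be shorter than the nominal window size; using its actual span
#' keeps densities <= 100). The raw percentage is rounded down
#' (`"floor"`, the default) or up (`"ceil"`) to an integer, so a window
#' with any coverage at all still shows as 1% under `"ceil"`.
#'
#' @param merged Data frame of disjoint intervals ([merge_intervals()]).
#' @param windows Data frame of windows ([tile_windows()]).
#' @param rounding `"floor"` or `"ceil"`.
#' @param seqid,ftype,track Labels stored on the track.
#' @param scale_id Optional colour-scale id used at render time.
#' @return A `density_track` object: list with `seqid`, `ftype`, `track`,
#'   `windows`, `covered` (int bases), `values` (int percent 0-100) and
#'   `scale_id`.
#' @examples
#' w <- tile_windows(40000, 40000)
#' m <- merge_intervals(1001, 1200)  # 200 covered bases
#' density_track(m, w, rounding = "ceil")$values   # 1
#' density_track(m, w, rounding = "floor")$values  # 0
#' @export
density_track <- function(merged, windows, rounding = "floor",
                          seqid = "seq", ftype = "feature",
                          track = "fused", scale_id = NA_integer_) {
  covered <- window_coverage(merged, windows)
  raw <- 100 * covered / windows$span
  structure(
    list(seqid = seqid, ftype = ftype, track = track, windows = windows,
         covered = covered, values = round_density(raw, rounding),
         scale_id = as.integer(scale_id)),
    class = "density_track"
  )
}

#' @export
print.density_track <- function(x, ...) {
  cat("<density_track> ", x$seqid, " ", x$ftype, " [", x$track, "] ",
      nrow(x$windows), " windows, density ", min(x$values), "-",
      max(x$values), "%\n", sep = "")
  invisible(x)
}

#' GC-content track over tiled windows
#'
#' Per window, the GC percentage is `100 * (G+C) / (A+C+G+T)`: ambiguous
#' bases (N etc.) are excluded from the denominator, and an entirely
#' ambiguous window reports 0 rather than NaN. Case-insensitive. The
#' resulting track carries `ftype = "GC%"`.
#'
#' @param sequence Nucleotide string covering the whole sequence.
#' @param windows Data frame of windows ([tile_windows()]).
#' @inheritParams density_track
#' @return A `density_track` with `ftype = "GC%"`.
#' @examples
#' w <- tile_windows(8, 4)
#' gc_track("GGGGATAT", w)$values  # 100, 0
#' @export
gc_track <- function(sequence, windows, rounding = "floor",
                     seqid = "seq", scale_id = NA_integer_) {
  if (is.na(sequence) || !nzchar(sequence)) {
    cd_stop("GC density requested but no sequence available ",
            "(no ##FASTA section for ", seqid, ")")
  }
  dna <- Biostrings::DNAString(sequence)
  v <- Biostrings::Views(dna, start = windows$start, end = windows$end)
  counts <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
  gc <- counts[, "C|G"]
  denom <- gc + counts[, "A|T"]
  raw <- ifelse(denom == 0, 0, 100 * gc / denom)
  structure(
    list(seqid = seqid, ftype = "GC%", track = "fused", windows = windows,
         covered = as.integer(gc), values = round_density(raw, rounding),
         scale_id = as.integer(scale_id)),
    class = "density_track"
  )
}

#' Window size that fits the longest chromosome in a pixel budget
#'
#' Chooses `W = ceiling(max(seq_lengths) / available_px)` where
#' `available_px` is the picture height minus the fixed vertical chrome
#' (margins, title, sequence and track labels). With one window drawn per
#' pixel this guarantees the longest chromosome occupies at most
#' `available_px` windows.
#'
#' @param seq_lengths Lengths (bp) of the sequences to plot.
#' @param max_height_px Maximum picture height in pixels.
#' @param opts Graphics options (see [dm_options()]), used for the fixed
#'   vertical chrome.
#' @return Window size in bp.
#' @export
auto_window_size <- function(seq_lengths, max_height_px,
                             opts = dm_options()) {
  chrome <- vertical_chrome(opts)
  available <- max_height_px - chrome
  if (available <= 0) {
    cd_stop("maximum picture height ", max_height_px, "px leaves no room ",
            "for density maps (fixed vertical elements need ", chrome, "px)")
  }
  ceiling(max(seq_lengths) / available)
}
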