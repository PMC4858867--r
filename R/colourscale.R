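#' Load the colour-scale catalog
#'
#' Densities (integer percentages 0-100) are mapped to colours through
#' numbered colour scales: an ordered list of inclusive integer bins
#' `[low, high] -> colour` that together cover 0-100 with no gaps or
#' overlaps. The shipped catalog (ids 1-12) lives in a plain
#' tab-separated definition file (`extdata/colour_scales.tsv`, columns
#' `scale_id`, `name`, `low`, `high`, `colour`) so any scale can be
#' overridden without code changes.
#'
#' Notable shipped scales:
#' \describe{
#'   \item{1}{deciles blue -> red, one tone step per 10% of density (the
#'     default).}
#'   \item{10}{low-density emphasis: 0% grey, 1-9% a blue -> red gradient
#'     with one bin per percent, 10% and above dark red.}
#'   \item{12}{GC content: below 30% grey, 30-49% a green -> red gradient,
#'     50% and above dark red.}
#' }
#'
#' @param path Optional path to a user scale-definition file with the
#'   same columns; defaults to the shipped catalog.
#' @return Named list of scales; each scale is a list with `id`, `name`
#'   and a `bins` data frame (`low`, `high`, `colour`).
#' @export
load_colour_scales <- function(path = NULL) {
  path <- path %||% system.file("extdata", "colour_scales.tsv",
                                package = "chromdens", mustWork = TRUE)
  if (!file.exists(path)) cd_stop("scale-definition file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scale_id", "name", "low", "high", "colour")
  if (!all(need %in% names(tab))) {
    cd_stop("scale-definition file ", path, " must have columns: ",
            paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$scale_id), function(s) {
    s <- s[order(s$low), , drop = FALSE]
    validate_scale_bins(s, path)
    list(id = s$scale_id[1L], name = s$name[1L],
         bins = data.frame(low = s$low, high = s$high,
                           colour = toupper(s$colour),
                           stringsAsFactors = FALSE))
  })
  names(out) <- vapply(out, function(s) as.character(s$id), "")
  out
}

#' @noRd
validate_scale_bins <- function(s, path) {
  id <- s$scale_id[1L]
  if (s$low[1L] != 0 || s$high[nrow(s)] != 100) {
    cd_stop(path, ": scale ", id, " does not span 0-100")
  }
  if (nrow(s) > 1L && any(s$low[-1L] != s$high[-nrow(s)] + 1L)) {
    cd_stop(path, ": scale ", id, " has gaps or overlapping bins")
  }
  if (any(s$high < s$low)) cd_stop(path, ": scale ", id, " has inverted bins")
  bad <- !grepl("^#[0-9a-fA-F]{6}$", s$colour)
  if (any(bad)) cd_stop(path, ": scale ", id, " has invalid colour '",
                        s$colour[which(bad)[1L]], "'")
}

#' Fetch one colour scale by id
#'
#' @param id Integer scale number.
#' @param catalog Catalog from [load_colour_scales()].
#' @return The scale (list with `id`, `name`, `bins`).
#' @export
get_scale <- function(id, catalog = load_colour_scales()) {
  s <- catalog[[as.character(id)]]
  if (is.null(s)) {
    cd_stop("unknown colour scale ", id, "; available scales: ",
            paste(names(catalog), collapse = ", "))
  }
  s
}

#' Map integer densities to colours
#'
#' @param values Integer densities in 0-100 (vectorised).
#' @param scale A scale from [get_scale()].
#' @return Character vector of `#RRGGBB` colours.
#' @examples
#' sc <- get_scale(10)
#' map_density(c(0, 5, 15), sc)
#' @export
map_density <- function(values, scale) {
  if (any(values < 0 | values > 100 | is.na(values))) {
    cd_stop("density values outside 0-100 cannot be mapped to colours")
  }
  idx <- findInterval(values, scale$bins$low)
  scale$bins$colour[idx]
}
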