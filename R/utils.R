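# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a chromdens-classed condition
#' @noRd
cd_stop <- function(..., class = "chromdens_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "chromdens_error")))
}

cd_warn <- function(...) warning(paste0(...), call. = FALSE)

#' Format a number for SVG attributes: fixed locale, no scientific
#' notation, trailing zeros stripped (keeps output byte-stable).
#' @noRd
fmt_px <- function(x) {
  s <- formatC(x, format = "f", digits = 3, big.mark = "", decimal.mark = ".")
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Normalise a colour given as name or hex to uppercase #RRGGBB.
#' @noRd
normalize_colour <- function(col) {
  if (length(col) != 1L || is.na(col) || !nzchar(col)) {
    cd_stop("invalid colour: ", deparse(col))
  }
  if (grepl("^#[0-9a-fA-F]{6}$", col)) return(toupper(col))
  rgb <- tryCatch(grDevices::col2rgb(col), error = function(e) NULL)
  if (is.null(rgb)) cd_stop("unknown colour '", col, "'")
  sprintf("#%02X%02X%02X", rgb[1L], rgb[2L], rgb[3L])
}

#' Map GFF column 7 to the internal strand vocabulary.
#' Anything other than '+'/'-' (".", "?", "") is unstranded.
#' @noRd
normalize_strand <- function(x) {
  out <- rep("unstranded", length(x))
  out[x == "+"] <- "plus"
  out[x == "-"] <- "minus"
  out
}

#' Escape text for inclusion in SVG/XML content and attributes.
#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Canonical ordering of strand-track labels in output tables and layout.
TRACK_LEVELS <- c("minus", "plus", "fused")
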