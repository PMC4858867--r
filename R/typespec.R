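#' Parse a feature-type drawing specification
#'
#' The specification selects which feature types (GFF column 3) to draw,
#' which strand tracks to compute for each, and optionally a per-type
#' colour scale overriding the global one. Entries are separated by
#' `;`, fields within an entry by `=`, surrounding whitespace is
#' ignored:
#'
#' ```
#' "match = all = 7;gene = both = 4;CDS = fused = 10"
#' ```
#'
#' A missing third field means the global colour scale applies; a missing
#' second field means the default strand mode (`fused`).
#'
#' @param spec Specification string.
#' @param default_mode Strand mode applied when an entry omits it.
#' @return Data frame with columns `ftype`, `mode`, `scale_id`
#'   (`NA` when the entry inherits the global scale).
#' @examples
#' parse_type_spec("gene = fused;exon = fused;ncRNA = fused = 10")
#' @export
parse_type_spec <- function(spec, default_mode = "fused") {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec))) {
    cd_stop("empty type specification")
  }
  entries <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  entries <- entries[nzchar(trimws(entries))]
  if (!length(entries)) cd_stop("empty type specification")
  modes <- c("minus", "plus", "both", "fused", "all")
  rows <- lapply(entries, function(e) {
    f <- trimws(strsplit(e, "=", fixed = TRUE)[[1L]])
    if (length(f) < 1L || !nzchar(f[1L])) {
      cd_stop("empty feature type in spec entry '", trimws(e), "'")
    }
    mode <- if (length(f) >= 2L) f[2L] else default_mode
    if (!(mode %in% modes)) {
      cd_stop("unknown strand keyword '", mode, "' in spec entry '",
              trimws(e), "'; valid: ", paste(modes, collapse = ", "))
    }
    scale_id <- NA_integer_
    if (length(f) >= 3L) {
      scale_id <- suppressWarnings(as.integer(f[3L]))
      if (is.na(scale_id)) {
        cd_stop("non-integer colour scale '", f[3L], "' in spec entry '",
                trimws(e), "'")
      }
    }
    if (length(f) > 3L) {
      cd_stop("too many fields in spec entry '", trimws(e), "'")
    }
    data.frame(ftype = f[1L], mode = mode, scale_id = scale_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
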