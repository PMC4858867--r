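#' Read features and sequences from a GFF file
#'
#' Parses GFF2, GFF2.5 or GFF3. The three dialects differ only in the
#' attribute syntax of column 9, which this tool never interprets, so a
#' single tolerant parser handles all of them (column 9 is carried as
#' opaque text and otherwise ignored). `##sequence-region` pragmas and an
#' embedded `##FASTA` section are honoured; all other `#` lines are
#' skipped.
#'
#' Sequence lengths are determined with the precedence
#' `##sequence-region` pragma > FASTA sequence length > maximum feature
#' end on that seqid. A pragma that contradicts the FASTA sequence length
#' is an error. Features extending past the declared length are clipped
#' to it with a warning.
#'
#' @param path Path to a GFF file.
#' @param types Character vector of feature types (GFF column 3) to keep.
#'   `NULL` or empty keeps everything. If filtering leaves no features the
#'   function errors, listing the types actually present in the file.
#' @return A list with two data frames:
#'   \describe{
#'     \item{features}{columns `seqid`, `source`, `ftype`, `start`, `end`
#'       (1-based inclusive), `strand` (one of `"plus"`, `"minus"`,
#'       `"unstranded"`).}
#'     \item{sequences}{columns `seqid`, `length` (bp) and `sequence`
#'       (nucleotide string, `NA` when the file carries no FASTA section
#'       for that seqid).}
#'   }
#' @examples
#' gff <- generate_gff_fixture(seed = 1, n_seqs = 1, seq_length = 10000,
#'                             n_features = 20, types = "gene")
#' tmp <- tempfile(fileext = ".gff3")
#' writeLines(gff, tmp)
#' ann <- read_gff(tmp, types = "gene")
#' nrow(ann$features)
#' @export
read_gff <- function(path, types = NULL) {
  if (!file.exists(path)) cd_stop("GFF file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  fasta_at <- match(TRUE, startsWith(lines, "##FASTA"))
  head_lines <- if (is.na(fasta_at)) lines else lines[seq_len(fasta_at - 1L)]
  fasta_lines <- if (is.na(fasta_at)) character() else
    lines[seq.int(fasta_at + 1L, length.out = length(lines) - fasta_at)]

  # ##sequence-region <seqid> <start> <end>
  pragma <- head_lines[startsWith(head_lines, "##sequence-region")]
  pragma_tab <- NULL
  if (length(pragma)) {
    parts <- strsplit(trimws(sub("^##sequence-region", "", pragma)), "[ \t]+")
    ok <- lengths(parts) >= 3L
    if (any(!ok)) cd_stop(path, ": malformed ##sequence-region pragma")
    pragma_tab <- data.frame(
      seqid = vapply(parts, `[[`, "", 1L),
      length = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L))),
      stringsAsFactors = FALSE
    )
    if (anyNA(pragma_tab$length)) {
      cd_stop(path, ": non-integer coordinates in ##sequence-region pragma")
    }
  }

  is_body <- !startsWith(head_lines, "#") & nzchar(trimws(head_lines))
  body <- head_lines[is_body]
  body_lineno <- which(is_body)

  feats <- parse_gff_body(body, body_lineno, path)
  types_seen <- unique(feats$ftype)

  if (!is.null(types) && length(types)) {
    feats <- feats[feats$ftype %in% types, , drop = FALSE]
  }
  if (nrow(feats) == 0L) {
    cd_stop("no features of requested types (",
            paste(types %||% character(), collapse = ", "),
            ") in ", path, "; types seen: ",
            if (length(types_seen)) paste(types_seen, collapse = ", ")
            else "<none>")
  }

  fasta <- parse_fasta_section(fasta_lines, path)
  seqs <- build_sequence_records(feats, pragma_tab, fasta, path)

  # clip features that overhang the declared sequence length
  len <- seqs$length[match(feats$seqid, seqs$seqid)]
  over <- feats$end > len
  if (any(over)) {
    cd_warn(sum(over), " feature(s) extend past the declared sequence ",
            "length in ", path, "; clipped")
    feats$end[over] <- len[over]
    drop <- feats$start > len
    if (any(drop)) feats <- feats[!drop, , drop = FALSE]
  }

  rownames(feats) <- NULL
  list(features = feats, sequences = seqs)
}

#' Vectorised parse of GFF feature lines with per-line diagnostics
#' @noRd
parse_gff_body <- function(body, lineno, path) {
  empty <- data.frame(seqid = character(), source = character(),
                      ftype = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)

  cols <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(cols) < 8L) {
    cd_stop(path, " line ", lineno[1L],
            ": expected 9 tab-separated GFF columns, found ", length(cols))
  }
  if (length(cols) > 9L) {
    bad <- which(!is.na(cols[[10L]]))[1L]
    cd_stop(path, " line ", lineno[bad], ": more than 9 GFF columns")
  }
  short <- which(is.na(cols[[8L]]))
  if (length(short)) {
    cd_stop(path, " line ", lineno[short[1L]],
            ": fewer than 8 tab-separated GFF columns")
  }
  start <- suppressWarnings(as.numeric(cols[[4L]]))
  end <- suppressWarnings(as.numeric(cols[[5L]]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    cd_stop(path, " line ", lineno[bad[1L]],
            ": non-integer coordinates '", cols[[4L]][bad[1L]], "', '",
            cols[[5L]][bad[1L]], "'")
  }
  bad <- which(end < start | start < 1)
  if (length(bad)) {
    cd_stop(path, " line ", lineno[bad[1L]], ": invalid interval ",
            start[bad[1L]], "-", end[bad[1L]])
  }
  if (any(!nzchar(cols[[3L]]))) {
    bad <- which(!nzchar(cols[[3L]]))[1L]
    cd_stop(path, " line ", lineno[bad], ": empty feature type")
  }
  data.frame(seqid = cols[[1L]], source = cols[[2L]], ftype = cols[[3L]],
             start = start, end = end,
             strand = normalize_strand(cols[[7L]]),
             stringsAsFactors = FALSE)
}

#' Parse the post-##FASTA lines into named sequences
#' @noRd
parse_fasta_section <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(character())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) cd_stop(path, ": ##FASTA section does not start with '>'")
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[is_hdr])
  grp <- cumsum(is_hdr)
  chunks <- split(lines[!is_hdr], grp[!is_hdr])
  seqs <- vapply(chunks, function(x) paste0(x, collapse = ""), "")
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- unname(seqs)
  names(out) <- ids
  out
}

#' Assemble per-seqid length/sequence records
#' @noRd
build_sequence_records <- function(feats, pragma_tab, fasta, path) {
  ids <- unique(c(feats$seqid, pragma_tab$seqid, names(fasta)))
  len <- rep(NA_real_, length(ids))
  seq <- rep(NA_character_, length(ids))

  if (length(fasta)) {
    i <- match(names(fasta), ids)
    seq[i] <- unname(fasta)
    len[i] <- nchar(fasta)
  }
  if (!is.null(pragma_tab)) {
    i <- match(pragma_tab$seqid, ids)
    clash <- !is.na(len[i]) & len[i] != pragma_tab$length
    if (any(clash)) {
      k <- which(clash)[1L]
      cd_stop(path, ": ##sequence-region length for ", pragma_tab$seqid[k],
              " (", pragma_tab$length[k], ") contradicts FASTA sequence ",
              "length (", len[i][k], ")")
    }
    len[i] <- pragma_tab$length
  }
  if (anyNA(len)) {
    miss <- is.na(len)
    mx <- tapply(feats$end, feats$seqid, max)
    len[miss] <- as.numeric(mx[ids[miss]])
  }
  if (anyNA(len)) cd_stop(path, ": cannot determine sequence length for ",
                          paste(ids[is.na(len)], collapse = ", "))
  data.frame(seqid = ids, length = len, sequence = seq,
             stringsAsFactors = FALSE)
}

#' Read several GFF files as one annotation set
#'
#' Convenience wrapper: features are concatenated; a seqid present in
#' more than one file must declare the same length in all of them.
#'
#' @param paths Character vector of GFF paths.
#' @inheritParams read_gff
#' @return Same shape as [read_gff()].
#' @export
read_gff_many <- function(paths, types = NULL) {
  parts <- lapply(paths, read_gff, types = types)
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  seqs <- do.call(rbind, lapply(parts, `[[`, "sequences"))
  dup <- duplicated(seqs$seqid)
  if (any(dup)) {
    for (id in unique(seqs$seqid[dup])) {
      ls <- unique(seqs$length[seqs$seqid == id])
      if (length(ls) > 1L) {
        cd_stop("seqid ", id, " declared with conflicting lengths across ",
                "input files: ", paste(ls, collapse = ", "))
      }
    }
    # prefer a record that carries sequence
    seqs <- seqs[order(seqs$seqid, is.na(seqs$sequence)), , drop = FALSE]
    seqs <- seqs[!duplicated(seqs$seqid), , drop = FALSE]
  }
  rownames(seqs) <- NULL
  list(features = feats, sequences = seqs)
}

#' Read a BED file of regions to plot
#'
#' BED coordinates are 0-based, half-open; they are converted to 1-based
#' inclusive on ingest so that all internal arithmetic shares the GFF
#' convention. Columns beyond the third are ignored; `#` lines are
#' skipped.
#'
#' @param path Path to a BED3(+) file.
#' @return Data frame with columns `seqid`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) cd_stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) cd_stop(path, ": no regions found")
  cols <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(cols) < 3L || anyNA(cols[[3L]])) {
    bad <- if (length(cols) < 3L) lineno[1L] else lineno[which(is.na(cols[[3L]]))[1L]]
    cd_stop(path, " line ", bad, ": expected at least 3 tab-separated columns")
  }
  start0 <- suppressWarnings(as.numeric(cols[[2L]]))
  end0 <- suppressWarnings(as.numeric(cols[[3L]]))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad)) {
    cd_stop(path, " line ", lineno[bad[1L]], ": non-integer coordinates")
  }
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad)) {
    cd_stop(path, " line ", lineno[bad[1L]], ": empty or negative region ",
            start0[bad[1L]], "-", end0[bad[1L]])
  }
  data.frame(seqid = cols[[1L]], start = start0 + 1, end = end0,
             stringsAsFactors = FALSE)
}

#' Write the per-window density table
#'
#' One row per (sequence, feature type, strand track, window), tab
#' separated, ordered by seqid and feature type in their order of first
#' appearance, strand track in the order minus, plus, fused, then window
#' start. Window coordinates are 1-based inclusive, matching GFF. The
#' window size used is recorded as a `# window_size=` comment line above
#' the header.
#'
#' @param tracks List of density tracks (see [density_track()]).
#' @param path Output path.
#' @param window_size Nominal window length in bp, echoed as a comment.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(tracks, path, window_size = NULL) {
  tab <- tracks_table(tracks)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(window_size)) {
    writeLines(paste0("# window_size=", format(window_size, scientific = FALSE)),
               con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Flatten density tracks to the output table
#' @noRd
tracks_table <- function(tracks) {
  if (!length(tracks)) cd_stop("no density tracks to write")
  rows <- lapply(tracks, function(tr) {
    data.frame(seqid = tr$seqid,
               window_start = tr$windows$start,
               window_end = tr$windows$end,
               ftype = tr$ftype,
               strand_mode = tr$track,
               density = tr$values,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sid <- factor(tab$seqid, levels = unique(tab$seqid))
  fty <- factor(tab$ftype, levels = unique(tab$ftype))
  trk <- factor(tab$strand_mode, levels = TRACK_LEVELS)
  tab <- tab[order(sid, fty, trk, tab$window_start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read back a density table written by [write_density_csv()]
#'
#' @param path Path to the tab-separated density table.
#' @return Data frame with the documented columns.
#' @export
read_density_csv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "seqid"))
}
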