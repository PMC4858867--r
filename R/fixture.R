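#' Generate a synthetic GFF3 annotation for testing
#'
#' Produces a deterministic (seeded) GFF3 document: `##sequence-region`
#' pragmas, uniformly placed features of the requested types on random
#' strands, and (optionally) a `##FASTA` section whose nucleotide
#' composition has the requested GC fraction (bases drawn i.i.d., so the
#' realised whole-sequence GC is binomially concentrated around
#' `gc_bias`). Feature lengths are uniform on 50-2000 bp (clipped to the
#' sequence end), start positions uniform, strands drawn
#' plus/minus/unstranded with probabilities 0.48/0.48/0.04 — the sprinkle
#' of unstranded records mirrors real annotations where some feature
#' classes carry no strand. Output round-trips through [read_gff()].
#'
#' The caller's random-number state is left untouched.
#'
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @param n_seqs Number of sequences (named `seq1`, `seq2`, ...).
#' @param seq_length Length of every sequence, bp.
#' @param n_features Total number of features across all sequences.
#' @param types Feature types to draw from (uniformly).
#' @param gc_bias Target GC fraction of the generated sequence.
#' @param with_sequence Emit the `##FASTA` section? Disable for large
#'   fixtures where only intervals matter.
#' @param path If given, write the document there and return the path;
#'   otherwise return the lines.
#' @return Character vector of GFF lines, or `path`.
#' @examples
#' gff <- generate_gff_fixture(seed = 42, n_seqs = 1, seq_length = 5000,
#'                             n_features = 10, types = c("gene", "exon"))
#' head(gff, 3)
#' @export
generate_gff_fixture <- function(seed, n_seqs = 2, seq_length = 100000,
                                 n_features = 200,
                                 types = c("gene", "exon"),
                                 gc_bias = 0.5, with_sequence = TRUE,
                                 path = NULL) {
  stopifnot(n_seqs >= 1, seq_length >= 1, n_features >= 1,
            length(types) >= 1, gc_bias >= 0, gc_bias <= 1)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  seqids <- paste0("seq", seq_len(n_seqs))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqids, seq_length))

  sid <- sample(seqids, n_features, replace = TRUE)
  start <- sample.int(seq_length, n_features, replace = TRUE)
  len <- sample(50:2000, n_features, replace = TRUE)
  end <- pmin(start + len - 1L, seq_length)
  strand <- sample(c("+", "-", "."), n_features, replace = TRUE,
                   prob = c(0.48, 0.48, 0.04))
  ftype <- sample(types, n_features, replace = TRUE)
  ord <- order(match(sid, seqids), start, end)
  lines <- c(lines, sprintf(
    "%s\tchromdens_synth\t%s\t%d\t%d\t.\t%s\t.\tID=f%06d",
    sid[ord], ftype[ord], start[ord], end[ord], strand[ord],
    seq_len(n_features)))

  if (with_sequence) {
    lines <- c(lines, "##FASTA")
    p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
           G = gc_bias / 2, T = (1 - gc_bias) / 2)
    for (s in seqids) {
      bases <- sample(names(p), seq_length, replace = TRUE, prob = p)
      seq <- paste0(bases, collapse = "")
      lines <- c(lines, paste0(">", s),
                 substring(seq, seq(1, seq_length, by = 70),
                           pmin(seq(70, seq_length + 69, by = 70),
                                seq_length)))
    }
  }

  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
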