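# Independent per-base bitmap oracle for interval coverage, plus small
# random-feature helpers. Kept deliberately naive: a logical vector over
# the sequence, filled interval by interval.

bitmap_coverage <- function(start, end, seq_length) {
  bm <- logical(seq_length)
  for (i in seq_along(start)) {
    bm[start[i]:min(end[i], seq_length)] <- TRUE
  }
  bm
}

# covered bases per window, straight off the bitmap
oracle_window_cover <- function(start, end, windows, seq_length) {
  bm <- bitmap_coverage(start, end, seq_length)
  cs <- c(0, cumsum(bm))
  as.integer(cs[windows$end + 1] - cs[windows$start])
}

random_features <- function(n, seq_length, seqid = "chr") {
  start <- sample.int(seq_length, n, replace = TRUE)
  len <- sample.int(max(2, seq_length %/% 20), n, replace = TRUE)
  data.frame(seqid = seqid, source = "synth", ftype = "feat",
             start = start, end = pmin(start + len - 1L, seq_length),
             strand = sample(c("plus", "minus", "unstranded"), n,
                             replace = TRUE, prob = c(0.45, 0.45, 0.1)),
             stringsAsFactors = FALSE)
}

write_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(lines, path)
  path
}
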