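test_that("GFF lines map to features with normalised strands", {
  p <- write_gff(c(
    "##gff-version 3",
    "2L\tFlyBase\tgene\t100\t500\t.\t+\t.\tID=g1",
    "2L\tFlyBase\texon\t120\t180\t.\t-\t.\tID=e1",
    "2L\tFlyBase\tmatch\t10\t20\t.\t.\t.\tID=m1"
  ))
  ann <- read_gff(p, types = "gene")
  expect_equal(nrow(ann$features), 1L)
  f <- ann$features[1, ]
  expect_equal(f$seqid, "2L")
  expect_equal(f$ftype, "gene")
  expect_equal(f$start, 100)
  expect_equal(f$end, 500)
  expect_equal(f$strand, "plus")

  all3 <- read_gff(p)$features
  expect_equal(sort(all3$strand), c("minus", "plus", "unstranded"))
})

test_that("type filtering errors list the types actually present", {
  p <- write_gff(c("2L\tx\tgene\t100\t500\t.\t+\t.\tid"))
  err <- expect_error(read_gff(p, types = "exon"), "no features")
  expect_match(conditionMessage(err), "gene")
})

test_that("a mixed fixture partitions by type as generated", {
  p <- write_gff(c(
    sprintf("2L\tx\tgene\t%d\t%d\t.\t+\t.\tid", c(1, 50, 200), c(10, 70, 260)),
    sprintf("2L\tx\texon\t%d\t%d\t.\t-\t.\tid", c(5, 300), c(9, 330))
  ))
  ann <- read_gff(p, types = c("gene", "exon"))
  expect_equal(as.vector(table(ann$features$ftype)[c("gene", "exon")]),
               c(3L, 2L))
})

test_that("malformed lines are reported with file and line number", {
  p <- write_gff(c("##gff-version 3",
                   "2L\tx\tgene\t100\t500\t.\t+\t.\tid",
                   "2L\tx\tgene\tabc\t500\t.\t+\t.\tid"))
  expect_error(read_gff(p), "line 3.*non-integer", ignore.case = TRUE)

  p2 <- write_gff("2L\tx\tgene\t500\t100\t.\t+\t.\tid")
  expect_error(read_gff(p2), "line 1.*invalid interval")

  p3 <- write_gff("2L\tgene\t100")
  expect_error(read_gff(p3), "column")
})

test_that("sequence length precedence: pragma > FASTA > max feature end", {
  # pragma only
  p <- write_gff(c("##sequence-region chrA 1 9000",
                   "chrA\tx\tgene\t10\t100\t.\t+\t.\tid"))
  expect_equal(read_gff(p)$sequences$length, 9000)

  # FASTA only
  p <- write_gff(c("chrA\tx\tgene\t10\t100\t.\t+\t.\tid",
                   "##FASTA", ">chrA", strrep("ACGT", 50)))
  s <- read_gff(p)$sequences
  expect_equal(s$length, 200)
  expect_equal(nchar(s$sequence), 200)

  # neither: max feature end
  p <- write_gff(c("chrA\tx\tgene\t10\t100\t.\t+\t.\tid",
                   "chrA\tx\tgene\t50\t777\t.\t-\t.\tid"))
  expect_equal(read_gff(p)$sequences$length, 777)

  # pragma contradicting FASTA is an error
  p <- write_gff(c("##sequence-region chrA 1 100",
                   "chrA\tx\tgene\t10\t50\t.\t+\t.\tid",
                   "##FASTA", ">chrA", strrep("ACGT", 50)))
  expect_error(read_gff(p), "contradicts")
})

test_that("features past the declared length are clipped with a warning", {
  p <- write_gff(c("##sequence-region chrA 1 120",
                   "chrA\tx\tgene\t100\t500\t.\t+\t.\tid"))
  expect_warning(ann <- read_gff(p), "clipped")
  expect_equal(ann$features$end, 120)
})

test_that("parsing loses no (seqid, ftype, start, end, strand) tuple", {
  set.seed(7)
  f <- random_features(50, 10000, seqid = "sq")
  p <- write_gff(c("##sequence-region sq 1 10000", sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=x",
    f$seqid, f$source, f$ftype, f$start, f$end,
    c(plus = "+", minus = "-", unstranded = ".")[f$strand])))
  got <- read_gff(p)$features
  key <- function(d) sort(paste(d$seqid, d$ftype, d$start, d$end, d$strand))
  expect_identical(key(got), key(f))
})

test_that("BED regions parse and convert to 1-based inclusive", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("2L\t100000\t200000", "2R\t300000\t450000"), p)
  reg <- read_bed_regions(p)
  expect_equal(reg$seqid, c("2L", "2R"))
  expect_equal(reg$start, c(100001, 300001))
  expect_equal(reg$end, c(200000, 450000))
  expect_equal(reg$end - reg$start + 1, c(100000, 150000))

  writeLines("chr\t10\t10", p)
  expect_error(read_bed_regions(p), "empty")
  writeLines("chr\tten\t20", p)
  expect_error(read_bed_regions(p), "non-integer")
  writeLines("chr\t10", p)
  expect_error(read_bed_regions(p), "3 tab-separated")
})

test_that("density CSV round-trips values and row counts exactly", {
  w <- tile_windows(300, 100)
  tr1 <- density_track(merge_intervals(c(1, 150), c(100, 199)), w,
                       seqid = "s1", ftype = "gene", track = "fused")
  tr2 <- density_track(merge_intervals(10, 40), w,
                       seqid = "s1", ftype = "exon", track = "plus")
  expect_equal(tr1$values, c(100, 50, 0))

  p <- tempfile(fileext = ".csv")
  write_density_csv(list(tr1, tr2), p, window_size = 100)
  lines <- readLines(p)
  expect_equal(lines[1], "# window_size=100")
  expect_equal(length(lines), 2L + 2L * nrow(w))  # comment + header + rows

  back <- read_density_csv(p)
  expect_equal(nrow(back), 6L)
  expect_equal(back$density[back$ftype == "gene"], tr1$values)
  expect_equal(back$density[back$ftype == "exon"], tr2$values)
  # ordered by seqid, ftype appearance, track, window start
  expect_equal(back$window_start[back$ftype == "gene"], w$start)
})

test_that("multi-file reads concatenate and reconcile sequence lengths", {
  p1 <- write_gff(c("##sequence-region a 1 500",
                    "a\tx\tgene\t1\t10\t.\t+\t.\tid"))
  p2 <- write_gff(c("##sequence-region b 1 900",
                    "b\tx\tgene\t5\t20\t.\t-\t.\tid"))
  ann <- read_gff_many(c(p1, p2))
  expect_equal(nrow(ann$features), 2L)
  expect_setequal(ann$sequences$seqid, c("a", "b"))

  p3 <- write_gff(c("##sequence-region a 1 600",
                    "a\tx\tgene\t1\t10\t.\t+\t.\tid"))
  expect_error(read_gff_many(c(p1, p3)), "conflicting lengths")
})
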