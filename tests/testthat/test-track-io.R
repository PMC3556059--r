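seqset4 <- function() {
  sequenceSet(c("s1", "s2"), c("chr1", "chr2"), c(100, 0), c(140, 30),
              strand = c("+", "-"), build = "test")
}

test_that("FASTA round-trips DNA tracks including masked and lowercase letters", {
  ss <- seqset4()
  d <- dnaTrack(c(s1 = paste(rep("ACGTNXacgt", 4), collapse = ""),
                  s2 = strrep("GATTACAxnn", 3)))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeTrack(d, path, "fasta", ss)
  back <- readTrack(path, "fasta", ss)
  expect_identical(dnaStrings(back), dnaStrings(d))
  ## mismatched length is an error
  ss2 <- sequenceSet(c("s1", "s2"), c("chr1", "chr2"), c(100, 0), c(139, 30))
  expect_error(readTrack(path, "fasta", ss2), "length mismatch")
})

test_that("GFF writer emits 1-based inclusive coordinates", {
  ss <- seqset4()
  rt <- regionTrack(list(s1 = regionFrame(c(0, 10), c(4, 20), c("cpg", "peak"),
                                          c(0.5, 2), c("-", "+"))), seqLengths(ss))
  path <- withr::local_tempfile(fileext = ".gff")
  writeTrack(rt, path, "gff", ss)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  f <- strsplit(lines[1], "\t")[[1]]
  ## internal [0,4) on a sequence at genomic 100 -> GFF 101..104
  expect_identical(f[4], "101")
  expect_identical(f[5], "104")
  expect_identical(f[6], "0.5")
  expect_identical(f[7], "-")
})

test_that("GFF round-trips regions with properties and children exactly", {
  ss <- seqset4()
  child <- regionFrame(c(2, 5), c(4, 8), c("A", "B"), c(0.25, 0.75), c("+", "-"))
  rt <- regionTrack(list(
    s1 = regionFrame(c(0, 11), c(9, 23), c("mod", "site"), c(1.25, 0.3), c(".", "+"),
                     properties = list(list(depth = 3.5, note = "alpha"), list()),
                     children = list(child, NULL)),
    s2 = regionFrame(5, 25, "site", 0.125, "-")), seqLengths(ss))
  path <- withr::local_tempfile(fileext = ".gff")
  writeTrack(rt, path, "gff", ss)
  back <- readTrack(path, "gff", ss)
  expect_equal(trackRegions(back), trackRegions(rt))
  ## writers are deterministic: same input, byte-identical output
  path2 <- withr::local_tempfile(fileext = ".gff")
  writeTrack(rt, path2, "gff", ss)
  expect_identical(readLines(path), readLines(path2))
})

test_that("GFF records outside all sequences are dropped with a count", {
  ss <- seqset4()
  path <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("chr9\tx\tregion\t1\t5\t.\t+\t.\tID=a;Name=t",
               "chr1\tx\tregion\t101\t104\t.\t+\t.\tID=b;Name=t"), path)
  expect_message(tr <- readTrack(path, "gff", ss), "1 GFF record")
  expect_equal(regionCount(tr), 1L)
  expect_equal(trackRegions(tr)$s1$start, 0L)
})

test_that("malformed GFF and BED records report the line number", {
  ss <- seqset4()
  path <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("chr1\tx\tregion\t101\t104\t.\t+\t.\tID=a", "garbage line"), path)
  expect_error(readTrack(path, "gff", ss), "line 2")
  pb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tabc\tdef", pb)
  expect_error(readTrack(pb, "bed", ss), "line 1")
})

test_that("BED round-trips six-column region data (0-based half-open)", {
  ss <- seqset4()
  rt <- regionTrack(list(s1 = regionFrame(c(3, 8), c(6, 14), c("r1", "r2"),
                                          c(1, 0.5), c("+", ".")),
                         s2 = regionFrame(0, 30, "whole", 2, "-")), seqLengths(ss))
  path <- withr::local_tempfile(fileext = ".bed")
  writeTrack(rt, path, "bed", ss)
  f <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_identical(f[2], "103")   # genomic = sequence start 100 + internal 3
  expect_identical(f[3], "106")
  back <- readTrack(path, "bed", ss)
  expect_equal(trackRegions(back), trackRegions(rt))
})

test_that("fixed-step WIG round-trips numeric tracks within text precision", {
  ss <- seqset4()
  set.seed(42)
  nt <- numericTrack(list(s1 = round(stats::rnorm(40), 5), s2 = stats::runif(30) * 1000))
  path <- withr::local_tempfile(fileext = ".wig")
  writeTrack(nt, path, "wig", ss)
  back <- readTrack(path, "wig", ss)
  for (nm in c("s1", "s2"))
    expect_equal(trackValues(back)[[nm]], trackValues(nt)[[nm]], tolerance = 1e-6)
})

test_that("bedGraph intervals fill the covered positions and leave the rest 0", {
  ss <- sequenceSet("s1", "chr1", 0, 5)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t2.5", path)
  nt <- readTrack(path, "bedgraph", ss)
  expect_equal(trackValues(nt)$s1, c(2.5, 2.5, 2.5, 0, 0))
})

test_that("JASPAR counts are normalized with a 0.25 pseudocount per cell", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M_ONE test",
               "A [ 10  0 ]",
               "C [  0 10 ]",
               "G [  0  0 ]",
               "T [  0  0 ]",
               ">M_TWO other",
               "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]"), path)
  ms <- readMotifs(path, "jaspar")
  expect_length(motifIds(ms), 2L)
  m1 <- getMotif(ms, "M_ONE")@matrix
  ## (10 + 0.25) / (10 + 4*0.25) = 10.25 / 11
  expect_equal(unname(m1["A", 1]), 10.25 / 11)
  expect_equal(unname(m1["C", 1]), 0.25 / 11)
  expect_equal(colSums(m1), c(1, 1), ignore_attr = TRUE)
})

test_that("TRANSFAC matrix blocks parse into normalized motifs", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("ID MX1", "BF something", "P0  A  C  G  T",
               "01  4  0  0  0  A",
               "02  0  4  0  0  C",
               "XX", "//",
               "ID MX2", "P0  A  C  G  T",
               "01  1  1  1  1  N", "//"), path)
  ms <- readMotifs(path, "transfac")
  expect_identical(motifIds(ms), c("MX1", "MX2"))
  expect_equal(unname(getMotif(ms, "MX1")@matrix["A", 1]), 4.25 / 5)
})

test_that("MEME minimal probability matrices pass the column-sum invariant", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF CREB_like", "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
               " 0.9 0.1 0.0 0.0", " 0.0 0.0 1.0 0.0", " 0.25 0.25 0.25 0.25"), path)
  ms <- readMotifs(path, "meme")
  m <- getMotif(ms, "CREB_like")@matrix
  expect_equal(unname(colSums(m)), rep(1, 3))
  expect_equal(ncol(m), 3L)
})

test_that("motif columns summing to zero and unknown markers are errors", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">BAD", "A [ 0 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]"), path)
  expect_error(readMotifs(path, "jaspar"), "sums? to 0|summing to 0")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("this is not a motif file", p2)
  expect_error(readMotifs(p2, "meme"), "MEME")
  expect_error(readMotifs(p2, "jaspar"), "no JASPAR")
})

test_that("sequence sets from coordinates validate names and bounds", {
  specs <- data.frame(name = c("a", "b"), chrom = c("chr1", "chr2"),
                      start = c(100, 0), end = c(200, 50),
                      strand = c("+", "-"), build = "hg18")
  ss <- sequencesFromCoordinates(specs)
  expect_equal(unname(seqLengths(ss)), c(100, 50))
  expect_error(sequencesFromCoordinates(transform(specs, end = start)), "end must be")
  expect_error(sequencesFromCoordinates(rbind(specs, specs[1, ])), "duplicate")
})

test_that("promoter windows around the TSS are strand-aware", {
  ann <- data.frame(gene = c("g1", "g2", "g3"), chrom = "chr5",
                    strand = c("+", "-", "+"), tss = c(5000, 5000, 120),
                    tes = c(7000, 3000, 500), stringsAsFactors = FALSE)
  ## 2000 bp upstream to 200 bp downstream of the TSS
  ss <- sequencesFromGenes(c("g1", "g2"), ann, "TSS", upstream = 2000, downstream = 200)
  i1 <- ss@info[ss@info$name == "g1", ]
  expect_equal(c(i1$start, i1$end), c(3000, 5200))
  expect_equal(i1$tss_offset, 2000)
  i2 <- ss@info[ss@info$name == "g2", ]
  expect_equal(c(i2$start, i2$end), c(4800, 7000))
  expect_equal(i2$tss_offset, 200)
  ## clipping at zero warns; empty windows and unknown genes are handled
  expect_warning(sequencesFromGenes("g3", ann, "TSS", 2000, 200), "clipped")
  expect_error(sequencesFromGenes("g1", ann, "TSS", 0, 0), "empty window")
  expect_message(sequencesFromGenes(c("g1", "nope"), ann, "TSS", 100, 10), "not in annotation")
})

test_that("PSP priors export round-trips and rejects negative values", {
  pr <- numericTrack(list(s1 = c(0.5, 0.5, 0.5), s2 = c(0.123456, 1)))
  path <- withr::local_tempfile(fileext = ".psp")
  exportPriors(pr, path)
  lines <- readLines(path)
  expect_identical(lines[2], "0.5 0.5 0.5")
  back <- readPriors(path)
  expect_equal(trackValues(back)$s2, trackValues(pr)$s2, tolerance = 1e-6)
  expect_error(exportPriors(numericTrack(list(a = c(-0.1))), path), "non-negative")
})
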