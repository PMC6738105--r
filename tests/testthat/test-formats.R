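test_that("expression TSV round-trips losslessly and validates its input", {
  co <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(co, path)
  back <- read_expression(path, "toy")
  expect_identical(back$genes, co$genes)
  expect_identical(back$samples, co$samples)
  expect_lt(max(abs(back$values - co$values)), 1e-12)

  # shape of a well-formed minimal file
  writeLines(c("gene\tA\tB", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"), path)
  expect_equal(dim(read_expression(path, "x")), c(3L, 2L))

  # NA cells are tolerated as missing
  writeLines(c("gene\tA\tB", "g1\tNA\t2"), path)
  expect_true(is.na(read_expression(path, "x")$values[1, 1]))
})

test_that("duplicated gene rows collapse to the highest-mean row with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tA\tB", "g1\t1\t1", "g1\t5\t5", "g2\t2\t2"), path)
  expect_warning(co <- read_expression(path, "x"), "duplicated gene")
  expect_equal(nrow(co$values), 2L)
  expect_equal(unname(co$values["g1", ]), c(5, 5))
})

test_that("malformed expression files fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tA\tB", "g1\t1\t2", "g2\tfoo\t4"), path)
  expect_error(read_expression(path, "x"), ":3")
  writeLines(c("gene\tA\tB", "g1\t1"), path)
  expect_error(read_expression(path, "x"), ":2")
  writeLines("gene", path)
  expect_error(read_expression(path, "x"), "header|at least one")
})

test_that("GMT reading handles the standard dialect, dedup and errors", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB", path)
  gs <- read_gmt(path)
  expect_identical(gs[["S1"]], c("A", "B"))
  expect_identical(attr(gs, "descriptions")[["S1"]], "desc")

  writeLines("S1\td\tA\tA", path)
  expect_warning(gs <- read_gmt(path), "duplicate member")
  expect_identical(gs[["S1"]], "A")

  writeLines(c("S1\td\tA", "S2\tonly-two-fields"), path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("a 21-set synthetic collection round-trips through GMT losslessly", {
  truth <- small_bundle()$truth
  gen <- gen_gmt(truth, core_size = 10, n_motif_sets = 6, extra_module = 5,
                 extra_background = 4, n_decoy_sets = 15, decoy_size = 8,
                 seed = 7L)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gen$collection, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(gen$collection))
  for (nm in names(back)) expect_identical(back[[nm]], gen$collection[[nm]])
})

test_that("BED parsing keeps 0-based half-open coordinates and validates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", path)
  iv <- read_bed(path)
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 200L)

  writeLines(c("chr1\t100\t200\tp1\t0.01\t+", "chr2\t0\t50\tp2\t0.5\t-"), path)
  iv <- read_bed(path)
  expect_equal(iv$score, c(0.01, 0.5))
  expect_equal(iv$strand, c("+", "-"))

  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path), ":1")
  writeLines("chr1\t-5\t100", path)
  expect_error(read_bed(path), ":1")
})

test_that("BED round-trips through write_bed", {
  iv <- genomic_intervals(c("chr1", "chr2"), c(10L, 0L), c(20L, 5L),
                          name = c("a", "b"), score = c(0.02, 0.3),
                          strand = c("+", "."))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  back <- read_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(iv))
})

test_that("GTF gene models convert 1-based closed to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tgene_id "gA";',
    'chr1\tsrc\tCDS\t301\t400\t.\t+\t0\tgene_id "gA";',
    'chr2\tsrc\tCDS\t51\t150\t.\t-\t0\tgene_id "gB";'
  ), path)
  gm <- read_gene_models(path)
  a <- gm[gm$name == "gA", ]
  expect_equal(a$start, 100L)  # spans the two CDS rows
  expect_equal(a$end, 400L)
  b <- gm[gm$name == "gB", ]
  expect_equal(c(b$start, b$end), c(50L, 150L))
  expect_equal(b$strand, "-")

  writeLines('chr1\tsrc\tCDS\t0\t200\t.\t+\t0\tgene_id "gA";', path)
  expect_error(read_gene_models(path), "1-based")
})

test_that("GTF coordinate conversion agrees with rtracklayer", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tgene_id "gA";',
    'chr3\tsrc\tCDS\t7\t1000\t.\t-\t0\tgene_id "gC";'
  ), path)
  gm <- read_gene_models(path)
  gr <- rtracklayer::import(path)
  # rtracklayer keeps 1-based closed; our start is GRanges start - 1
  ref <- data.frame(
    name = as.character(gr$gene_id),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr)
  )
  ref <- ref[order(ref$name), ]
  got <- as.data.frame(gm[order(gm$name), c("name", "start", "end")])
  expect_equal(got, ref, ignore_attr = TRUE)
})

test_that("gene models from equivalent BED6 and GTF are identical", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    'chr1\tsrc\tCDS\t1001\t2000\t.\t+\t0\tgene_id "gA";',
    'chr2\tsrc\tCDS\t501\t900\t.\t-\t0\tgene_id "gB";'
  ), gtf)
  writeLines(c(
    "chr1\t1000\t2000\tgA\t0\t+",
    "chr2\t500\t900\tgB\t0\t-"
  ), bed)
  from_gtf <- read_gene_models(gtf)
  from_bed <- read_gene_models(bed)
  cols <- c("chrom", "start", "end", "name", "strand")
  expect_equal(
    as.data.frame(from_gtf[order(from_gtf$name), cols]),
    as.data.frame(from_bed[order(from_bed$name), cols]),
    ignore_attr = TRUE
  )
})

test_that("survival and DE table readers enforce their invariants", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttime\tevent", "s1\t10\t1", "s2\t5\t0"), p)
  st <- read_survival(p)
  expect_equal(st$event, c(1L, 0L))
  writeLines(c("sample_id\ttime\tevent", "s1\t-1\t1"), p)
  expect_error(read_survival(p), ">= 0")
  writeLines(c("sample_id\ttime\tevent", "s1\t1\t1", "s1\t2\t0"), p)
  expect_error(read_survival(p), "duplicated")

  writeLines(c("gene\tlogFC\tfdr", "g1\t2\t0.01"), p)
  expect_equal(read_de_table(p)$logFC, 2)
  writeLines(c("gene\tlogFC\tfdr", "g1\t2\t1.5"), p)
  expect_error(read_de_table(p), "fdr")
})
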