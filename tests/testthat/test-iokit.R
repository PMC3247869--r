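# file dialects and domain containers

test_that("homology reader drops capped hits and collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_gene\torganism\tref_gene\te_value\tcoverage_pct",
               "g1\torgA\tr1\t1e-6\t80",
               "g1\torgA\tr1\t1e-9\t70",
               "g2\torgA\tr2\t0.5\t90",
               "g3\torgB\tr3\t2\t60"), f)
  h <- read_homology_table(f, e_cap = 1)
  expect_equal(nrow(h), 2L)        # E=2 dropped, duplicate g1 collapsed
  hit <- h[h$target_gene == "g1", ]
  expect_equal(hit$e_value, 1e-9)                 # min-E rule
  expect_equal(hit$coverage_pct, 80)              # max-coverage rule
})

test_that("malformed homology rows error with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_gene\torganism\tref_gene\te_value\tcoverage_pct",
               "g1\torgA\tr1\t1e-6\t80",
               "g2\torgA\tr2\t-1\t90"), f)
  expect_error(read_homology_table(f), "line 3")
})

test_that("annotation ranks follow start coordinates with the id tie rule", {
  ann <- tiny_annotation(starts = c(10, 200, 500, 900),
                         ends = c(100, 300, 600, 950),
                         strands = c("+", "+", "-", "+"))
  expect_equal(ann$genes$rank, 1:4)
  # equal starts: lexicographically smaller id gets the lower rank
  ann2 <- genome_annotation(
    data.frame(gene_id = c("b0002", "b0001"), organism = "orgA",
               replicon_id = "chr", start = c(50, 50), end = c(90, 95),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(replicon_id = "chr", organism = "orgA",
               length_bases = 200L, circular = TRUE))
  expect_equal(ann2$genes$gene_id[ann2$genes$rank == 1], "b0001")
  # two replicons rank independently
  g3 <- data.frame(gene_id = c("a1", "a2", "b1"), organism = "orgA",
                   replicon_id = c("chr1", "chr1", "chr2"),
                   start = c(10, 50, 30), end = c(20, 60, 40),
                   strand = "+", stringsAsFactors = FALSE)
  r3 <- data.frame(replicon_id = c("chr1", "chr2"), organism = "orgA",
                   length_bases = 100L, circular = FALSE)
  ann3 <- genome_annotation(g3, r3)
  expect_equal(ann3$genes$rank[ann3$genes$gene_id == "b1"], 1L)
})

test_that("missing strand is rejected", {
  expect_error(tiny_annotation(10, 20, "."), "strand")
})

test_that("annotation TSV dialect round-trips", {
  w <- cached_world()
  ann <- w$annotations[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, f)
  back <- read_annotation(f, dialect = "tsv")
  expect_equal(back$genes, ann$genes)
  expect_equal(back$replicons, ann$replicons)
})

test_that("gff3 reader picks up genes, lengths and circularity", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 5000",
               paste("chr1", "src", "region", "1", "5000", ".", "+", ".",
                     "ID=chr1;Is_circular=true", sep = "\t"),
               paste("chr1", "src", "gene", "100", "400", ".", "+", ".",
                     "ID=gA", sep = "\t"),
               paste("chr1", "src", "gene", "600", "900", ".", "-", ".",
                     "ID=gB", sep = "\t")), f)
  ann <- read_annotation(f, dialect = "gff3", organism = "orgX")
  expect_equal(ann$genes$gene_id, c("gA", "gB"))
  expect_equal(ann$genes$rank, c(1L, 2L))
  expect_true(ann$replicons$circular)
  expect_equal(ann$replicons$length_bases, 5000L)
})

test_that("pair score writer/reader round-trips and honors the NA flag", {
  g <- c("g1", "g2", "g3")
  m <- matrix(c(NA, 1, 2, 1, NA, NA, 2, NA, NA), 3, 3,
              dimnames = list(g, g))
  sm <- score_matrix(m, method = "toy")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_scores(sm, f, missing = "omit")
  expect_equal(nrow(utils::read.table(f, header = TRUE)), 2L)
  back <- read_pair_scores(f, genes = g)
  expect_equal(back["g1", "g2"], 1)
  expect_equal(back["g1", "g3"], 2)
  expect_true(is.na(back["g2", "g3"]))
  write_pair_scores(sm, f, missing = "na")
  expect_equal(nrow(utils::read.table(f, header = TRUE)), 3L)
  back2 <- read_pair_scores(f, genes = g)
  expect_equal(unclass(back2), unclass(back), ignore_attr = TRUE)
})

test_that("full 3-gene matrix writes n(n-1)/2 rows", {
  g <- c("a", "b", "c")
  m <- matrix(1, 3, 3, dimnames = list(g, g))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_scores(score_matrix(m), f)
  expect_equal(nrow(utils::read.table(f, header = TRUE)), 3L)
})

test_that("label file rejects self pairs and duplicates", {
  expect_error(pair_labels(data.frame(gene_a = "g1", gene_b = "g1",
                                      label = "positive")), "self-pair")
  expect_error(pair_labels(data.frame(gene_a = c("g1", "g2"),
                                      gene_b = c("g2", "g1"),
                                      label = "positive")), "duplicate")
  f <- withr::local_tempfile(fileext = ".tsv")
  lb <- pair_labels(data.frame(gene_a = c("g2", "g1"),
                               gene_b = c("g3", "g2"),
                               label = c("negative", "positive")))
  write_pair_labels(lb, f)
  expect_equal(read_pair_labels(f), lb)
})
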