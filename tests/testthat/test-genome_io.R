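test_that("gene-order tables round-trip through write and read", {
  g1 <- new_genome("gen_b", list(
    list(replicon_id = "chr", topology = "circular",
         cog = c("c1", "c2", "c3", "c4"), strand = c("+", "-", "-", "+")),
    list(replicon_id = "pA", topology = "linear",
         cog = c("p1", "p2"), strand = c("-", "-"))))
  g2 <- genome("gen_a", c("c1", "c2", "c5"), topology = "circular")
  ds <- clade_dataset("CL01", list(g1, g2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_order_table(ds, path)
  back <- read_gene_order_table(path, clade_id = "CL01")
  expect_equal(back$clade_id, ds$clade_id)
  expect_equal(back$genomes, ds$genomes)
})

test_that("reader validates structure and reports offending coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # position gap 0,1,3
  writeLines(c("genome_id\treplicon_id\ttopology\tposition\tstrand\tcog_id",
               "G1\tchr\tcircular\t0\t+\ta",
               "G1\tchr\tcircular\t1\t+\tb",
               "G1\tchr\tcircular\t3\t+\tc"), path)
  expect_error(read_gene_order_table(path), "gapless")
  expect_error(read_gene_order_table(path), "G1")
  # unknown topology token
  writeLines(c("genome_id\treplicon_id\ttopology\tposition\tstrand\tcog_id",
               "G1\tchr\tround\t0\t+\ta"), path)
  expect_error(read_gene_order_table(path), "topology")
  # missing column
  writeLines(c("genome_id\treplicon_id\ttopology\tposition\tstrand",
               "G1\tchr\tcircular\t0\t+"), path)
  expect_error(read_gene_order_table(path), "cog_id")
})

test_that("a two-genome table reads fine; size filtering is separate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_table(path, list(
    list(genome = "G1", replicon = "chr", topology = "circular",
         cogs = c("a", "b", "c")),
    list(genome = "G2", replicon = "chr", topology = "circular",
         cogs = c("a", "c", "d"))))
  ds <- read_gene_order_table(path)
  expect_length(ds$genomes, 2L)
  expect_length(filter_clades(list(ds)), 0L)
})

test_that("clique reduction keeps one representative per content class", {
  mk <- function(id, cogs) genome(id, cogs)
  # G2 and G4 have identical COG multisets in different orders
  ds <- clade_dataset("CL", list(mk("G3", c("a", "b", "c")),
                                 mk("G4", c("b", "a", "a")),
                                 mk("G1", c("a", "b", "d")),
                                 mk("G2", c("a", "a", "b"))))
  red <- reduce_cliques(ds)
  expect_length(red$genomes, 3L)
  expect_equal(names(red$genomes), c("G3", "G1", "G2"))  # G2 < G4 represents

  # brute-force oracle: pairwise multiset equality
  eq <- function(x, y) identical(sort(genome_cogs(x)), sort(genome_cogs(y)))
  for (i in seq_along(red$genomes))
    for (j in seq_along(red$genomes))
      if (i < j) expect_false(eq(red$genomes[[i]], red$genomes[[j]]))

  expect_equal(reduce_cliques(red)$genomes, red$genomes)  # idempotent

  distinct <- clade_dataset("CL", list(mk("G1", c("a", "b")),
                                       mk("G2", c("a", "c"))))
  expect_equal(reduce_cliques(distinct)$genomes, distinct$genomes)

  all_same <- clade_dataset("CL", list(mk("G2", c("a", "b")),
                                       mk("G1", c("b", "a")),
                                       mk("G3", c("a", "b"))))
  expect_equal(names(reduce_cliques(all_same)$genomes), "G1")
})

test_that("clade filtering applies the size threshold and exclusion list", {
  mk <- function(id, n) clade_dataset(id, lapply(seq_len(n), function(i)
    genome(sprintf("%s_g%d", id, i), letters[1:3])))
  sets <- list(mk("C2", 2L), mk("C3", 3L), mk("C5", 5L))
  expect_length(filter_clades(sets), 2L)
  expect_length(filter_clades(sets, min_genomes = 4L), 1L)
  expect_equal(vapply(filter_clades(sets, exclude_ids = "C5"), `[[`, "",
                      "clade_id"), "C3")
  expect_length(filter_clades(list()), 0L)
  # never increases counts
  expect_lte(length(filter_clades(sets)), length(sets))
})
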