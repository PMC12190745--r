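test_that("gene content distance follows the log-corrected shared fraction", {
  a <- genome("A", sprintf("c%02d", 1:20))
  expect_equal(gene_content_distance(a, a)$gcd, 0)

  # N_A = N_B = 20, N_AB = 10 -> -ln(10 / sqrt(400)) = ln 2
  b <- genome("B", sprintf("%s%02d", rep(c("c", "x"), c(10, 10)),
                           c(1:10, 1:10)))
  gc <- gene_content_distance(a, b)
  expect_equal(gc$n_shared, 10L)
  expect_equal(gc$gcd, log(2), tolerance = 1e-12)

  # symmetry, and copy number ignored
  a2 <- genome("A2", c(sprintf("c%02d", 1:20), "c01", "c01"))
  expect_equal(gene_content_distance(a2, b)$gcd, gc$gcd)
  expect_equal(gene_content_distance(b, a)$gcd, gc$gcd)

  disjoint <- genome("D", c("z1", "z2"))
  expect_error(gene_content_distance(a, disjoint), "share no COGs")
})

test_that("common complement keeps shared single-copy genes in order", {
  a <- genome("A", c("x", "p", "q", "r"), topology = "linear")
  b <- genome("B", c("p", "q", "r", "y"), topology = "linear")
  red <- common_complement(a, b)
  expect_equal(genome_cogs(red$a), c("p", "q", "r"))
  expect_equal(genome_cogs(red$b), c("p", "q", "r"))

  # duplicated shared COG removed from both sides
  a2 <- genome("A", c("p", "q", "p", "r"), topology = "linear")
  red2 <- common_complement(a2, b)
  expect_equal(genome_cogs(red2$a), c("q", "r"))
  expect_equal(genome_cogs(red2$b), c("q", "r"))
  # brute-force oracle: every kept cog occurs exactly once on each side
  for (g in red2) {
    tab <- table(genome_cogs(g))
    expect_true(all(tab == 1L))
  }

  same <- common_complement(a, a)
  expect_equal(genome_cogs(same$a), genome_cogs(a))

  expect_error(common_complement(genome("A", c("u", "u")),
                                 genome("B", c("u", "v"))),
               "single-copy")
})

test_that("synteny blocks are maximal shared-adjacency runs", {
  lin <- function(id, cogs) genome(id, as.character(cogs), topology = "linear")
  # one internal breakpoint, reversal does not break
  sbl <- extract_synteny_blocks(lin("A", 1:6), lin("B", c(1, 2, 3, 6, 5, 4)))
  expect_equal(as.numeric(sbl$counts), 2)
  expect_equal(names(sbl$counts), "3")

  # no shared adjacencies: all singletons
  sbl2 <- extract_synteny_blocks(lin("A", 1:4), lin("B", c(3, 1, 4, 2)))
  expect_equal(unname(sbl2$counts["1"]), 4)
  expect_equal(mean_sbl(sbl2), 1)

  # identical circular genomes: a single wrap-around block
  ca <- genome("A", as.character(1:10))
  sbl3 <- extract_synteny_blocks(ca, genome("B", as.character(c(4:10, 1:3))))
  expect_equal(sbl3$counts, setNames(1, "10"))

  # inputs that were not reduced are rejected
  expect_error(extract_synteny_blocks(lin("A", c(1, 1, 2)), lin("B", 1:2)),
               "common_complement")
})

test_that("blocks partition the shared genes and are symmetric in the pair", {
  for (s in 1:5) {
    sim <- simulate_jumps(400, 80, topology = "circular", seed = s)
    red <- common_complement(sim$ancestral, sim$derived)
    ab <- extract_synteny_blocks(red$a, red$b)
    ba <- extract_synteny_blocks(red$b, red$a)
    expect_equal(ab$counts, ba$counts)
    k <- as.numeric(names(ab$counts))
    expect_equal(sum(k * ab$counts), genome_size(red$a))
  }
})

test_that("mean block length shrinks as translocations accumulate", {
  mean_at <- function(jumps) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_jumps(2000, jumps, seed = s + 100 * jumps)
      mean_sbl(extract_synteny_blocks(sim$ancestral, sim$derived))
    }, 0))
  }
  m <- vapply(c(50L, 200L, 800L), mean_at, 0)
  expect_true(all(diff(m) < 0))
})

test_that("mean SBL matches its definition on simple tallies", {
  expect_equal(mean_sbl(sbl_distribution(c(3, 3))), 3)
  expect_equal(mean_sbl(sbl_distribution(rep(1L, 17))), 1)
  expect_equal(mean_sbl(sbl_distribution(10L)), 10)
  expect_error(sbl_distribution(integer(0)), "empty")
})

test_that("all unordered pairs are compared and degenerate pairs flagged", {
  set.seed(42)
  anc <- make_ancestor(200)
  gs <- lapply(1:5, function(i) {
    g <- evolve_branch(anc, 5, 5, 2, branch_id = sprintf("g%02d", i))
    g$genome_id <- sprintf("G%d", i)
    g
  })
  expect_length(compare_all_pairs(clade_dataset("C", gs[1:3])), 3L)
  pairs <- compare_all_pairs(clade_dataset("C", gs))
  expect_length(pairs, 10L)
  expect_true(all(vapply(pairs, `[[`, NA, "usable")))

  # an identical pair (content clique) is reported but unusable
  dup <- gs[1:3]
  dup[[3L]] <- gs[[1L]]
  dup[[3L]]$genome_id <- "G1copy"
  pairs2 <- compare_all_pairs(clade_dataset("C", dup))
  flagged <- Filter(function(p) !p$usable, pairs2)
  expect_length(flagged, 1L)
  expect_match(flagged[[1L]]$note, "gcd = 0")
})
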