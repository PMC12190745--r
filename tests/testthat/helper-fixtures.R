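# Small in-code fixtures shared across test files.

# A genome pair whose observed SBL equals the (truncated) model pmf at
# lam = q * d: the exact self-consistency input for the fitters.
model_exact_pair <- function(d, lam, n_genes_used = 2000L,
                             ids = c("A", "B")) {
  tab <- jump_model_table(lam, kmax = 2L * n_genes_used)
  sbl <- sbl_distribution(setNames(tab$pmf, tab$k), counted = TRUE)
  structure(list(clade_id = "FIX", genome_a = ids[1L], genome_b = ids[2L],
                 n_a = n_genes_used, n_b = n_genes_used,
                 n_shared = n_genes_used, gcd = d, sbl = sbl,
                 mean_sbl = mean_sbl(sbl), n_genes_used = n_genes_used,
                 usable = TRUE, note = ""),
            class = "pair_comparison")
}

# Pair whose observed distribution is fully scrambled (all blocks length 1).
scrambled_pair <- function(n = 500L, d = 0.1) {
  sbl <- sbl_distribution(rep(1L, n))
  structure(list(clade_id = "FIX", genome_a = "A", genome_b = "B",
                 n_a = n, n_b = n, n_shared = n, gcd = d, sbl = sbl,
                 mean_sbl = 1, n_genes_used = n, usable = TRUE, note = ""),
            class = "pair_comparison")
}

# Write a tiny gene-order table; rows are (genome, replicon, topology,
# cogs-in-order).
write_toy_table <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(genome_id = r$genome, replicon_id = r$replicon,
               topology = r$topology, position = seq_along(r$cogs) - 1L,
               strand = rep_len(c("+", "-"), length(r$cogs)),
               cog_id = r$cogs, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Empirical block-length pmf of ancestor vs derived pooled over seeds.
pooled_sim_pmf <- function(n_genes, lam, seeds) {
  counts <- numeric(0)
  for (s in seeds) {
    sim <- simulate_jumps(n_genes, round(lam * n_genes), seed = s)
    sbl <- extract_synteny_blocks(sim$ancestral, sim$derived)
    k <- as.integer(names(sbl$counts))
    m <- max(length(counts), max(k))
    counts <- c(counts, numeric(m - length(counts)))
    counts[k] <- counts[k] + as.numeric(sbl$counts)
  }
  counts / sum(counts)
}
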