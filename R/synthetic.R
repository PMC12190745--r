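#' Generate an ancestral genome
#'
#' One replicon of `n_genes` unique COGs (`anc000000`, `anc000001`, ...)
#' with alternating strands (strand is carried but ignored by all
#' comparisons).
#'
#' @param n_genes Positive integer.
#' @param topology `"circular"` (default, the prokaryote chromosome case)
#'   or `"linear"`.
#' @param seed Optional integer seed (the construction is deterministic;
#'   the seed only anchors downstream use of the RNG).
#' @param genome_id Genome label.
#' @return A `genome`.
#' @export
make_ancestor <- function(n_genes, topology = "circular", seed = NULL,
                          genome_id = "ancestor") {
  if (n_genes < 1L) stop("'n_genes' must be positive")
  if (!is.null(seed)) set.seed(seed)
  genome(genome_id, sprintf("anc%06d", seq_len(n_genes) - 1L),
         topology = topology,
         strand = rep_len(c("+", "-"), n_genes))
}

#' Evolve a genome along one branch
#'
#' Applies gene losses (uniformly chosen genes deleted), gains (brand-new
#' unique COGs inserted at uniform positions — re-gain of a previously
#' present gene is not modelled, matching the view that a horizontally
#' acquired gene is usually new to the genome), single-gene jumps (as in
#' [simulate_jumps()]) and, optionally, segmental inversions (a uniformly
#' placed segment of geometric length is reversed; an out-of-model
#' confounder, never part of the fitted process). Events are applied in
#' uniformly shuffled order.
#'
#' @param g A `genome`.
#' @param n_loss,n_gain,n_jumps,n_inversions Event counts.
#' @param seed Optional integer seed.
#' @param branch_id Label used to make gained COG ids unique across
#'   branches and in the derived genome id.
#' @param inversion_mean_length Mean of the geometric inversion segment
#'   length (default 50 genes, segmental scale: operon-scale segments are
#'   statistically equivalent to pairs of single-gene jumps and carry no
#'   diagnostic signal against the jump model).
#' @return The evolved `genome`.
#' @export
evolve_branch <- function(g, n_loss = 0L, n_gain = 0L, n_jumps = 0L,
                          n_inversions = 0L, seed = NULL,
                          branch_id = "b1", inversion_mean_length = 50) {
  stopifnot(inherits(g, "genome"))
  if (!is.null(seed)) set.seed(seed)
  if (n_loss >= genome_size(g))
    stop("cannot lose ", n_loss, " genes from a genome of ",
         genome_size(g))
  reps <- lapply(g$replicons, function(r) r[c("replicon_id", "topology",
                                              "cog", "strand")])
  events <- sample(rep(c("loss", "gain", "jump", "inv"),
                       c(n_loss, n_gain, n_jumps, n_inversions)))
  gain_counter <- 0L

  pick_gene <- function() {
    sizes <- vapply(reps, function(r) length(r$cog), 1L)
    ri <- sample.int(length(reps), 1L, prob = sizes)
    list(ri = ri, pos = sample.int(sizes[ri], 1L))
  }
  n_slots <- function(r) length(r$cog) + (r$topology == "linear")
  insert_at <- function(cog, strand) {
    slots <- vapply(reps, n_slots, 1L)
    ri <- sample.int(length(reps), 1L, prob = slots)
    # slot s means: insert after position s - 1 (s = 1 is the front; on a
    # circular replicon the front and the end are the same slot)
    s <- sample.int(slots[ri], 1L)
    r <- reps[[ri]]
    r$cog <- append(r$cog, cog, after = s - 1L)
    r$strand <- append(r$strand, strand, after = s - 1L)
    reps[[ri]] <<- r
  }

  for (ev in events) {
    if (ev == "loss") {
      p <- pick_gene()
      if (length(reps[[p$ri]]$cog) == 1L && length(reps) == 1L)
        stop("branch events would empty the genome")
      reps[[p$ri]]$cog <- reps[[p$ri]]$cog[-p$pos]
      reps[[p$ri]]$strand <- reps[[p$ri]]$strand[-p$pos]
    } else if (ev == "gain") {
      gain_counter <- gain_counter + 1L
      insert_at(sprintf("%s_gain%05d", branch_id, gain_counter),
                sample(c("+", "-"), 1L))
    } else if (ev == "jump") {
      p <- pick_gene()
      cog <- reps[[p$ri]]$cog[p$pos]
      strand <- reps[[p$ri]]$strand[p$pos]
      reps[[p$ri]]$cog <- reps[[p$ri]]$cog[-p$pos]
      reps[[p$ri]]$strand <- reps[[p$ri]]$strand[-p$pos]
      insert_at(cog, strand)
    } else { # inversion
      sizes <- vapply(reps, function(r) length(r$cog), 1L)
      ri <- sample.int(length(reps), 1L, prob = sizes)
      m <- sizes[ri]
      len <- min(m, 1L + rgeom(1L, prob = 1 / inversion_mean_length))
      start <- sample.int(m - len + 1L, 1L)
      span <- start:(start + len - 1L)
      reps[[ri]]$cog[span] <- rev(reps[[ri]]$cog[span])
      reps[[ri]]$strand[span] <- chartr("+-", "-+",
                                        rev(reps[[ri]]$strand[span]))
    }
  }
  new_genome(paste0(g$genome_id, "_", branch_id), reps)
}

# Unbiased stochastic rounding: floor(x) + Bernoulli(frac(x)).
.stoch_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (runif(length(x)) < (x - fl)))
}

#' Generate a synthetic clade with known rearrangement-to-flux ratio
#'
#' Emulates an ATGC-like clade on a star tree: one ancestor evolved
#' independently along `n_genomes` branches with balanced gains and
#' losses and single-gene jumps. Branch flux loads are drawn so pairwise
#' gene content distances land in `d_range` (each branch contributes half
#' a pairwise distance), and each branch receives `q_true` jumps per
#' gain-loss pair, so every pair satisfies \eqn{\lambda = q \cdot d} in
#' expectation. A star tree suffices because the analysis is purely
#' pairwise. `inversion_rate` adds Poisson-many segmental inversions per
#' branch (`rate` per gain-loss pair) as an out-of-model confounder.
#'
#' @param n_genes Ancestral genome size (>= 500 recommended for the
#'   asymptotic model regime).
#' @param n_genomes Number of descendant genomes, at least 3.
#' @param q_true Ground-truth rearrangement-to-flux ratio.
#' @param d_range Target interval of pairwise gene content distances.
#' @param topology Replicon topology, default `"circular"`.
#' @param inversion_rate Expected inversions per gain-loss pair,
#'   default 0 (the jump-model conditions).
#' @param inversion_mean_length Mean inversion segment length, see
#'   [evolve_branch()].
#' @param seed Integer seed; the full clade is reproducible.
#' @param clade_id Clade label.
#' @return List with `dataset` (a [clade_dataset()]) and `truth` (the
#'   ground-truth record: `q_true`, per-branch event counts, seed).
#' @examples
#' clade <- make_clade(n_genes = 500, n_genomes = 3, q_true = 0.2, seed = 1)
#' clade$dataset
#' @export
make_clade <- function(n_genes = 3000L, n_genomes = 6L, q_true = 0.1,
                       d_range = c(0.02, 0.1), topology = "circular",
                       inversion_rate = 0, inversion_mean_length = 50,
                       seed = 1L, clade_id = "SYN001") {
  if (n_genomes < 3L) stop("'n_genomes' must be at least 3")
  if (q_true <= 0) stop("'q_true' must be positive")
  if (d_range[1L] <= 0 || d_range[2L] > 0.5 || d_range[1L] > d_range[2L])
    stop("'d_range' must lie within (0, 0.5]")
  if (d_range[1L] / 2 * n_genes < 1)
    stop("'d_range' infeasible for 'n_genes': less than one event per branch")
  if (d_range[2L] * n_genes >= n_genes / 2)
    stop("'d_range' infeasible: branches would erode most of the genome")
  set.seed(seed)
  anc <- make_ancestor(n_genes, topology = topology)
  b <- runif(n_genomes, d_range[1L] / 2, d_range[2L] / 2)
  losses <- pmax(1L, .stoch_round(b * n_genes))
  gains <- losses                               # balanced flux
  jumps <- .stoch_round(q_true * losses)
  invs <- if (inversion_rate > 0) rpois(n_genomes, inversion_rate * losses)
          else integer(n_genomes)
  genomes <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    genomes[[i]] <- evolve_branch(anc, n_loss = losses[i], n_gain = gains[i],
                                  n_jumps = jumps[i], n_inversions = invs[i],
                                  branch_id = sprintf("g%02d", i),
                                  inversion_mean_length = inversion_mean_length)
    genomes[[i]]$genome_id <- sprintf("%s_g%02d", clade_id, i)
  }
  list(dataset = clade_dataset(clade_id, genomes,
                               provenance = sprintf("synthetic, seed %d", seed)),
       truth = list(q_true = q_true, losses = losses, gains = gains,
                    jumps = jumps, inversions = invs, seed = seed,
                    branch_d = b))
}

#' Generate a synthetic COG presence matrix with per-clade ratios
#'
#' Emulates the cross-clade screen input: per-COG presence fractions that
#' are mostly 0 or 1 across clades (a COG is usually in all genomes of a
#' clade or in none) and log-normally distributed rearrangement-to-flux
#' ratios. If `effect_cog` is set, that COG's presence multiplies the
#' clade's ratio by `effect_factor` (the alternative hypothesis for power
#' checks).
#'
#' @param n_clades Number of clades (rows), at least 10.
#' @param n_cogs Number of COGs (columns).
#' @param effect_cog Optional column index carrying a real effect.
#' @param effect_factor Multiplicative shift of the ratio where the
#'   effect COG is present, default 4.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the ratios (defaults:
#'   median 0.13, sdlog 1).
#' @return List with `presence` (matrix clade x cog of fractions in
#'   `[0, 1]`) and `q_values`.
#' @export
make_presence_matrix <- function(n_clades = 139L, n_cogs = 50L,
                                 effect_cog = NULL, effect_factor = 4,
                                 seed = 1L, meanlog = log(0.13), sdlog = 1) {
  if (n_clades < 10L) stop("'n_clades' must be at least 10")
  set.seed(seed)
  p_c <- runif(n_cogs, 0.15, 0.85)
  # the planted determinant segregates evenly across clades; at extreme
  # base rates no effect size can reach a strong rank correlation
  if (!is.null(effect_cog)) p_c[effect_cog] <- 0.5
  presence <- matrix(rbinom(n_clades * n_cogs, 1L, rep(p_c, each = n_clades)),
                     nrow = n_clades, ncol = n_cogs,
                     dimnames = list(sprintf("clade%03d", seq_len(n_clades)),
                                     sprintf("COG%04d", seq_len(n_cogs))))
  # a few partially-present COGs, as in real clades
  frac <- runif(n_clades * n_cogs) < 0.03
  presence[frac] <- round(runif(sum(frac)), 2)
  q_values <- rlnorm(n_clades, meanlog = meanlog, sdlog = sdlog)
  if (!is.null(effect_cog)) {
    if (effect_cog < 1L || effect_cog > n_cogs) stop("'effect_cog' out of range")
    q_values <- q_values * effect_factor^presence[, effect_cog]
  }
  list(presence = presence, q_values = q_values)
}
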