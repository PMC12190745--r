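#' Gene content distance between two genomes
#'
#' The log-corrected fraction of shared ortholog clusters,
#' \deqn{d_{A,B} = -\ln\frac{N_{A,B}}{\sqrt{N_A N_B}},}
#' where \eqn{N_A}, \eqn{N_B} are the numbers of distinct COGs in each
#' genome and \eqn{N_{A,B}} the number shared. Copy number is ignored
#' (each COG counted once), so paralogy does not affect the distance. At
#' short distances the GCD approximates gains + losses per gene and serves
#' as a clade-local clock.
#'
#' @param a,b `genome` objects.
#' @return List with `n_a`, `n_b`, `n_shared` and `gcd`.
#' @examples
#' a <- genome("A", letters[1:4]); b <- genome("B", letters[3:6])
#' gene_content_distance(a, b)$gcd
#' @export
gene_content_distance <- function(a, b) {
  ca <- unique(genome_cogs(a))
  cb <- unique(genome_cogs(b))
  ns <- length(intersect(ca, cb))
  if (ns == 0L)
    stop("genomes '", a$genome_id, "' and '", b$genome_id,
         "' share no COGs; gene content distance is undefined")
  list(n_a = length(ca), n_b = length(cb), n_shared = ns,
       gcd = -log(ns / sqrt(as.numeric(length(ca)) * length(cb))))
}

#' Reduce two genomes to their shared single-copy gene complement
#'
#' Genes whose COG is absent from the other genome are removed, as are
#' COGs present in more than one copy in either genome (multi-copy COGs
#' make block identity ambiguous; dropping them yields a clean bijection
#' between the reduced genomes, consistent with ignoring paralogy in the
#' content comparison). Relative order within each replicon is preserved
#' and empty replicons are dropped.
#'
#' @param a,b `genome` objects.
#' @return List with reduced genomes `a` and `b`.
#' @export
common_complement <- function(a, b) {
  ta <- cog_multiset(a)
  tb <- cog_multiset(b)
  keep <- intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])
  if (length(keep) == 0L)
    stop("genomes '", a$genome_id, "' and '", b$genome_id,
         "' share no single-copy COGs")
  strip <- function(g) {
    reps <- lapply(g$replicons, function(r) {
      sel <- r$cog %in% keep
      if (!any(sel)) return(NULL)
      list(replicon_id = r$replicon_id, topology = r$topology,
           cog = r$cog[sel], strand = r$strand[sel])
    })
    new_genome(g$genome_id, reps[!vapply(reps, is.null, NA)])
  }
  list(a = strip(a), b = strip(b))
}

# Unordered adjacency codes of a genome over a fixed cog universe.
# Circular replicons contribute the wrap-around adjacency; a replicon of
# one gene contributes none.
.adjacency_codes <- function(g, universe) {
  n <- length(universe)
  unlist(lapply(g$replicons, function(r) {
    idx <- match(r$cog, universe)
    m <- length(idx)
    if (m < 2L) return(numeric(0))
    x <- idx
    y <- c(idx[-1L], if (r$topology == "circular") idx[1L])
    x2 <- pmin(x[seq_along(y)], y)
    y2 <- pmax(x[seq_along(y)], y)
    x2 * (n + 1) + y2
  }), use.names = FALSE)
}

#' Syntenic block lengths of a reduced genome pair
#'
#' A syntenic block is a maximal run of genes consecutive in both genomes,
#' regardless of orientation (adjacency is an unordered pair of COGs
#' occupying neighbouring positions on the same replicon). Degenerate
#' blocks of one gene count. On circular replicons the adjacency across
#' the origin counts and blocks may wrap; blocks never span replicon
#' boundaries. Inputs must come from [common_complement()] so that every
#' COG occurs exactly once in each genome; the result is then symmetric in
#' the two genomes.
#'
#' @param reduced_a,reduced_b `genome` objects sharing the same single-copy
#'   COG set.
#' @return An object of class `sbl_distribution`.
#' @examples
#' a <- genome("A", as.character(1:6), topology = "linear")
#' b <- genome("B", as.character(c(1, 2, 3, 6, 5, 4)), topology = "linear")
#' extract_synteny_blocks(a, b)$counts
#' @export
extract_synteny_blocks <- function(reduced_a, reduced_b) {
  universe <- genome_cogs(reduced_a)
  cb <- genome_cogs(reduced_b)
  if (length(universe) != length(cb) ||
      anyDuplicated(universe) || anyDuplicated(cb) ||
      !setequal(universe, cb))
    stop("inputs must be reduced to a shared single-copy complement; ",
         "call common_complement() first")
  codes_b <- .adjacency_codes(reduced_b, universe)

  lengths <- unlist(lapply(reduced_a$replicons, function(r) {
    m <- length(r$cog)
    if (m == 1L) return(1L)
    idx <- match(r$cog, universe)
    circ <- r$topology == "circular"
    x <- idx
    y <- c(idx[-1L], if (circ) idx[1L])
    x1 <- pmin(x[seq_along(y)], y)
    y1 <- pmax(x[seq_along(y)], y)
    conserved <- (x1 * (length(universe) + 1) + y1) %in% codes_b
    if (circ) {
      breaks <- which(!conserved)            # edge i joins gene i and i+1 (mod m)
      if (!length(breaks)) return(m)         # fully conserved circle: one block
      diff(c(breaks, breaks[1L] + m))        # arc lengths between breaks
    } else {
      diff(c(0L, which(!conserved), m))      # linear: cut at broken edges
    }
  }), use.names = FALSE)
  sbl_distribution(lengths)
}

#' Syntenic block length distribution
#'
#' Tallies block lengths into counts and a normalized probability mass
#' function. `counts` may be non-integer weights (e.g. an expected
#' distribution) as long as they are non-negative.
#'
#' @param lengths Vector of block lengths (positive integers), or a named
#'   numeric vector of counts when `counted = TRUE` (names are the block
#'   lengths).
#' @param counted Set `TRUE` if `lengths` already holds counts keyed by
#'   block length.
#' @return Object of class `sbl_distribution` with elements `counts`
#'   (named, ascending k), `total_blocks` and `pmf`.
#' @export
sbl_distribution <- function(lengths, counted = FALSE) {
  if (counted) {
    k <- as.integer(names(lengths))
    if (anyNA(k) || any(k < 1L)) stop("block lengths must be positive integers")
    counts <- as.numeric(lengths)
    ord <- order(k)
    k <- k[ord]; counts <- counts[ord]
    keep <- counts > 0
    k <- k[keep]; counts <- counts[keep]
  } else {
    if (!length(lengths)) stop("empty block length vector")
    if (any(lengths < 1L)) stop("block lengths must be positive integers")
    tab <- table(lengths)
    k <- as.integer(names(tab))
    counts <- as.numeric(tab)
  }
  if (!length(k)) stop("empty block length distribution")
  total <- sum(counts)
  structure(list(counts = setNames(counts, k), total_blocks = total,
                 pmf = setNames(counts / total, k)),
            class = "sbl_distribution")
}

#' @export
print.sbl_distribution <- function(x, ...) {
  cat(sprintf("<sbl_distribution> %s blocks, mean length %.3f, max %s\n",
              format(x$total_blocks), mean_sbl(x),
              names(x$counts)[length(x$counts)]))
  invisible(x)
}

# Dense pmf vector over support 1..max(k).
.sbl_pmf_vector <- function(sbl) {
  k <- as.integer(names(sbl$pmf))
  out <- numeric(max(k))
  out[k] <- sbl$pmf
  out
}

#' Mean syntenic block length
#'
#' Ranges from the full (reduced) genome length for identical gene orders
#' down to 1 for completely scrambled pairs.
#'
#' @param sbl An `sbl_distribution`.
#' @return Mean block length.
#' @export
mean_sbl <- function(sbl) {
  stopifnot(inherits(sbl, "sbl_distribution"))
  if (sbl$total_blocks <= 0) stop("empty block length distribution")
  k <- as.numeric(names(sbl$counts))
  sum(k * sbl$counts) / sbl$total_blocks
}

#' Compare all genome pairs within a clade
#'
#' For every unordered pair, computes the gene content distance, reduces
#' the pair to its shared single-copy complement and extracts the syntenic
#' block length distribution. Pairs that cannot inform the model fit
#' (identical content, no usable shared genes) are reported with
#' `usable = FALSE` rather than dropped silently.
#'
#' @param dataset A [clade_dataset()] (after preprocessing).
#' @return List of `pair_comparison` objects. Use [pairs_table()] for a
#'   tabular summary.
#' @export
compare_all_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "clade_dataset"))
  ids <- names(dataset$genomes)
  if (length(ids) < 2L) stop("need at least two genomes to compare")
  idx <- combn(length(ids), 2L)
  out <- vector("list", ncol(idx))
  for (j in seq_len(ncol(idx))) {
    a <- dataset$genomes[[idx[1L, j]]]
    b <- dataset$genomes[[idx[2L, j]]]
    pc <- list(clade_id = dataset$clade_id,
               genome_a = a$genome_id, genome_b = b$genome_id,
               n_a = NA_integer_, n_b = NA_integer_,
               n_shared = NA_integer_, gcd = NA_real_,
               sbl = NULL, mean_sbl = NA_real_,
               n_genes_used = NA_integer_,
               usable = FALSE, note = "")
    gc <- tryCatch(gene_content_distance(a, b), error = function(e) NULL)
    if (is.null(gc)) {
      pc$note <- "no shared COGs"
      out[[j]] <- structure(pc, class = "pair_comparison")
      next
    }
    pc[c("n_a", "n_b", "n_shared")] <- gc[c("n_a", "n_b", "n_shared")]
    pc$gcd <- gc$gcd
    red <- tryCatch(common_complement(a, b), error = function(e) NULL)
    if (is.null(red)) {
      pc$note <- "no shared single-copy COGs"
      out[[j]] <- structure(pc, class = "pair_comparison")
      next
    }
    pc$sbl <- extract_synteny_blocks(red$a, red$b)
    pc$mean_sbl <- mean_sbl(pc$sbl)
    pc$n_genes_used <- genome_size(red$a)
    if (pc$gcd <= 0) {
      pc$note <- "identical COG sets (gcd = 0), excluded from fitting"
    } else if (pc$n_genes_used < 2L) {
      pc$note <- "fewer than two shared single-copy genes"
    } else {
      pc$usable <- TRUE
    }
    out[[j]] <- structure(pc, class = "pair_comparison")
  }
  out
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s vs %s: gcd = %s, mean SBL = %s%s\n",
              x$genome_a, x$genome_b,
              formatC(x$gcd, digits = 4, format = "fg"),
              formatC(x$mean_sbl, digits = 4, format = "fg"),
              if (x$usable) "" else paste0(" [unusable: ", x$note, "]")))
  invisible(x)
}

#' Tabulate pair comparisons
#'
#' @param pairs List of `pair_comparison` objects from
#'   [compare_all_pairs()].
#' @return A data frame with one row per pair.
#' @export
pairs_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(clade_id = p$clade_id, genome_a = p$genome_a,
               genome_b = p$genome_b, n_a = p$n_a, n_b = p$n_b,
               n_shared = p$n_shared, gcd = p$gcd,
               n_blocks = if (is.null(p$sbl)) NA_real_ else p$sbl$total_blocks,
               mean_sbl = p$mean_sbl, n_genes_used = p$n_genes_used,
               usable = p$usable, note = p$note,
               stringsAsFactors = FALSE)
  }))
}
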