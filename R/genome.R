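#' Construct a genome from per-replicon gene orders
#'
#' A genome is an ordered collection of replicons (chromosomes, plasmids),
#' each carrying genes labelled by ortholog-cluster (COG) ids in positional
#' order. Strand is stored for export but ignored by all comparisons, which
#' are direction-agnostic.
#'
#' @param genome_id Character scalar identifying the genome.
#' @param replicons List of replicons, each a list with elements
#'   `replicon_id` (character), `topology` (`"circular"` or `"linear"`),
#'   `cog` (character vector of ortholog-cluster ids in positional order)
#'   and optionally `strand` (character vector of `"+"`/`"-"`, defaults to
#'   `"+"`).
#' @return An object of class `genome`.
#' @seealso [genome()] for the common single-replicon case.
#' @export
new_genome <- function(genome_id, replicons) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("'genome_id' must be a non-empty character scalar")
  if (!is.list(replicons) || length(replicons) == 0L)
    stop("a genome needs at least one replicon")
  replicons <- lapply(replicons, function(r) {
    if (is.null(r$replicon_id) || is.null(r$topology) || is.null(r$cog))
      stop("each replicon needs 'replicon_id', 'topology' and 'cog'")
    if (!r$topology %in% c("circular", "linear"))
      stop("unknown topology '", r$topology, "' (expected 'circular' or 'linear')")
    r$cog <- as.character(r$cog)
    if (is.null(r$strand)) r$strand <- rep("+", length(r$cog))
    if (length(r$strand) != length(r$cog))
      stop("replicon '", r$replicon_id, "': strand and cog lengths differ")
    if (!all(r$strand %in% c("+", "-")))
      stop("replicon '", r$replicon_id, "': strand must be '+' or '-'")
    r[c("replicon_id", "topology", "cog", "strand")]
  })
  if (sum(vapply(replicons, function(r) length(r$cog), 1L)) == 0L)
    stop("a genome needs at least one gene")
  structure(list(genome_id = genome_id, replicons = replicons),
            class = "genome")
}

#' Construct a single-replicon genome
#'
#' @param genome_id Character scalar.
#' @param cogs Character vector of ortholog-cluster ids in positional order.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param strand Optional character vector of `"+"`/`"-"`.
#' @param replicon_id Replicon label, default `"chr"`.
#' @return An object of class `genome`.
#' @examples
#' g <- genome("G1", c("a", "b", "c"), topology = "linear")
#' genome_size(g)
#' @export
genome <- function(genome_id, cogs, topology = "circular", strand = NULL,
                   replicon_id = "chr") {
  new_genome(genome_id, list(list(replicon_id = replicon_id,
                                  topology = topology,
                                  cog = cogs, strand = strand)))
}

#' @export
print.genome <- function(x, ...) {
  n <- genome_size(x)
  cat(sprintf("<genome> %s: %d genes on %d replicon(s)\n",
              x$genome_id, n, length(x$replicons)))
  for (r in x$replicons)
    cat(sprintf("  %s [%s]: %d genes\n", r$replicon_id, r$topology,
                length(r$cog)))
  invisible(x)
}

#' Number of genes in a genome
#' @param g A `genome`.
#' @return Integer gene count over all replicons.
#' @export
genome_size <- function(g) {
  sum(vapply(g$replicons, function(r) length(r$cog), 1L))
}

#' All COG labels of a genome, in replicon order
#' @param g A `genome`.
#' @return Character vector of cog ids.
#' @export
genome_cogs <- function(g) {
  unlist(lapply(g$replicons, `[[`, "cog"), use.names = FALSE)
}

#' COG copy-number table of a genome
#' @param g A `genome`.
#' @return Named integer vector mapping cog id to copy number.
#' @export
cog_multiset <- function(g) {
  tab <- table(genome_cogs(g))
  setNames(as.integer(tab), names(tab))
}

#' Construct a clade dataset
#'
#' A clade dataset bundles the genomes of one group of closely related
#' organisms (an ATGC-like clade) that share an ortholog-cluster labelling.
#'
#' @param clade_id Character scalar.
#' @param genomes List of `genome` objects with unique ids.
#' @param provenance Free-text metadata.
#' @return Object of class `clade_dataset`.
#' @export
clade_dataset <- function(clade_id, genomes, provenance = "") {
  if (!is.character(clade_id) || length(clade_id) != 1L)
    stop("'clade_id' must be a character scalar")
  if (!length(genomes)) stop("a clade dataset needs at least one genome")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome ids in clade '", clade_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genomes) <- ids
  structure(list(clade_id = clade_id, genomes = genomes,
                 provenance = provenance),
            class = "clade_dataset")
}

#' @export
print.clade_dataset <- function(x, ...) {
  cat(sprintf("<clade_dataset> %s: %d genomes\n", x$clade_id,
              length(x$genomes)))
  invisible(x)
}
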