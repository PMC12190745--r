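#' Read a gene-order table into a clade dataset
#'
#' The expected format is TSV with header columns `genome_id`,
#' `replicon_id`, `topology`, `position`, `strand`, `cog_id`. Positions are
#' 0-based and must form a gapless `0..m-1` sequence within each
#' (genome, replicon); topology must be constant within a replicon and one
#' of `circular`/`linear`.
#'
#' @param path Path to a TSV file.
#' @param clade_id Clade identifier; defaults to the file name without
#'   extension.
#' @return A [clade_dataset()].
#' @export
read_gene_order_table <- function(path, clade_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(clade_id))
    clade_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("genome_id", "replicon_id", "topology", "position",
                "strand", "cog_id")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("gene-order table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(tab)) stop("gene-order table ", path, " is empty")
  bad_topo <- setdiff(unique(tab$topology), c("circular", "linear"))
  if (length(bad_topo))
    stop("unknown topology token(s): ", paste(bad_topo, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos) || any(pos < 0L))
    stop("positions must be non-negative integers")
  tab$position <- pos

  genomes <- lapply(split(tab, tab$genome_id)[unique(tab$genome_id)],
                    function(gt) {
    reps <- lapply(split(gt, gt$replicon_id)[unique(gt$replicon_id)],
                   function(rt) {
      rt <- rt[order(rt$position), , drop = FALSE]
      m <- nrow(rt)
      if (!identical(rt$position, 0:(m - 1L)))
        stop("positions on genome '", rt$genome_id[1L], "' replicon '",
             rt$replicon_id[1L], "' are not a gapless 0..m-1 sequence")
      topo <- unique(rt$topology)
      if (length(topo) != 1L)
        stop("topology not constant on genome '", rt$genome_id[1L],
             "' replicon '", rt$replicon_id[1L], "'")
      list(replicon_id = rt$replicon_id[1L], topology = topo,
           cog = rt$cog_id, strand = rt$strand)
    })
    new_genome(gt$genome_id[1L], unname(reps))
  })
  clade_dataset(clade_id, unname(genomes), provenance = path)
}

#' Write a clade dataset as a gene-order table
#'
#' Inverse of [read_gene_order_table()]; round-trips all fields.
#'
#' @param dataset A [clade_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_order_table <- function(dataset, path) {
  rows <- lapply(dataset$genomes, function(g) {
    do.call(rbind, lapply(g$replicons, function(r) {
      data.frame(genome_id = g$genome_id, replicon_id = r$replicon_id,
                 topology = r$topology,
                 position = seq_along(r$cog) - 1L,
                 strand = r$strand, cog_id = r$cog,
                 stringsAsFactors = FALSE)
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Collapse cliques of genomes with identical gene complements
#'
#' Genomes whose COG multisets (content including copy number, ignoring
#' order) are identical are reduced to a single representative: the
#' lexicographically smallest genome id of each clique. Identical-content
#' pairs have gene content distance 0 and would degenerate the downstream
#' model fit, so they must not reach it.
#'
#' @param dataset A [clade_dataset()].
#' @return A [clade_dataset()] with one genome per content clique, input
#'   order otherwise preserved.
#' @export
reduce_cliques <- function(dataset) {
  stopifnot(inherits(dataset, "clade_dataset"))
  keys <- vapply(dataset$genomes, function(g) {
    ms <- cog_multiset(g)
    ms <- ms[order(names(ms))]
    paste(names(ms), ms, sep = "\r", collapse = "\n")
  }, "")
  ids <- names(dataset$genomes)
  keep <- vapply(split(ids, keys), function(members) min(members), "")
  kept <- dataset$genomes[ids %in% keep]
  clade_dataset(dataset$clade_id, unname(kept), dataset$provenance)
}

#' Filter clades by size and exclusion list
#'
#' Keeps clades with at least `min_genomes` genomes (counted after clique
#' reduction) whose id is not excluded. Very large outlier clades can be
#' dropped via `exclude_ids`.
#'
#' @param datasets List of [clade_dataset()] objects.
#' @param min_genomes Minimum genomes per clade, default 3.
#' @param exclude_ids Character vector of clade ids to drop regardless of
#'   size.
#' @return Filtered list of clade datasets.
#' @export
filter_clades <- function(datasets, min_genomes = 3L,
                          exclude_ids = character()) {
  keep <- vapply(datasets, function(d) {
    length(d$genomes) >= min_genomes && !(d$clade_id %in% exclude_ids)
  }, NA)
  datasets[keep]
}
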