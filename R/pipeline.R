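#' Pipeline configuration
#'
#' Bundles the tunable settings of [run_pipeline()] with validation.
#'
#' @param min_genomes Minimum genomes per clade after clique reduction.
#' @param exclude_ids Clade ids dropped regardless of size.
#' @param q_range,n_grid Search bounds and grid size for the ratio fit.
#' @param B Bootstrap replicates.
#' @param seed Base seed; per-clade bootstrap seeds are derived from it.
#' @param tail_epsilon,kmax_factor Model truncation controls.
#' @return List of class `run_config`.
#' @export
run_config <- function(min_genomes = 3L, exclude_ids = character(),
                       q_range = c(1e-3, 10), n_grid = 200L, B = 100L,
                       seed = 1L, tail_epsilon = 1e-9, kmax_factor = 2) {
  stopifnot(min_genomes >= 2L, length(q_range) == 2L,
            q_range[1L] > 0, q_range[2L] > q_range[1L],
            n_grid >= 10L, B >= 2L, tail_epsilon > 0, kmax_factor >= 1)
  structure(list(min_genomes = as.integer(min_genomes),
                 exclude_ids = exclude_ids, q_range = q_range,
                 n_grid = as.integer(n_grid), B = as.integer(B),
                 seed = as.integer(seed), tail_epsilon = tail_epsilon,
                 kmax_factor = kmax_factor),
            class = "run_config")
}

#' Read a pipeline configuration from a key = value file
#'
#' Plain-text lines of the form `key = value`; `#` starts a comment.
#' `exclude_ids` takes a comma-separated list, `q_range` two
#' comma-separated numbers. Unknown keys are an error.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    args[[key]] <- switch(key,
      exclude_ids = trimws(strsplit(val, ",")[[1L]]),
      q_range = as.numeric(trimws(strsplit(val, ",")[[1L]])),
      min_genomes = , n_grid = , B = , seed = as.integer(val),
      tail_epsilon = , kmax_factor = as.numeric(val),
      stop("unknown config key: ", key))
  }
  do.call(run_config, args)
}

#' Run the full comparison and fitting pipeline
#'
#' Reads gene-order tables (one TSV per clade), reduces identical-content
#' cliques, filters clades by size, compares all genome pairs, fits the
#' clade-specific rearrangement-to-flux ratio, bootstraps its robustness
#' and writes per-pair and per-clade result tables. A failure in one
#' clade is logged and skipped; only unreadable input or an empty input
#' set is fatal.
#'
#' Outputs in `output_dir`: `pairs.tsv` (one row per genome pair),
#' `sbl_histograms.tsv` (block-length counts per pair), `clades.tsv`
#' (per-clade fit summary) and `run.log`.
#'
#' @param input A directory of `.tsv` gene-order tables or a character
#'   vector of file paths.
#' @param output_dir Output directory, created if needed.
#' @param config A [run_config()].
#' @return Invisibly, a list with `pairs`, `clades` (data frames) and
#'   `results` (per-clade fit objects).
#' @export
run_pipeline <- function(input, output_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  files <- if (length(input) == 1L && dir.exists(input))
    list.files(input, pattern = "\\.tsv$", full.names = TRUE)
  else input
  if (!length(files)) stop("no input gene-order tables found")
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input not readable: ",
                            paste(missing, collapse = ", "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  log_lines <- c(sprintf("synflux %s", as.character(utils::packageVersion("synflux"))),
                 sprintf("seed: %d, B: %d, q_range: [%g, %g], grid: %d",
                         config$seed, config$B, config$q_range[1L],
                         config$q_range[2L], config$n_grid))

  datasets <- lapply(sort(files), read_gene_order_table)
  datasets <- lapply(datasets, reduce_cliques)
  datasets <- filter_clades(datasets, config$min_genomes, config$exclude_ids)
  log_lines <- c(log_lines, sprintf("%d clade(s) after filtering", length(datasets)))

  pair_rows <- list(); hist_rows <- list(); clade_rows <- list()
  results <- list()
  for (ci in seq_along(datasets)) {
    d <- datasets[[ci]]
    res <- tryCatch({
      pairs <- compare_all_pairs(d)
      fit <- fit_q(pairs, q_range = config$q_range, n_grid = config$n_grid,
                   tail_epsilon = config$tail_epsilon,
                   kmax_factor = config$kmax_factor)
      boot <- bootstrap_q(pairs, B = config$B, seed = config$seed + ci,
                          q_range = config$q_range, n_grid = config$n_grid,
                          tail_epsilon = config$tail_epsilon,
                          kmax_factor = config$kmax_factor)
      acc <- flux_accounting(fit$q_star)
      list(pairs = pairs, fit = fit, boot = boot, acc = acc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf("clade %s: SKIPPED (%s)",
                                        d$clade_id, conditionMessage(res)))
      next
    }
    results[[d$clade_id]] <- res
    pair_rows[[d$clade_id]] <- pairs_table(res$pairs)
    hist_rows[[d$clade_id]] <- do.call(rbind, lapply(res$pairs, function(p) {
      if (is.null(p$sbl)) return(NULL)
      data.frame(clade_id = p$clade_id, genome_a = p$genome_a,
                 genome_b = p$genome_b,
                 k = as.integer(names(p$sbl$counts)),
                 count = as.numeric(p$sbl$counts),
                 stringsAsFactors = FALSE)
    }))
    clade_rows[[d$clade_id]] <- data.frame(
      clade_id = d$clade_id, n_genomes = length(d$genomes),
      n_pairs_used = res$fit$n_pairs_used, q_star = res$fit$q_star,
      objective = res$fit$objective_at_optimum,
      boundary_flag = res$fit$boundary_flag,
      rank6 = res$boot$rank6, rank95 = res$boot$rank95,
      robust = res$boot$robust,
      pairs_per_translocation = res$acc$pairs_per_translocation,
      flux_fraction = res$acc$flux_fraction, stringsAsFactors = FALSE)
    log_lines <- c(log_lines,
                   sprintf("clade %s: q* = %.4g (%s), robust = %s",
                           d$clade_id, res$fit$q_star,
                           res$fit$boundary_flag, res$boot$robust))
  }
  pairs_df <- do.call(rbind, unname(pair_rows))
  clades_df <- do.call(rbind, unname(clade_rows))
  wr <- function(x, f) if (!is.null(x))
    write.table(x, file.path(output_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wr(pairs_df, "pairs.tsv")
  wr(do.call(rbind, unname(hist_rows)), "sbl_histograms.tsv")
  wr(clades_df, "clades.tsv")
  writeLines(log_lines, log_path)
  invisible(list(pairs = pairs_df, clades = clades_df, results = results))
}

#' Export dot-plot coordinates for a genome pair
#'
#' Writes a TSV of positions of shared single-copy orthologs in the two
#' genomes (one dot per ortholog pair) plus rows marking genes unique to
#' either genome, mirroring classic genome-comparison dot plots where
#' gene flux shows as missing dots and rearrangements as off-diagonal
#' structure.
#'
#' @param a,b `genome` objects.
#' @param path Output TSV path.
#' @return The output path, invisibly.
#' @export
export_dotplot <- function(a, b, path) {
  coords <- function(g) {
    do.call(rbind, lapply(g$replicons, function(r) {
      data.frame(cog_id = r$cog, replicon = r$replicon_id,
                 pos = seq_along(r$cog) - 1L, stringsAsFactors = FALSE)
    }))
  }
  ca <- coords(a); cb <- coords(b)
  ta <- table(ca$cog_id); tb <- table(cb$cog_id)
  shared <- intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])
  if (!length(shared))
    stop("genomes share no single-copy COGs; nothing to plot")
  m <- merge(ca[ca$cog_id %in% shared, ], cb[cb$cog_id %in% shared, ],
             by = "cog_id", suffixes = c("_a", "_b"))
  m$status <- "shared"
  ua <- ca[!ca$cog_id %in% shared, , drop = FALSE]
  ub <- cb[!cb$cog_id %in% shared, , drop = FALSE]
  if (nrow(ua)) ua <- data.frame(cog_id = ua$cog_id, replicon_a = ua$replicon,
                                 pos_a = ua$pos, replicon_b = NA, pos_b = NA,
                                 status = "unique_a")
  if (nrow(ub)) ub <- data.frame(cog_id = ub$cog_id, replicon_a = NA,
                                 pos_a = NA, replicon_b = ub$replicon,
                                 pos_b = ub$pos, status = "unique_b")
  names(m) <- c("cog_id", "replicon_a", "pos_a", "replicon_b", "pos_b",
                "status")
  out <- rbind(m, if (nrow(ua)) ua, if (nrow(ub)) ub)
  out <- out[order(out$status, out$pos_a, out$pos_b), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
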