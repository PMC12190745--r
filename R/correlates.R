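#' Spearman correlation between gene content distance and mean block
#' length
#'
#' Gene content and gene order diverge together: across genome pairs the
#' mean syntenic block length falls as the gene content distance grows.
#' This pools the supplied pairs (typically across clades) and reports
#' the Spearman rank correlation of (GCD, mean SBL), ties mid-ranked.
#'
#' @param pairs List of `pair_comparison` objects with defined `gcd` and
#'   `mean_sbl` (at least 3).
#' @return Spearman rho in `[-1, 1]`.
#' @export
gcd_sbl_correlation <- function(pairs) {
  tab <- pairs_table(pairs)
  tab <- tab[is.finite(tab$gcd) & is.finite(tab$mean_sbl), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 pairs with defined gcd and mean SBL")
  if (sd(tab$gcd) == 0 || sd(tab$mean_sbl) == 0)
    stop("constant input: Spearman correlation undefined")
  cor(tab$gcd, tab$mean_sbl, method = "spearman")
}

#' Permutation screen of COG presence against rearrangement-to-flux
#' ratios
#'
#' For every COG, computes the Spearman rank correlation between its
#' per-clade presence fraction and the per-clade ratios, then assesses
#' robustness by permuting the ratio vector `n_perm` times (the same
#' permutations for every COG). The permutation p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{|\rho_{perm}| \ge |\rho|\})/(n_{perm}+1)},
#' two-sided since both enrichment and depletion are meaningful. A COG is
#' significant when \eqn{|\rho| \ge} `r_threshold` *and*
#' \eqn{p \le} `p_threshold`. Constant presence columns are skipped with
#' a warning (their correlation is undefined).
#'
#' @param presence Matrix (clades x COGs) of presence fractions in
#'   `[0, 1]`.
#' @param q_values Numeric vector of per-clade ratios, length
#'   `nrow(presence)`.
#' @param n_perm Number of permutations, default 10000 (at least 1000).
#' @param r_threshold,p_threshold Joint significance thresholds
#'   (defaults 0.4 and 0.001).
#' @param seed Integer seed for the permutations.
#' @return Data frame with `cog_id`, `rho`, `p_perm`, `significant`, one
#'   row per non-constant COG column.
#' @export
cog_presence_screen <- function(presence, q_values, n_perm = 10000L,
                                r_threshold = 0.4, p_threshold = 0.001,
                                seed = 1L) {
  presence <- as.matrix(presence)
  n <- nrow(presence)
  if (length(q_values) != n)
    stop("length of 'q_values' (", length(q_values),
         ") does not match rows of 'presence' (", n, ")")
  if (n_perm < 1000L) stop("'n_perm' must be at least 1000")
  if (is.null(colnames(presence)))
    colnames(presence) <- sprintf("COG%04d", seq_len(ncol(presence)))
  constant <- apply(presence, 2L, function(x) length(unique(x)) == 1L)
  if (any(constant))
    warning("skipping ", sum(constant),
            " constant presence column(s): correlation undefined")
  pres <- presence[, !constant, drop = FALSE]
  if (!ncol(pres)) return(data.frame(cog_id = character(), rho = numeric(),
                                     p_perm = numeric(),
                                     significant = logical()))
  set.seed(seed)
  zr <- function(x) { r <- rank(x); (r - mean(r)) / sqrt(sum((r - mean(r))^2)) }
  P <- apply(pres, 2L, zr)                   # n x C, unit-norm centered ranks
  z <- zr(q_values)
  rho <- as.numeric(crossprod(P, z))         # observed Spearman rho per COG
  perm_idx <- replicate(n_perm, sample.int(n))
  Zp <- matrix(z[perm_idx], nrow = n)        # n x n_perm permuted rank scores
  R <- crossprod(P, Zp)                      # C x n_perm permuted rho
  exceed <- rowSums(abs(R) >= abs(rho) - 1e-12)
  p_perm <- (1 + exceed) / (n_perm + 1)
  data.frame(cog_id = colnames(pres), rho = rho, p_perm = p_perm,
             significant = abs(rho) >= r_threshold & p_perm <= p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
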