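#' Expression symmetry of interreplichore gene pairs
#'
#' Tests whether strongly co-expressed genes on opposite replichores tend
#' to be equidistant from oriC. For every gene pair with one member on
#' each replichore, the Spearman correlation of expression profiles across
#' conditions is computed. Pairs with correlation above `rho_cut` form the
#' co-expressed set, pairs with correlation at or below zero the
#' uncorrelated set; the distributions of the oriC-distance difference
#' `|d_i - d_j|` in the two sets are compared with a two-sided Wilcoxon
#' rank-sum test. Co-expression concentrated at small `|d_i - d_j|`
#' indicates that symmetric positioning preserves expression state.
#'
#' @param expr Numeric matrix, genes x conditions; rownames are gene ids
#'   present in `genome`.
#' @param genome A [genome()] object.
#' @param rho_cut Spearman correlation defining the co-expressed set.
#' @return List with `delta_d_high`, `delta_d_low` (the `|d_i - d_j|`
#'   vectors), `median_high`, `median_low`, `p_value`, `n_high`, `n_low`.
#' @export
expression_symmetry <- function(expr, genome, rho_cut = 0.5) {
  stopifnot(is.matrix(expr), inherits(genome, "genome"))
  if (ncol(expr) < 2L) stop_validation("need at least 2 conditions")
  if (is.null(rownames(expr))) stop_validation("expr must have gene ids as rownames")
  pos <- gene_positions(genome)
  idx <- match(rownames(expr), pos$gene_id)
  if (anyNA(idx)) {
    stop_validation("%d expression gene id(s) not in genome", sum(is.na(idx)))
  }
  pos <- pos[idx, , drop = FALSE]
  on_R <- pos$replichore == "R"
  if (sum(on_R) == 0L || sum(!on_R) == 0L) {
    stop_validation("need genes on both replichores")
  }
  rho <- stats::cor(t(expr[on_R, , drop = FALSE]),
                    t(expr[!on_R, , drop = FALSE]), method = "spearman")
  delta <- abs(outer(pos$d_norm[on_R], pos$d_norm[!on_R], "-"))
  high <- delta[rho > rho_cut]
  low <- delta[rho <= 0]
  if (length(high) < 2L || length(low) < 2L) {
    stop_validation("too few gene pairs in the co-expressed or uncorrelated set")
  }
  wt <- stats::wilcox.test(high, low, alternative = "two.sided",
                           correct = TRUE, exact = FALSE)
  list(
    delta_d_high = high, delta_d_low = low,
    median_high = stats::median(high), median_low = stats::median(low),
    p_value = wt$p.value, n_high = length(high), n_low = length(low)
  )
}
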