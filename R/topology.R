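#' Gene-order conservation between two genomes
#'
#' Correlation between the normalized oriC-distance vectors of orthologous
#' genes in two genomes (positions equidistant from oriC on either
#' replichore are equivalent under this distance). High values mean
#' orthologs sit at similar distances from oriC, i.e. similar expected gene
#' dosage. Spearman rank correlation by default.
#'
#' @param map An [ortholog_map()] with genomes attached, or a data.frame
#'   as returned by [map_positions()].
#' @param method Correlation type, `"spearman"` (default) or `"pearson"`.
#' @return The correlation `rho_GOC`, or `NA` with a warning when fewer
#'   than 3 ortholog pairs are available.
#' @export
gene_order_conservation <- function(map, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mp <- as_map_positions(map)
  if (nrow(mp) < 3L) {
    warning("fewer than 3 ortholog pairs: rho_GOC undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(mp$d_a, mp$d_b, method = method)
}

as_map_positions <- function(map) {
  if (inherits(map, "ortholog_map")) map_positions(map)
  else if (is.data.frame(map)) map
  else stop_validation("expected an ortholog_map or a map-positions data.frame")
}

#' Residuals after removing the phylogenetic-distance trend
#'
#' Fits a statistic `y` (e.g. rho_GOC across genome pairs) against 16S
#' sequence identity by local polynomial regression (LOESS) and returns the
#' residuals `y - fitted`, the component of `y` not explained by
#' phylogenetic distance. With this sign convention a positive residual
#' means more conservation than expected at that phylogenetic distance.
#'
#' @param y Numeric response vector.
#' @param identity_16s 16S identity (percent) per observation.
#' @param span LOESS span.
#' @return Numeric residual vector.
#' @export
loess_residual <- function(y, identity_16s, span = 0.75) {
  if (length(y) != length(identity_16s)) {
    stop_validation("y and identity_16s must have equal length")
  }
  if (length(y) < 10L) stop_validation("need at least 10 observations")
  if (stats::sd(identity_16s) == 0) {
    stop_validation("identity_16s is constant; fall back to uncorrected y")
  }
  fit <- stats::loess(y ~ x, data = data.frame(y = y, x = identity_16s),
                      span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  as.numeric(y - stats::fitted(fit))
}

#' Bin-wise conservation and translocation counts
#'
#' Cross-tabulates ortholog pairs by chromosomal bin (O, R, T, L) of the
#' gene in genome A (rows) against the bin of its ortholog in genome B
#' (columns). Row-normalized rates give the gene position conservation
#' `P_i` on the diagonal and translocation rates `T_i-j` off the diagonal;
#' denominators are the genes of bin i in A that have an ortholog at all.
#' Rows with no genes have `NA` rates.
#'
#' @inheritParams gene_order_conservation
#' @return Object of class `bin_matrix`: list with `counts` (4x4 integer),
#'   `rates` (4x4, row-normalized), `n_orthologs`.
#' @export
bin_conservation <- function(map) {
  mp <- as_map_positions(map)
  counts <- table(factor(mp$bin_a, levels = BIN_LEVELS),
                  factor(mp$bin_b, levels = BIN_LEVELS))
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(BIN_LEVELS, BIN_LEVELS))
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(counts = counts, rates = rates, n_orthologs = nrow(mp)),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<bin_matrix> %d ortholog pairs\n", x$n_orthologs))
  cat("rates (rows: bin in A, cols: bin of ortholog in B):\n")
  print(round(x$rates, digits))
  invisible(x)
}

#' Interreplichore translocation rates
#'
#' The fraction of L-bin genes of genome A whose ortholog lies in the R bin
#' of genome B (`T_L_to_R`), and vice versa (`T_R_to_L`), plus the pooled
#' combined rate. Only the L and R bins enter, deliberately excluding the
#' quarter-chromosome around oriC and around ter where local inversions are
#' frequent, so the rate reflects genuine interreplichore translocation
#' rather than origin/terminus-proximal inversion.
#'
#' @inheritParams gene_order_conservation
#' @return List with `T_L_to_R`, `T_R_to_L`, `T_LR_combined` (each `NA`
#'   when its denominator is empty) and the underlying counts.
#' @export
interreplichore_rate <- function(map) {
  mp <- as_map_positions(map)
  n_L <- sum(mp$bin_a == "L")
  n_R <- sum(mp$bin_a == "R")
  x_LR <- sum(mp$bin_a == "L" & mp$bin_b == "R")
  x_RL <- sum(mp$bin_a == "R" & mp$bin_b == "L")
  list(
    T_L_to_R = if (n_L > 0) x_LR / n_L else NA_real_,
    T_R_to_L = if (n_R > 0) x_RL / n_R else NA_real_,
    T_LR_combined = if (n_L + n_R > 0) (x_LR + x_RL) / (n_L + n_R) else NA_real_,
    n_L = n_L, n_R = n_R, crossings = x_LR + x_RL
  )
}

#' Interreplichore translocation profile
#'
#' One entry per ortholog pair whose replichore label differs between the
#' two genomes (regardless of bin, so origin- and terminus-proximal
#' interreplichore moves are included). For each such pair: the two
#' normalized oriC distances, their absolute difference
#' `D_inter = |d_A - d_B|` (near zero for a symmetric translocation), and
#' whether the move flipped leading/lagging-strand status (leading = coding
#' co-directional with the replication fork).
#'
#' @inheritParams gene_order_conservation
#' @param symmetric_cut `D_inter` below which a translocation is called
#'   symmetric (for `frac_symmetric`).
#' @return Object of class `translocation_profile`: list with `pairs`
#'   (data.frame `gene_a`, `gene_b`, `d_a`, `d_b`, `repl_a`, `repl_b`,
#'   `d_inter`, `strand_flip`), directional and combined L/R-bin rates
#'   (from [interreplichore_rate()]), `frac_symmetric`, `flip_rate`.
#' @export
translocation_profile <- function(map, symmetric_cut = 0.1) {
  mp <- as_map_positions(map)
  rates <- interreplichore_rate(mp)
  cross <- mp[mp$repl_a != mp$repl_b, , drop = FALSE]
  pairs <- data.frame(
    gene_a = cross$gene_a, gene_b = cross$gene_b,
    d_a = cross$d_a, d_b = cross$d_b,
    repl_a = cross$repl_a, repl_b = cross$repl_b,
    leading_a = cross$leading_a, leading_b = cross$leading_b,
    d_inter = abs(cross$d_a - cross$d_b),
    strand_flip = cross$leading_a != cross$leading_b,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    T_L_to_R = rates$T_L_to_R, T_R_to_L = rates$T_R_to_L,
    T_LR_combined = rates$T_LR_combined,
    frac_symmetric = if (nrow(pairs) > 0) mean(pairs$d_inter < symmetric_cut) else NA_real_,
    flip_rate = if (nrow(pairs) > 0) mean(pairs$strand_flip) else NA_real_,
    symmetric_cut = symmetric_cut
  ), class = "translocation_profile")
}

#' @export
print.translocation_profile <- function(x, ...) {
  cat(sprintf("<translocation_profile> %d interreplichore pairs\n",
              nrow(x$pairs)))
  cat(sprintf("  T_L-R = %s, T_R-L = %s, combined = %s\n",
              format(x$T_L_to_R, digits = 3), format(x$T_R_to_L, digits = 3),
              format(x$T_LR_combined, digits = 3)))
  if (nrow(x$pairs) > 0) {
    cat(sprintf("  median D_inter = %.3f, frac symmetric (<%.2g) = %.3f, flip rate = %.3f\n",
                stats::median(x$pairs$d_inter), x$symmetric_cut,
                x$frac_symmetric, x$flip_rate))
  }
  invisible(x)
}

#' Randomized null for interreplichore symmetry and strand flips
#'
#' Breaks the gene-to-ortholog assignment within the interreplichore
#' translocated set: per replicate, the partner-genome positions and
#' strands are permuted uniformly among those pairs and `D_inter` and the
#' strand-flip rate are recomputed. The pooled `D_inter` samples form the
#' null distribution against which the observed symmetry (excess of
#' `D_inter` near 0) is judged.
#'
#' @param map An [ortholog_map()] (or map-positions data.frame) or a
#'   [translocation_profile()].
#' @param n_reps Number of permutation replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `null_distribution`: list with `samples`
#'   (pooled null `D_inter` values, length `n_reps * n_pairs`),
#'   `flip_rates` (per replicate), `n_reps`, `seed`, `summary`.
#' @export
randomized_null <- function(map, n_reps = 100, seed = 1) {
  if (!is.numeric(n_reps) || n_reps < 1) {
    stop_validation("n_reps must be >= 1")
  }
  prof <- if (inherits(map, "translocation_profile")) map
          else translocation_profile(map)
  p <- prof$pairs
  n <- nrow(p)
  if (n == 0L) stop_validation("empty translocation profile: no null to build")
  with_seed(seed, {
    samples <- numeric(n_reps * n)
    flip_rates <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      perm <- sample.int(n)
      samples[((r - 1) * n + 1):(r * n)] <- abs(p$d_a - p$d_b[perm])
      flip_rates[r] <- mean(p$leading_a != p$leading_b[perm])
    }
    structure(list(
      samples = samples, flip_rates = flip_rates, n_reps = as.integer(n_reps),
      n_pairs = n, seed = as.integer(seed),
      summary = c(mean = mean(samples), median = stats::median(samples),
                  q25 = unname(stats::quantile(samples, 0.25)),
                  q75 = unname(stats::quantile(samples, 0.75)),
                  flip_rate = mean(flip_rates))
    ), class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d reps x %d pairs (seed %d)\n",
              x$n_reps, x$n_pairs, x$seed))
  cat(sprintf("  mean D_inter = %.4f, null flip rate = %.4f\n",
              x$summary[["mean"]], x$summary[["flip_rate"]]))
  invisible(x)
}

#' Call gross chromosome topology from the interreplichore rate
#'
#' Genomes whose replichores are spatially close (longitudinal topology,
#' as in Caulobacter crescentus) accumulate frequent interreplichore
#' translocations; genomes with spatially separated replichores
#' (transverse topology, as in Escherichia coli) do not. The call is
#' `"longitudinal"` iff the combined L/R translocation rate strictly
#' exceeds the threshold (default 0.1).
#'
#' @param T_LR_combined Combined interreplichore translocation rate in
#'   `[0, 1]`.
#' @param threshold Decision threshold.
#' @return List with `topology` (`"transverse"`/`"longitudinal"`),
#'   `T_LR_combined`, `threshold`.
#' @examples
#' topology_call(0.03)  # transverse (E. coli / Salmonella regime)
#' topology_call(0.50)  # longitudinal (C. crescentus regime)
#' @export
topology_call <- function(T_LR_combined, threshold = 0.1) {
  if (!is.numeric(T_LR_combined) || length(T_LR_combined) != 1L ||
      is.na(T_LR_combined) || T_LR_combined < 0 || T_LR_combined > 1) {
    stop_validation("T_LR_combined must be a single value in [0, 1]")
  }
  list(
    topology = if (T_LR_combined > threshold) "longitudinal" else "transverse",
    T_LR_combined = T_LR_combined,
    threshold = threshold
  )
}
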