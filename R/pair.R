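#' Compare two genomes and call their gross chromosome topology
#'
#' The package's central estimator. Given two closely related genomes and
#' their one-to-one ortholog map, computes the full set of gene-order and
#' translocation statistics — gene-order conservation (rho_GOC), the 4x4
#' bin conservation/translocation matrix, directional and combined
#' interreplichore translocation rates, the interreplichore translocation
#' profile with per-pair symmetry (`D_inter`) and strand-flip flags, a
#' seeded randomized null for both, and the resulting topology call
#' (longitudinal when the combined L/R rate exceeds the threshold,
#' transverse otherwise).
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param map An [ortholog_map()]; when `NULL` the genomes must carry the
#'   same identifiers and an identity mapping is attempted. Genomes given
#'   in `map` take precedence.
#' @param topology_threshold Combined L/R rate above which the pair is
#'   called longitudinal.
#' @param symmetric_cut `D_inter` below which a translocation counts as
#'   symmetric.
#' @param n_null Randomization replicates for the null (0 skips it).
#' @param seed Seed for the randomized null.
#' @param goc_method Correlation type for rho_GOC.
#' @return Object of class `topology_pair` with components `goc`,
#'   `bin_matrix`, `rates`, `profile`, `null`, `call`, `n_orthologs`,
#'   `genomes`, plus the input settings. Has `print`, `summary` and `plot`
#'   methods.
#' @examples
#' anc <- generate_genome(n_genes = 300, genome_length = 3e5,
#'                        proteins = FALSE, seed = 7)
#' ev <- evolve_pair(anc, evolution_params(crossing_fraction = 0.45,
#'                                         seed = 7))
#' fit <- compare_genomes(anc$genome, ev$genome_b, ev$map)
#' fit
#' @export
compare_genomes <- function(genome_a, genome_b, map = NULL,
                            topology_threshold = 0.1, symmetric_cut = 0.1,
                            n_null = 100, seed = 1,
                            goc_method = c("spearman", "pearson")) {
  goc_method <- match.arg(goc_method)
  stopifnot(inherits(genome_a, "genome"), inherits(genome_b, "genome"))
  if (is.null(map)) {
    shared <- intersect(genome_a$genes$gene_id, genome_b$genes$gene_id)
    if (length(shared) == 0L) {
      stop_validation("no ortholog map given and no shared gene ids")
    }
    map <- ortholog_map(data.frame(gene_a = shared, gene_b = shared,
                                   stringsAsFactors = FALSE))
  }
  map$genome_a <- genome_a
  map$genome_b <- genome_b
  mp <- map_positions(map)
  goc <- gene_order_conservation(mp, method = goc_method)
  bm <- bin_conservation(mp)
  rates <- interreplichore_rate(mp)
  prof <- translocation_profile(mp, symmetric_cut = symmetric_cut)
  null <- NULL
  if (n_null > 0 && nrow(prof$pairs) > 0) {
    null <- randomized_null(prof, n_reps = n_null, seed = seed)
  }
  call <- if (is.na(rates$T_LR_combined)) {
    list(topology = NA_character_, T_LR_combined = NA_real_,
         threshold = topology_threshold)
  } else {
    topology_call(rates$T_LR_combined, threshold = topology_threshold)
  }
  # ter can sit off-center in the T bin when replichores are unequal; the
  # bins are anchored on oriC only, so surface that in the metadata.
  ter_d <- locate(genome_a$ter, genome_a$oriC, genome_a$length)
  structure(list(
    goc = goc, goc_method = goc_method,
    bin_matrix = bm, rates = rates, profile = prof, null = null,
    call = call, n_orthologs = nrow(mp),
    genomes = c(genome_a$accession, genome_b$accession),
    genome_a = genome_a, genome_b = genome_b, map_positions = mp,
    ter_offcenter = abs(1 - ter_d$d_norm),
    settings = list(topology_threshold = topology_threshold,
                    symmetric_cut = symmetric_cut, n_null = n_null,
                    seed = seed)
  ), class = "topology_pair")
}

#' @export
print.topology_pair <- function(x, ...) {
  cat(sprintf("<topology_pair> %s vs %s: %d orthologs\n",
              x$genomes[1], x$genomes[2], x$n_orthologs))
  cat(sprintf("  rho_GOC (%s) = %s\n", x$goc_method, format(x$goc, digits = 3)))
  cat(sprintf("  T_L-R = %s, T_R-L = %s, combined = %s\n",
              format(x$rates$T_L_to_R, digits = 3),
              format(x$rates$T_R_to_L, digits = 3),
              format(x$rates$T_LR_combined, digits = 3)))
  cat(sprintf("  topology: %s (threshold %.2g)\n", x$call$topology,
              x$call$threshold))
  invisible(x)
}

#' @export
summary.topology_pair <- function(object, ...) {
  x <- object
  print(x)
  cat("\nbin conservation/translocation rates:\n")
  print(round(x$bin_matrix$rates, 3))
  if (nrow(x$profile$pairs) > 0) {
    cat(sprintf("\ninterreplichore pairs: %d\n", nrow(x$profile$pairs)))
    cat(sprintf("  median D_inter = %.3f (null %.3f)\n",
                stats::median(x$profile$pairs$d_inter),
                if (is.null(x$null)) NA else x$null$summary[["median"]]))
    cat(sprintf("  frac symmetric = %.3f (null %.3f)\n",
                x$profile$frac_symmetric,
                if (is.null(x$null)) NA else
                  mean(x$null$samples < x$profile$symmetric_cut)))
    cat(sprintf("  strand-flip rate = %.3f (null %.3f)\n",
                x$profile$flip_rate,
                if (is.null(x$null)) NA else x$null$summary[["flip_rate"]]))
  }
  if (x$ter_offcenter > 0.05) {
    cat(sprintf("\nnote: ter lies %.2f d_norm units off the antipode; bins are oriC-anchored\n",
                x$ter_offcenter))
  }
  invisible(x)
}

#' Plot method: ortholog position map
#'
#' Scatter of normalized oriC distances of orthologs (`d_A` vs `d_B`),
#' interreplichore translocations highlighted in red; points on the
#' diagonal are symmetric translocations.
#'
#' @param x A `topology_pair`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.topology_pair <- function(x, ...) {
  mp <- x$map_positions
  cross <- mp$repl_a != mp$repl_b
  graphics::plot(mp$d_a, mp$d_b, pch = 16, cex = 0.4,
                 col = ifelse(cross, "red", "grey50"),
                 xlab = expression(d[A]), ylab = expression(d[B]),
                 main = sprintf("%s vs %s (T_LR = %.2f, %s)", x$genomes[1],
                                x$genomes[2], x$rates$T_LR_combined,
                                x$call$topology), ...)
  graphics::abline(0, 1, lty = 2, col = "grey30")
  invisible(x)
}

#' Run configuration for pipeline drivers
#'
#' Bundles the analysis thresholds used by [run_pair()] and
#' [run_simulate()]: the 16S identity and genome-size pair filters, the
#' best-hit E-value cutoff, the topology threshold, the expression
#' co-correlation cutoff, the replication fork speed, the number of
#' randomization replicates, and the master seed (recorded in every output
#' header).
#'
#' @param identity_min Minimum 16S identity (percent).
#' @param evalue_cutoff Best-hit E-value cutoff.
#' @param topology_threshold Combined L/R rate threshold.
#' @param rho_cut Expression-correlation cutoff.
#' @param fork_speed Replication fork speed (nt/s).
#' @param n_reps Randomization replicates.
#' @param seed Master seed.
#' @param out_dir Output directory for TSVs.
#' @return List of class `run_config`.
#' @export
run_config <- function(identity_min = 97, evalue_cutoff = 1e-10,
                       topology_threshold = 0.1, rho_cut = 0.5,
                       fork_speed = 600, n_reps = 100, seed = 1,
                       out_dir = ".") {
  for (nm in c("identity_min", "topology_threshold", "rho_cut",
               "fork_speed", "n_reps", "evalue_cutoff")) {
    check_scalar_positive(get(nm), nm)
  }
  structure(list(identity_min = identity_min, evalue_cutoff = evalue_cutoff,
                 topology_threshold = topology_threshold, rho_cut = rho_cut,
                 fork_speed = fork_speed, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_header <- function(config) {
  c(sprintf("# seed=%d", config$seed),
    sprintf("# identity_min=%g evalue_cutoff=%g topology_threshold=%g rho_cut=%g fork_speed=%g n_reps=%d",
            config$identity_min, config$evalue_cutoff,
            config$topology_threshold, config$rho_cut, config$fork_speed,
            config$n_reps))
}

write_tsv_with_header <- function(d, path, config) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full per-pair analysis and write result TSVs
#'
#' Executes the comparison of one genome pair ([compare_genomes()], plus
#' COG enrichment of genome A when COG annotations are present) and writes
#' a per-pair summary TSV and the translocation-profile TSV into
#' `config$out_dir`, both with commented header lines carrying the seed
#' and thresholds.
#'
#' @param config A [run_config()].
#' @param genome_a,genome_b [genome()] objects.
#' @param map Optional [ortholog_map()] (see [compare_genomes()]).
#' @return The `topology_pair`, invisibly; side effect: TSV files
#'   `pair_<A>_<B>.tsv` and `profile_<A>_<B>.tsv`.
#' @export
run_pair <- function(config, genome_a, genome_b, map = NULL) {
  stopifnot(inherits(config, "run_config"))
  fit <- compare_genomes(genome_a, genome_b, map,
                         topology_threshold = config$topology_threshold,
                         n_null = config$n_reps, seed = config$seed)
  r <- fit$bin_matrix$rates
  row <- data.frame(
    accession_a = fit$genomes[1], accession_b = fit$genomes[2],
    n_orthologs = fit$n_orthologs, rho_goc = fit$goc,
    P_O = r["O", "O"], P_R = r["R", "R"], P_T = r["T", "T"], P_L = r["L", "L"],
    T_O_T = r["O", "T"], T_T_O = r["T", "O"],
    T_L_R = fit$rates$T_L_to_R, T_R_L = fit$rates$T_R_to_L,
    T_LR_combined = fit$rates$T_LR_combined,
    flip_rate = fit$profile$flip_rate,
    frac_symmetric = fit$profile$frac_symmetric,
    topology = fit$call$topology,
    stringsAsFactors = FALSE
  )
  stem <- sprintf("%s_%s", fit$genomes[1], fit$genomes[2])
  write_tsv_with_header(row, file.path(config$out_dir,
                                       sprintf("pair_%s.tsv", stem)), config)
  write_tsv_with_header(
    fit$profile$pairs[, c("gene_a", "gene_b", "d_a", "d_b", "d_inter",
                          "strand_flip")],
    file.path(config$out_dir, sprintf("profile_%s.tsv", stem)), config)
  invisible(fit)
}

#' Simulate a parameter grid and compare truth with estimates
#'
#' For every combination of crossing fraction and seed, generates an
#' ancestor genome, evolves a partner with known ground truth, runs the
#' pair comparison, and tabulates generator truth against the estimated
#' statistics. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param crossing_fractions Numeric vector of generator crossing
#'   fractions.
#' @param seeds Integer vector of generator seeds.
#' @param n_genes,genome_length Genome size of each simulated pair.
#' @param ... Further arguments passed to [evolution_params()].
#' @return data.frame with one row per (fraction, seed): true and
#'   estimated rates and the topology call; written to
#'   `simulation_results.tsv` in `config$out_dir`.
#' @export
run_simulate <- function(config, crossing_fractions = c(0.03, 0.45),
                         seeds = 1:3, n_genes = 1000,
                         genome_length = 1e6, ...) {
  stopifnot(inherits(config, "run_config"))
  if (length(crossing_fractions) == 0L || length(seeds) == 0L) {
    stop_validation("empty parameter grid")
  }
  grid <- expand.grid(f = crossing_fractions, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    f <- grid$f[k]; s <- grid$seed[k]
    anc <- generate_genome(n_genes = n_genes, genome_length = genome_length,
                           proteins = FALSE,
                           seed = config$seed + 1000 * s)
    ev <- evolve_pair(anc, evolution_params(
      n_genes = n_genes, genome_length = genome_length,
      crossing_fraction = f, seed = config$seed + 1000 * s + 1, ...))
    fit <- compare_genomes(anc$genome, ev$genome_b, ev$map,
                           topology_threshold = config$topology_threshold,
                           n_null = 0)
    data.frame(
      crossing_fraction = f, seed = s,
      true_conserved = mean(ev$truth$label != "lost"),
      est_conserved = fit$n_orthologs / nrow(anc$genome$genes),
      est_T_LR = fit$rates$T_LR_combined,
      est_rho_goc = fit$goc,
      topology = fit$call$topology,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  write_tsv_with_header(out, file.path(config$out_dir,
                                       "simulation_results.tsv"), config)
  out
}
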