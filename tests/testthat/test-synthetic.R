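test_that("generated genomes are valid, non-overlapping and deterministic", {
  out <- generate_genome(n_genes = 60, genome_length = 60000, seed = 13)
  g <- out$genome
  expect_s3_class(g, "genome")
  expect_equal(nrow(g$genes), 60L)
  # Non-overlap on the circle (genes are sorted by start; none wrap here
  # except possibly the last).
  flat <- g$genes[!g$genes$wrapped, ]
  expect_true(all(diff(flat$start) > 0))
  expect_true(all(flat$end[-nrow(flat)] < flat$start[-1]))
  # Determinism: same seed, byte-identical tables and sequences.
  out2 <- generate_genome(n_genes = 60, genome_length = 60000, seed = 13)
  expect_identical(out$genome$genes, out2$genome$genes)
  expect_identical(out$proteome, out2$proteome)
  expect_identical(out$seq_16s, out2$seq_16s)
  # Minimal genome.
  tiny <- generate_genome(n_genes = 8, genome_length = 2400, seed = 1,
                          proteins = FALSE)
  expect_equal(nrow(tiny$genome$genes), 8L)
  expect_error(generate_genome(n_genes = 100, genome_length = 5000),
               "packing")
})

test_that("full leading-strand bias puts every gene on the leading strand", {
  out <- generate_genome(n_genes = 50, genome_length = 50000, lead_bias = 1,
                         proteins = FALSE, seed = 2)
  pos <- gene_positions(out$genome)
  expect_true(all(pos$leading))
  out0 <- generate_genome(n_genes = 50, genome_length = 50000, lead_bias = 0,
                          proteins = FALSE, seed = 2)
  expect_true(all(!gene_positions(out0$genome)$leading))
})

test_that("identity evolution reproduces the ancestor's statistics exactly", {
  anc <- generate_genome(n_genes = 200, genome_length = 2e5, seed = 19,
                         proteins = FALSE)
  ev <- evolve_pair(anc, evolution_params(
    crossing_fraction = 0, symmetry_sd = 0, ortholog_loss = 0,
    ot_inversion_rate = 0, seed = 20))
  fit <- compare_genomes(anc$genome, ev$genome_b, ev$map, n_null = 0)
  expect_equal(fit$goc, 1)
  expect_equal(fit$rates$T_LR_combined, 0)
  expect_equal(nrow(fit$profile$pairs), 0L)
  expect_true(all(ev$truth$label == "conserved"))
})

test_that("generator truth matches emitted annotations and the event model", {
  anc <- generate_genome(n_genes = 1000, genome_length = 1e6, seed = 23,
                         proteins = FALSE)
  params <- evolution_params(crossing_fraction = 0.4, symmetry_sd = 0.02,
                             ortholog_loss = 0.3, seed = 24)
  ev <- evolve_pair(anc, params)
  truth <- ev$truth
  # Labels partition the genes.
  expect_equal(nrow(truth), 1000L)
  expect_true(all(truth$label %in% c("conserved", "translocated",
                                     "inverted_local", "lost")))
  # Loss rate is exact by construction.
  expect_equal(sum(truth$label == "lost"), round(0.3 * 1000))
  # Truth d_b agrees with the partner genome's own annotation.
  mp <- map_positions(ev$map)
  keep <- truth$label != "lost"
  # map pairs are in ancestor gene order over surviving genes.
  expect_equal(mp$d_b, truth$d_b[keep], tolerance = 2e-3)
  expect_equal(mp$d_a, truth$d_a[keep], tolerance = 2e-3)
  # Translocated genes changed replichore; conserved ones did not.
  lab <- truth$label[keep]
  expect_true(all((mp$repl_a != mp$repl_b)[lab == "translocated"]))
  expect_true(all((mp$repl_a == mp$repl_b)[lab == "conserved"]))
  # Strand flips in truth agree with the annotation-derived flags.
  expect_equal(mp$leading_a != mp$leading_b, truth$flip[keep])
})

test_that("evolution parameters are recovered by the downstream estimators", {
  t_est <- c(); c_est <- c()
  for (s in 1:5) {
    anc <- generate_genome(n_genes = 2000, genome_length = 2e6,
                           seed = 100 + s, proteins = FALSE)
    ev <- evolve_pair(anc, evolution_params(crossing_fraction = 0.4,
                                            symmetry_sd = 0.02,
                                            ortholog_loss = 0.3,
                                            seed = 200 + s))
    fit <- compare_genomes(anc$genome, ev$genome_b, ev$map, n_null = 0)
    t_est <- c(t_est, fit$rates$T_LR_combined)
    c_est <- c(c_est, fit$n_orthologs / 2000)
  }
  expect_equal(mean(t_est), 0.4, tolerance = 0.05)
  expect_equal(mean(c_est), 0.7, tolerance = 0.03)
})

test_that("sequence-based best hits recover the generator's true map", {
  anc <- generate_genome(n_genes = 40, genome_length = 40000, seed = 29)
  ev <- evolve_pair(anc, evolution_params(crossing_fraction = 0.3,
                                          ortholog_loss = 0.2, seed = 30))
  bb <- best_hits(anc$proteome, ev$proteome_b)
  true_pairs <- ev$map$pairs
  got <- paste(bb$pairs$gene_a, bb$pairs$gene_b)
  want <- paste(true_pairs$gene_a, true_pairs$gene_b)
  expect_gte(length(intersect(got, want)) / length(want), 0.95)
})

test_that("synthetic contact maps are symmetric with a longitudinal band", {
  g <- genome("CC", length = 2e5, oriC = 2e5, ter = 1e5)
  m_t <- synth_contact_map(g, "transverse", bin_size = 1e4, seed = 31)
  m_l <- synth_contact_map(g, "longitudinal", bin_size = 1e4,
                           band_strength = 2, band_width = 0.06, seed = 31)
  expect_equal(m_t, t(m_t))
  expect_equal(m_l, t(m_l))
  n <- nrow(m_t)
  centers <- (seq_len(n) - 0.5) * 1e4
  pos <- locate(centers, g$oriC, g$length)
  mirrored <- abs(outer(pos$d_norm, pos$d_norm, "-")) < 0.06 &
    outer(pos$replichore, pos$replichore, "!=")
  same_sep <- !mirrored
  # Band pairs are enriched relative to the same matrix without a band.
  ratio <- m_l / m_t
  expect_gt(mean(ratio[mirrored & upper.tri(ratio)]), 2.5)
  expect_equal(mean(ratio[!mirrored & upper.tri(ratio)]), 1, tolerance = 1e-9)
  expect_error(synth_contact_map(g, decay_exponent = -1), "positive")
  # band_strength = 0 makes the two topologies identical.
  m_l0 <- synth_contact_map(g, "longitudinal", band_strength = 0,
                            bin_size = 1e4, seed = 31)
  expect_identical(m_t, m_l0)
})

test_that("synthetic output round-trips through the standard formats", {
  out <- generate_genome(n_genes = 30, genome_length = 30000, seed = 37)
  f_ptt <- withr::local_tempfile()
  write_ptt(out$genome, f_ptt)
  genes <- read_ptt(f_ptt, length = 30000)
  expect_equal(genes$start, out$genome$genes$start)
  f_faa <- withr::local_tempfile(fileext = ".faa")
  write_fasta(out$proteome, f_faa, type = "AA")
  back <- read_proteome(f_faa)
  expect_identical(back, out$proteome)
})

test_that("the pipeline recovers translocated genes with few false positives", {
  anc <- generate_genome(n_genes = 2000, genome_length = 2e6, seed = 41,
                         proteins = FALSE)
  ev <- evolve_pair(anc, evolution_params(crossing_fraction = 0.3,
                                          symmetry_sd = 0.03,
                                          ot_inversion_rate = 0,
                                          seed = 42))
  fit <- compare_genomes(anc$genome, ev$genome_b, ev$map, n_null = 0)
  truth <- ev$truth
  translocated_true <- truth$gene_b[truth$label == "translocated"]
  flagged <- fit$profile$pairs$gene_b
  recall <- length(intersect(flagged, translocated_true)) /
    length(translocated_true)
  false_pos <- length(setdiff(flagged, translocated_true)) /
    max(1, length(flagged))
  expect_gte(recall, 0.95)
  expect_lte(false_pos, 0.01)
})
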