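test_that("gene-order conservation hits +/-1 on identical and reversed ranks", {
  # All genes on one replichore so the distance ranks are tie-free.
  ga <- toy_genome(midpoints = seq(30, 470, by = 20))
  gb_same <- ga
  expect_equal(gene_order_conservation(toy_map(ga, gb_same)), 1)
  # Reverse-ranked partner positions.
  mp <- map_positions(toy_map(ga, ga))
  mp$d_b <- rev(sort(mp$d_a))[rank(mp$d_a, ties.method = "first")]
  expect_equal(gene_order_conservation(mp), -1, tolerance = 1e-9)
  expect_warning(val <- gene_order_conservation(mp[1:2, ]), "fewer than 3")
  expect_true(is.na(val))
})

test_that("random pairing yields near-zero gene-order conservation", {
  set.seed(55)
  mp <- data.frame(d_a = runif(1e4), d_b = runif(1e4))
  expect_lt(abs(gene_order_conservation(mp)), 0.05)
})

test_that("phylogenetic-distance correction removes trend, keeps planted offsets", {
  set.seed(66)
  x <- runif(60, 90, 100)
  # Exactly linear response -> residuals ~ 0.
  y_lin <- 0.02 * x - 1
  expect_lt(max(abs(loess_residual(y_lin, x))), 1e-6)
  # Constant response -> residuals ~ 0.
  expect_lt(max(abs(loess_residual(rep(0.7, 60), x))), 1e-9)
  # Planted offsets on a subset are recovered.
  offset <- rep(0, 60); offset[1:12] <- 0.3
  res <- loess_residual(y_lin + offset, x)
  expect_equal(mean(res[1:12]) - mean(res[-(1:12)]), 0.3, tolerance = 0.1)
  expect_error(loess_residual(y_lin, rep(95, 60)), "constant")
  expect_error(loess_residual(y_lin[1:5], x[1:5]), "at least 10")
})

test_that("bin matrix counts, rates and empty-row handling are exact", {
  # 4 O-bin genes (one partner moved to T) plus 2 T-bin genes conserved.
  ga <- toy_genome(midpoints = c(960, 980, 20, 40, 480, 520),
                   length = 1000, oriC = 1000)
  gb <- toy_genome(midpoints = c(960, 980, 20, 510, 480, 520),
                   length = 1000, oriC = 1000, accession = "TOY2")
  bm <- bin_conservation(toy_map(ga, gb))
  expect_equal(sum(bm$counts), 6)
  expect_equal(bm$rates["O", "O"], 0.75)
  expect_equal(bm$rates["O", "T"], 0.25)
  expect_equal(bm$rates["T", "T"], 1)
  # Empty rows (no R/L genes) are NA, not zero.
  expect_true(all(is.na(bm$rates["R", ])))
  expect_true(all(is.na(bm$rates["L", ])))
  # Identity mapping gives the identity rate matrix.
  bm_id <- bin_conservation(toy_map(ga, ga))
  expect_equal(bm_id$rates[c("O", "T"), c("O", "T")],
               diag(2) * 1, ignore_attr = TRUE)
})

test_that("row rates sum to one over nonempty rows", {
  anc <- generate_genome(n_genes = 400, genome_length = 4e5, seed = 9,
                         proteins = FALSE)
  ev <- evolve_pair(anc, evolution_params(n_genes = 400, genome_length = 4e5,
                                          crossing_fraction = 0.3, seed = 10))
  bm <- bin_conservation(ev$map)
  rs <- rowSums(bm$rates)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, sum(!is.na(rs))),
               tolerance = 1e-12)
  expect_equal(sum(bm$counts), nrow(ev$map$pairs))
})

test_that("interreplichore rates count L/R-bin crossings only", {
  # 10 L genes and 10 R genes; 5 crossing each way.
  ga <- toy_genome(midpoints = c(seq(150, 330, by = 20),
                                 seq(670, 850, by = 20)),
                   length = 1000, oriC = 1000)
  mirror <- function(m, len = 1000, ori = 1000) (2 * ori - m) %% len
  mids_b <- ga$genes$start  # width-1 genes: start == midpoint
  pos <- locate(mids_b, 1000, 1000)
  stopifnot(sum(pos$bin == "R") == 10, sum(pos$bin == "L") == 10)
  cross_idx <- c(which(pos$bin == "R")[1:5], which(pos$bin == "L")[1:5])
  mids_b[cross_idx] <- mirror(mids_b[cross_idx])
  gb <- toy_genome(midpoints = mids_b, length = 1000, oriC = 1000,
                   accession = "TOY2")
  rates <- interreplichore_rate(toy_map(ga, gb))
  expect_equal(rates$T_L_to_R, 0.5)
  expect_equal(rates$T_R_to_L, 0.5)
  expect_equal(rates$T_LR_combined, 0.5)
  # No crossings at all.
  rates0 <- interreplichore_rate(toy_map(ga, ga))
  expect_equal(rates0$T_LR_combined, 0)
})

test_that("translocation profile records symmetry and strand flips", {
  # Symmetric translocation R -> L at d = 0.4 preserving leading status.
  ga <- toy_genome(midpoints = c(200, 300, 700), strands = c("+", "+", "-"),
                   length = 1000, oriC = 1000)
  # Partner: first gene mirrored to L replichore at same d (coordinate 800);
  # leading on L means "-" strand.
  gb <- toy_genome(midpoints = c(800, 300, 700), strands = c("-", "+", "-"),
                   length = 1000, oriC = 1000, accession = "TOY2")
  prof <- translocation_profile(toy_map(ga, gb))
  expect_equal(nrow(prof$pairs), 1L)
  expect_equal(prof$pairs$d_inter, 0)
  expect_false(prof$pairs$strand_flip)
  expect_equal(prof$flip_rate, 0)
  # Keeping "+" on the new L replichore flips leading -> lagging.
  gb2 <- toy_genome(midpoints = c(800, 300, 700), strands = c("+", "+", "-"),
                    length = 1000, oriC = 1000, accession = "TOY3")
  prof2 <- translocation_profile(toy_map(ga, gb2))
  expect_true(prof2$pairs$strand_flip)
  # D_inter is the plain absolute difference of normalized distances.
  gb3 <- toy_genome(midpoints = c(650, 300, 700), strands = c("-", "+", "-"),
                    length = 1000, oriC = 1000, accession = "TOY4")
  prof3 <- translocation_profile(toy_map(ga, gb3))
  expect_equal(prof3$pairs$d_inter, abs(0.4 - 0.7))
})

test_that("randomized nulls are reproducible and match analytic expectations", {
  set.seed(77)
  n <- 1000
  d_a <- runif(n); d_b <- runif(n)
  prof <- structure(list(pairs = data.frame(
    gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
    d_a = d_a, d_b = d_b,
    repl_a = "R", repl_b = "L",
    leading_a = sample(c(TRUE, FALSE), n, TRUE),
    leading_b = sample(c(TRUE, FALSE), n, TRUE),
    d_inter = abs(d_a - d_b),
    strand_flip = FALSE, stringsAsFactors = FALSE),
    T_LR_combined = 0.5, frac_symmetric = 0, flip_rate = 0,
    symmetric_cut = 0.1), class = "translocation_profile")
  null1 <- randomized_null(prof, n_reps = 100, seed = 123)
  null2 <- randomized_null(prof, n_reps = 100, seed = 123)
  expect_identical(null1$samples, null2$samples)
  expect_equal(length(null1$samples), 100 * n)
  # E|U - U'| = 1/3 for independent uniforms.
  expect_equal(mean(null1$samples), 1 / 3, tolerance = 0.01)
  # Null flip rate with fair random leading status is 1/2.
  expect_equal(mean(null1$flip_rates), 0.5, tolerance = 0.02)
  expect_error(randomized_null(prof, n_reps = 0), "n_reps")
})

test_that("topology calls follow the strict threshold convention", {
  expect_equal(topology_call(0.03)$topology, "transverse")
  expect_equal(topology_call(0.50)$topology, "longitudinal")
  expect_equal(topology_call(0.1)$topology, "transverse")  # boundary
  expect_error(topology_call(1.2), "\\[0, 1\\]")
})
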