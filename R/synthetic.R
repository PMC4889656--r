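#' Parameters of the synthetic genome-pair evolution model
#'
#' Defines the event model used by [evolve_pair()]: a fraction
#' `crossing_fraction` of L/R-bin orthologs relocates to the mirrored
#' position on the opposite replichore (with Gaussian positional noise
#' `symmetry_sd` in normalized-distance units), local inversions flip
#' origin/terminus-proximal genes across replichores at
#' `ot_inversion_rate`, a fraction `ortholog_loss` of genes loses its
#' ortholog, and translocated genes keep their leading-strand status with
#' probability `strand_preservation`.
#'
#' Defaults describe a plausible longitudinal-topology genome pair:
#' 2000 genes on a 2 Mb chromosome (typical bacterial gene density),
#' ortholog loss 0.28 (matching the ~72% median ortholog conservation seen
#' between closely related genome pairs), crossing fraction 0.3, nearly
#' symmetric translocations (sd 0.02), strong leading-strand preservation
#' (0.9), and a low origin/terminus inversion rate (0.05).
#'
#' @param n_genes Number of genes.
#' @param genome_length Chromosome length in bp (>= 300 x `n_genes`).
#' @param crossing_fraction Share of L/R-bin orthologs moved to the
#'   opposite replichore.
#' @param symmetry_sd SD of the positional noise added to the mirrored
#'   position, in normalized-distance units.
#' @param strand_preservation Probability a translocated gene keeps its
#'   leading-strand status.
#' @param ortholog_loss Fraction of genes without an ortholog in the
#'   partner genome.
#' @param ot_inversion_rate Per-gene probability of a local
#'   origin/terminus-proximal inversion for O- and T-bin genes.
#' @param seed Integer seed.
#' @return List of class `evolution_params`.
#' @export
evolution_params <- function(n_genes = 2000, genome_length = 2e6,
                             crossing_fraction = 0.3, symmetry_sd = 0.02,
                             strand_preservation = 0.9, ortholog_loss = 0.28,
                             ot_inversion_rate = 0.05, seed = 1) {
  if (n_genes < 8) stop_validation("n_genes must be >= 8")
  if (genome_length < n_genes * 300) {
    stop_validation("genome_length must be >= 300 x n_genes")
  }
  for (p in c("crossing_fraction", "strand_preservation", "ortholog_loss",
              "ot_inversion_rate")) {
    check_probability(get(p), p)
  }
  if (symmetry_sd < 0) stop_validation("symmetry_sd must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), genome_length = genome_length,
    crossing_fraction = crossing_fraction, symmetry_sd = symmetry_sd,
    strand_preservation = strand_preservation, ortholog_loss = ortholog_loss,
    ot_inversion_rate = ot_inversion_rate, seed = as.integer(seed)
  ), class = "evolution_params")
}

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seqs <- function(n, len_range, alphabet) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, "")
}

# Default COG-class sampling weights; class J (translation, ribosome
# biogenesis) is additionally concentrated near oriC by generate_genome.
default_cog_probs <- function() {
  w <- stats::setNames(rep(1, length(COG_CLASSES)), COG_CLASSES)
  w / sum(w)
}

#' Generate a synthetic circular genome
#'
#' Places `n_genes` non-overlapping genes uniformly around a circular
#' chromosome with oriC at coordinate 1 and ter antipodal. Strands are
#' drawn with a configurable leading-strand bias (bacterial genes are
#' preferentially co-directional with the replication fork); COG classes
#' are drawn from `cog_probs`, with class J additionally up-weighted near
#' oriC to emulate the origin-proximal concentration of translation and
#' ribosome-biogenesis genes. Optionally emits a random proteome and a 16S
#' rRNA sequence. Fully deterministic given `seed`.
#'
#' @param n_genes Number of genes (>= 8).
#' @param genome_length Chromosome length in bp (>= 300 x `n_genes`).
#' @param lead_bias Probability a gene is on the leading strand.
#' @param cog_probs Named probability vector over COG class letters.
#' @param cog_j_ori_boost Multiplier applied to class J weight for genes
#'   with `d_norm < 0.25`.
#' @param proteins Emit a random proteome (`AA` sequences, named by
#'   protein id)? Skipping it speeds up simulation studies that use the
#'   generator's true ortholog map rather than sequence search.
#' @param accession Accession string for the genome.
#' @param seed Integer seed.
#' @return List with `genome` ([genome()]), `proteome` (named character
#'   vector or `NULL`), `seq_16s`.
#' @export
generate_genome <- function(n_genes = 2000, genome_length = 2e6,
                            lead_bias = 0.75, cog_probs = default_cog_probs(),
                            cog_j_ori_boost = 4, proteins = TRUE,
                            accession = "SYN_A", seed = 1) {
  if (n_genes < 8) stop_validation("n_genes must be >= 8")
  if (genome_length < n_genes * 300) {
    stop_validation("infeasible packing: genome_length < 300 x n_genes")
  }
  check_probability(lead_bias, "lead_bias")
  with_seed(seed, {
    spacing <- genome_length / n_genes
    gene_len <- max(90, min(900, floor(spacing * 0.8)))
    if (gene_len %% 2 == 0) gene_len <- gene_len - 1  # odd => integer midpoints
    starts <- round((seq_len(n_genes) - 1) * spacing +
                      stats::runif(n_genes, 1, spacing - gene_len))
    ends <- starts + gene_len - 1
    wrapped <- ends > genome_length
    ends[wrapped] <- ends[wrapped] - genome_length
    oriC <- genome_length  # equivalently coordinate 0 on the circle
    ter <- genome_length / 2
    mid <- circ_mod((starts + starts + gene_len - 1) / 2 - 1, genome_length) + 1
    pos <- locate(mid, oriC, genome_length)
    leading <- stats::runif(n_genes) < lead_bias
    strand <- ifelse(xor(pos$replichore == "R", leading), "-", "+")
    # COG assignment with origin-proximal boost for class J.
    cls <- character(n_genes)
    for (i in seq_len(n_genes)) {
      w <- cog_probs
      if (pos$d_norm[i] < 0.25) w["J"] <- w["J"] * cog_j_ori_boost
      cls[i] <- sample(names(w), 1, prob = w)
    }
    ids <- sprintf("g%05d", seq_len(n_genes))
    pids <- ids  # protein ids mirror gene ids: one CDS per gene
    g <- genome(
      accession = accession, length = genome_length, oriC = oriC, ter = ter,
      genes = data.frame(
        gene_id = ids, start = starts, end = ends, strand = strand,
        protein_id = pids, cog_class = cls,
        product = "hypothetical protein", wrapped = wrapped,
        stringsAsFactors = FALSE
      ),
      rrna_16s_count = 1L,
      seq_16s = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                      collapse = ""),
      organism = paste("Synthetica generata", accession)
    )
    proteome <- NULL
    if (proteins) {
      proteome <- stats::setNames(
        random_seqs(n_genes, c(120, 400), AA_ALPHABET20), pids)
    }
    list(genome = g, proteome = proteome, seq_16s = g$seq_16s)
  })
}

mutate_seq <- function(seq, rate, alphabet) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

# Reflect values into [0, 1] (mirror at the boundaries).
reflect01 <- function(x) {
  x <- abs(x)
  over <- x > 1
  x[over] <- 2 - x[over]
  pmin(pmax(x, 0), 1)
}

#' Evolve a partner genome with known ground truth
#'
#' Applies the event model of [evolution_params()] to a generated genome:
#' ortholog loss, symmetric interreplichore translocation of L/R-bin genes
#' (mirrored position plus Gaussian noise), origin/terminus-local
#' inversions of O/T-bin genes (replichore flip at preserved distance with
#' strand flip, which preserves leading-strand status), and stochastic
#' leading-strand preservation for translocated genes. Emits the partner
#' genome, the true one-to-one ortholog map, a per-gene truth table, and
#' (when the input has a proteome) a point-mutation-diverged partner
#' proteome and 16S sequence, so that sequence-based orthology can be
#' exercised against known truth.
#'
#' @param ancestor Output of [generate_genome()] (list with `genome`,
#'   `proteome`, `seq_16s`).
#' @param params An [evolution_params()] object; its `n_genes` and
#'   `genome_length` are ignored in favour of the ancestor's.
#' @param accession Accession for the partner genome.
#' @param divergence Per-site substitution rate applied to partner protein
#'   and 16S sequences (small, so best-hit orthology still recovers the
#'   true map).
#' @return List with `genome_b`, `proteome_b`, `seq_16s_b`, `map` (the
#'   true [ortholog_map()] with both genomes attached), `truth`
#'   (data.frame: `gene_a`, `gene_b`, `label` in conserved / translocated /
#'   inverted_local / lost, `d_a`, `d_b`, `flip`).
#' @export
evolve_pair <- function(ancestor, params = evolution_params(),
                        accession = "SYN_B", divergence = 0.02) {
  stopifnot(inherits(params, "evolution_params"))
  ga <- ancestor$genome
  stopifnot(inherits(ga, "genome"))
  n <- nrow(ga$genes)
  with_seed(params$seed, {
    pos <- gene_positions(ga)
    label <- rep("conserved", n)
    # Ortholog loss.
    n_lost <- round(params$ortholog_loss * n)
    lost <- sample.int(n, n_lost)
    label[lost] <- "lost"
    alive <- which(label != "lost")
    # Interreplichore translocation of surviving L/R-bin genes.
    lr <- alive[pos$bin[alive] %in% c("L", "R")]
    n_cross <- round(params$crossing_fraction * length(lr))
    if (n_cross > length(lr)) {
      stop_validation("crossing_fraction and ortholog_loss jointly exhaust the L/R bins")
    }
    crossed <- if (n_cross > 0) lr[sample.int(length(lr), n_cross)] else integer(0)
    label[crossed] <- "translocated"
    # Origin/terminus-local inversions among surviving O/T-bin genes.
    ot <- alive[pos$bin[alive] %in% c("O", "T")]
    inverted <- ot[stats::runif(length(ot)) < params$ot_inversion_rate]
    label[inverted] <- "inverted_local"
    # Partner-side positions.
    d_b <- pos$d_norm
    repl_b <- pos$replichore
    flip_repl <- c(R = "L", L = "R")
    d_b[crossed] <- reflect01(pos$d_norm[crossed] +
                                stats::rnorm(length(crossed), 0,
                                             params$symmetry_sd))
    repl_b[crossed] <- flip_repl[pos$replichore[crossed]]
    d_b[inverted] <- pos$d_norm[inverted]
    repl_b[inverted] <- flip_repl[pos$replichore[inverted]]
    # Strands: conserved genes keep strand; inverted genes flip strand
    # (preserving leading status); translocated genes keep leading status
    # with probability strand_preservation.
    leading_b <- pos$leading
    keep_lead <- stats::runif(length(crossed)) < params$strand_preservation
    leading_b[crossed] <- ifelse(keep_lead, pos$leading[crossed],
                                 !pos$leading[crossed])
    strand_b <- ifelse(xor(repl_b == "R", leading_b), "-", "+")
    flip <- leading_b != pos$leading
    # Build partner genome from surviving genes.
    keep <- label != "lost"
    mid_b <- position_to_coord(d_b[keep], repl_b[keep], ga$oriC, ga$length)
    glen <- ifelse(ga$genes$wrapped[keep],
                   ga$genes$end[keep] + ga$length - ga$genes$start[keep] + 1,
                   ga$genes$end[keep] - ga$genes$start[keep] + 1)
    # start such that the recomputed midpoint start + (len-1)/2 equals mid_b.
    start_b <- pmin(ga$length,
                    round(circ_mod(mid_b - (glen - 1) / 2 - 1, ga$length) + 1))
    end_b <- start_b + glen - 1
    wrapped_b <- end_b > ga$length
    end_b[wrapped_b] <- end_b[wrapped_b] - ga$length
    ids_b <- sprintf("h%05d", seq_len(sum(keep)))
    pids_b <- ids_b
    gb <- genome(
      accession = accession, length = ga$length, oriC = ga$oriC, ter = ga$ter,
      genes = data.frame(
        gene_id = ids_b, start = start_b, end = end_b,
        strand = strand_b[keep], protein_id = pids_b,
        cog_class = ga$genes$cog_class[keep],
        product = ga$genes$product[keep], wrapped = wrapped_b,
        stringsAsFactors = FALSE
      ),
      rrna_16s_count = ga$rrna_16s_count,
      seq_16s = if (is.null(ancestor$seq_16s)) NULL else
        mutate_seq(ancestor$seq_16s, min(divergence, 0.01),
                   c("A", "C", "G", "T")),
      organism = paste("Synthetica evoluta", accession)
    )
    map <- ortholog_map(
      data.frame(gene_a = ga$genes$protein_id[keep], gene_b = pids_b,
                 score = NA_real_, evalue = NA_real_,
                 stringsAsFactors = FALSE),
      genome_a = ga, genome_b = gb
    )
    truth <- data.frame(
      gene_a = ga$genes$gene_id,
      gene_b = c(NA_character_, ids_b)[cumsum(keep) * keep + 1L],
      label = label,
      d_a = pos$d_norm,
      d_b = ifelse(keep, d_b, NA_real_),
      flip = ifelse(keep, flip, NA),
      stringsAsFactors = FALSE
    )
    proteome_b <- NULL
    if (!is.null(ancestor$proteome)) {
      pa <- ancestor$proteome[ga$genes$protein_id[keep]]
      proteome_b <- stats::setNames(
        vapply(pa, mutate_seq, "", rate = divergence,
               alphabet = AA_ALPHABET20),
        pids_b)
    }
    list(genome_b = gb, proteome_b = proteome_b, seq_16s_b = gb$seq_16s,
         map = map, truth = truth, params = params)
  })
}

#' Synthetic chromosome contact map
#'
#' Builds a symmetric binned contact matrix with power-law distance decay
#' (`(s + 1)^-decay_exponent` in bin units of circular separation `s`) and
#' multiplicative log-normal noise. In `"longitudinal"` mode an
#' anti-diagonal band multiplies contacts between bin pairs on opposite
#' replichores at similar oriC distance by `1 + band_strength`, emulating
#' the symmetric interreplichore contacts of a longitudinally organised
#' chromosome; in `"transverse"` mode (or with `band_strength = 0`) no
#' band is added.
#'
#' @param genome A [genome()] object.
#' @param topology `"transverse"` or `"longitudinal"`.
#' @param bin_size Bin width in bp; must divide the genome length to
#'   within one bin.
#' @param decay_exponent Positive distance-decay exponent.
#' @param band_strength Relative strength of the interreplichore band.
#' @param band_width Half-width of the band in `|d_i - d_j|` units.
#' @param noise_sd SD of the log-normal noise on the log scale.
#' @param seed Integer seed.
#' @return Square symmetric numeric matrix.
#' @export
synth_contact_map <- function(genome, topology = c("transverse", "longitudinal"),
                              bin_size = 2e4, decay_exponent = 1,
                              band_strength = 2, band_width = 0.05,
                              noise_sd = 0.1, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(inherits(genome, "genome"))
  if (decay_exponent <= 0) stop_validation("decay_exponent must be positive")
  check_scalar_positive(bin_size, "bin_size")
  n <- round(genome$length / bin_size)
  if (abs(n * bin_size - genome$length) > bin_size) {
    stop_validation("bin_size must divide genome length within one bin")
  }
  centers <- pmin(genome$length, (seq_len(n) - 0.5) * bin_size)
  pos <- locate(centers, genome$oriC, genome$length)
  sep <- outer(seq_len(n), seq_len(n), function(i, j) {
    s <- abs(i - j)
    pmin(s, n - s)
  })
  base <- (sep + 1)^(-decay_exponent)
  if (topology == "longitudinal" && band_strength > 0) {
    inter <- outer(pos$replichore, pos$replichore, "!=")
    close_d <- abs(outer(pos$d_norm, pos$d_norm, "-")) < band_width
    base <- base * ifelse(inter & close_d, 1 + band_strength, 1)
  }
  with_seed(seed, {
    noise <- matrix(exp(stats::rnorm(n * n, 0, noise_sd)), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- base * noise
    (m + t(m)) / 2
  })
}
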