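#' Global-alignment percent identity of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (defaults
#' mirror the EMBOSS needle defaults: match +5 / mismatch -4 scoring,
#' gap opening 10, gap extension 0.5) and percent identity computed as
#' 100 x matches / alignment length. Used for 16S rRNA similarity in
#' genome-pair selection.
#'
#' @param seq_a,seq_b Nucleotide strings over `{A, C, G, T, N}`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Optional substitution matrix; defaults to +5/-4 with
#'   IUPAC ambiguity support.
#' @return Percent identity in `[0, 100]`, with the optimal alignment
#'   score attached as attribute `"score"`.
#' @examples
#' nw_identity("ACGTACGTAC", "ACGTACGTAA")  # 90
#' @export
nw_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                        matrix = NULL) {
  for (s in list(seq_a, seq_b)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
      stop_validation("sequences must be nonempty character scalars")
    }
  }
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b)) {
    stop_validation("sequences may contain only A, C, G, T, N")
  }
  if (is.null(matrix)) {
    matrix <- Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = FALSE, type = "DNA")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  # Identity over the full global alignment length (all gap columns
  # included). The optimal alignment score rides along as an attribute
  # for cross-checks.
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  structure(100 * Biostrings::nmatch(aln) / aln_len,
            score = Biostrings::score(aln))
}

#' Deterministic internal protein-similarity scorer
#'
#' Scores every ordered query/target protein pair by global alignment
#' (BLOSUM62, affine gaps) and maps the bit-score-like alignment score to a
#' pseudo E-value through a fixed monotone decreasing transform
#' (Karlin-Altschul form with gapped BLOSUM62 parameters). The transform
#' preserves score order exactly, so bidirectional-best-hit results are
#' identical to ranking on the raw scores; it exists so that the E-value
#' cutoff contract of an external phmmer-style search can be exercised
#' without that external tool.
#'
#' @param query,target Named character vectors of protein sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List with `score` and `evalue` matrices (rows = query,
#'   columns = target).
#' @export
alignment_scorer <- function(query, target, gap_open = 11, gap_extend = 1) {
  if (length(query) == 0L || length(target) == 0L) {
    stop_validation("scorer requires nonempty sequence sets")
  }
  if (is.null(names(query)) || is.null(names(target))) {
    stop_validation("sequences must be named")
  }
  BLOSUM62 <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  qset <- Biostrings::AAStringSet(query)
  score <- matrix(0, length(query), length(target),
                  dimnames = list(names(query), names(target)))
  for (j in seq_along(target)) {
    score[, j] <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(target[[j]]), type = "global",
      substitutionMatrix = BLOSUM62,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }
  # Karlin-Altschul-style map; lambda/K for gapped BLOSUM62. Monotone in score.
  lambda <- 0.267; K <- 0.041
  mn <- as.numeric(sum(nchar(query))) * sum(nchar(target))
  evalue <- K * mn * exp(-lambda * score)
  list(score = score, evalue = evalue)
}

#' Bidirectional best-hit ortholog mapping
#'
#' Runs the pluggable similarity scorer in both directions and keeps a pair
#' `(a, b)` iff `b` is `a`'s best hit, `a` is `b`'s best hit, and both
#' directions pass the E-value cutoff. Ties on the best score are broken by
#' lexicographic protein identifier, making the mapping deterministic. The
#' result is one-to-one by construction.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences (names are protein ids).
#' @param scorer A function `(query, target) -> list(score=, evalue=)` of
#'   matrices as returned by [alignment_scorer()] (the default), or an
#'   adapter around an external phmmer-compatible search.
#' @param evalue_cutoff Maximum E-value accepted in each direction.
#' @param genome_a,genome_b Optional [genome()] objects to attach, linking
#'   protein ids to gene records via the genomes' `protein_id` column (or
#'   `gene_id` when protein ids are absent).
#' @return An object of class `ortholog_map`: list with `pairs`
#'   (data.frame `gene_a`, `gene_b`, `score`, `evalue`), `genome_a`,
#'   `genome_b`.
#' @export
best_hits <- function(proteome_a, proteome_b, scorer = alignment_scorer,
                      evalue_cutoff = 1e-10,
                      genome_a = NULL, genome_b = NULL) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L) {
    stop_validation("proteomes must be nonempty")
  }
  ab <- scorer(proteome_a, proteome_b)
  ba <- scorer(proteome_b, proteome_a)
  best_of <- function(score) {
    # Index of best hit per row; ties broken by lexicographic column name.
    ord <- order(colnames(score))
    s <- score[, ord, drop = FALSE]
    colnames(s)[max.col(s, ties.method = "first")]
  }
  best_ab <- best_of(ab$score)  # per protein in A, its best in B
  best_ba <- best_of(ba$score)  # per protein in B, its best in A
  names(best_ab) <- rownames(ab$score)
  names(best_ba) <- rownames(ba$score)
  a_ids <- names(best_ab)
  b_ids <- best_ab
  mutual <- best_ba[b_ids] == a_ids
  pass <- ab$evalue[cbind(a_ids, b_ids)] <= evalue_cutoff &
    ba$evalue[cbind(b_ids, a_ids)] <= evalue_cutoff
  keep <- mutual & pass
  pairs <- data.frame(
    gene_a = a_ids[keep],
    gene_b = unname(b_ids[keep]),
    score = unname(ab$score[cbind(a_ids, b_ids)][keep]),
    evalue = unname(ab$evalue[cbind(a_ids, b_ids)][keep]),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  ortholog_map(pairs, genome_a, genome_b)
}

#' Construct an ortholog map object
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `score`, `evalue`; must be one-to-one in both columns.
#' @param genome_a,genome_b Optional [genome()] objects; required by the
#'   positional statistics. `gene_a`/`gene_b` values must then match either
#'   `protein_id` or `gene_id` entries of the respective genome.
#' @return Object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs, genome_a = NULL, genome_b = NULL) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    stop_validation("ortholog map must be one-to-one")
  }
  if (is.null(pairs$score)) pairs$score <- NA_real_
  if (is.null(pairs$evalue)) pairs$evalue <- NA_real_
  structure(list(pairs = pairs, genome_a = genome_a, genome_b = genome_b),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d one-to-one pairs", nrow(x$pairs)))
  if (!is.null(x$genome_a)) {
    cat(sprintf(" (%s vs %s)", x$genome_a$accession, x$genome_b$accession))
  }
  cat("\n")
  invisible(x)
}

# Resolve map identifiers against a genome's gene table and return the
# per-pair position table for that side. Ids may be protein_id or gene_id.
map_side_positions <- function(ids, genome) {
  pos <- gene_positions(genome)
  g <- genome$genes
  idx <- match(ids, g$protein_id)
  miss <- is.na(idx)
  idx[miss] <- match(ids[miss], g$gene_id)
  if (anyNA(idx)) {
    stop_validation("%d ortholog id(s) not found in genome %s",
                    sum(is.na(idx)), genome$accession)
  }
  pos[idx, , drop = FALSE]
}

#' Per-pair position annotations of an ortholog map
#'
#' Annotates every ortholog pair with each member's normalized oriC
#' distance, replichore, bin, strand and leading-strand status in its own
#' genome.
#'
#' @param map An [ortholog_map()] with both genomes attached.
#' @return data.frame with suffixed columns (`_a`, `_b`).
#' @export
map_positions <- function(map) {
  stopifnot(inherits(map, "ortholog_map"))
  if (is.null(map$genome_a) || is.null(map$genome_b)) {
    stop_validation("ortholog map has no genomes attached")
  }
  pa <- map_side_positions(map$pairs$gene_a, map$genome_a)
  pb <- map_side_positions(map$pairs$gene_b, map$genome_b)
  out <- data.frame(
    gene_a = map$pairs$gene_a, gene_b = map$pairs$gene_b,
    d_a = pa$d_norm, repl_a = pa$replichore, bin_a = pa$bin,
    strand_a = pa$strand, leading_a = pa$leading,
    d_b = pb$d_norm, repl_b = pb$replichore, bin_b = pb$bin,
    strand_b = pb$strand, leading_b = pb$leading,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write / read an ortholog map as TSV
#'
#' @param map An [ortholog_map()].
#' @param path TSV path (columns `gene_a`, `gene_b`, `score`, `evalue`).
#' @return `write_ortholog_map`: invisibly `path`; `read_ortholog_map`: an
#'   [ortholog_map()] (without genomes attached).
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  ortholog_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Select comparable genome pairs
#'
#' Applies the study-design filters to all unordered pairs of genome
#' summaries: 16S rRNA global-alignment identity of at least 97%, identical
#' 16S rRNA copy number (a growth-rate proxy), both genomes at least 1.3 Mb
#' (excluding reduced obligate-parasite genomes with atypically stable gene
#' order), and exclusion of strains of the same species (identical genus +
#' species name tokens). Among accepted pairs of the same unordered
#' species pair, only the lexicographically smallest accession pair is
#' kept, a deterministic stand-in for random de-duplication.
#'
#' @param metadata data.frame with columns `accession`, `organism`,
#'   `seq_16s`, `rrna_16s_count`, `length`.
#' @param identity_min Minimum 16S identity in percent.
#' @param genome_size_min Minimum genome length in bp.
#' @return data.frame audit of every scored pair (`accession_a`,
#'   `accession_b`, `identity_16s`, `same_copy_number`,
#'   `min_genome_size_ok`, `same_species_strains`, `accepted`,
#'   `kept_after_dedup`).
#' @export
select_pairs <- function(metadata, identity_min = 97,
                         genome_size_min = 1.3e6) {
  need <- c("accession", "organism", "seq_16s", "rrna_16s_count", "length")
  if (!all(need %in% names(metadata))) {
    stop_validation("metadata must have columns: %s", paste(need, collapse = ", "))
  }
  n <- nrow(metadata)
  if (n < 2L) stop_validation("need at least two genome summaries")
  species_of <- function(org) {
    toks <- strsplit(trimws(org), "\\s+")
    vapply(toks, function(t) paste(utils::head(t, 2), collapse = " "), "")
  }
  sp <- species_of(metadata$organism)
  combs <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    if (is.na(metadata$seq_16s[i]) || is.na(metadata$seq_16s[j]) ||
        !nzchar(metadata$seq_16s[i]) || !nzchar(metadata$seq_16s[j])) {
      warning(sprintf("skipping pair %s-%s: missing 16S sequence",
                      metadata$accession[i], metadata$accession[j]),
              call. = FALSE)
      return(NULL)
    }
    ident <- nw_identity(metadata$seq_16s[i], metadata$seq_16s[j])
    same_cn <- metadata$rrna_16s_count[i] == metadata$rrna_16s_count[j]
    size_ok <- metadata$length[i] >= genome_size_min &&
      metadata$length[j] >= genome_size_min
    same_sp <- sp[i] == sp[j]
    data.frame(
      accession_a = metadata$accession[i], accession_b = metadata$accession[j],
      species_a = sp[i], species_b = sp[j],
      identity_16s = ident,
      same_copy_number = same_cn,
      min_genome_size_ok = size_ok,
      same_species_strains = same_sp,
      accepted = ident >= identity_min && same_cn && size_ok && !same_sp,
      stringsAsFactors = FALSE
    )
  })
  audit <- do.call(rbind, rows)
  if (is.null(audit)) stop_validation("no scorable pairs")
  # De-duplicate: one pair per unordered species pair, smallest accessions.
  key <- apply(cbind(pmin(audit$species_a, audit$species_b),
                     pmax(audit$species_a, audit$species_b)), 1, paste,
               collapse = "|")
  acc_key <- apply(cbind(pmin(audit$accession_a, audit$accession_b),
                         pmax(audit$accession_a, audit$accession_b)), 1,
                   paste, collapse = "|")
  audit$kept_after_dedup <- FALSE
  for (k in unique(key[audit$accepted])) {
    idx <- which(audit$accepted & key == k)
    audit$kept_after_dedup[idx[order(acc_key[idx])][1]] <- TRUE
  }
  rownames(audit) <- NULL
  audit
}
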