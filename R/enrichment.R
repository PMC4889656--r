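# One-sided Fisher's exact test on a 2x2 table, as a thin wrapper kept in
# one place so the enrichment and depletion paths share it.
fisher_2x2 <- function(tbl, alternative) {
  stats::fisher.test(tbl, alternative = alternative)$p.value
}

#' COG-class positional enrichment per chromosomal bin
#'
#' For each chromosomal bin and each of the 23 single-letter COG functional
#' classes, builds the 2x2 table (in bin & in class, in bin & not in class;
#' out of bin & in class, out of bin & not in class) over the genome's
#' COG-annotated genes, and tests for enrichment with a one-sided Fisher's
#' exact test. P-values are Bonferroni-corrected over the family of
#' 23 classes x 4 bins = 92 tests per genome and reported alongside their
#' negative decadic logarithm (values >= 1.3 correspond to corrected
#' P < 0.05). Genes without a COG annotation are excluded.
#'
#' @param genome A [genome()] object whose genes carry `cog_class`
#'   annotations (either bare class letters or COG identifiers with a
#'   trailing class letter).
#' @return data.frame of class `enrichment_result` rows: `bin`, `category`,
#'   `direction`, the 2x2 counts (`n11`, `n12`, `n21`, `n22`), `p_raw`,
#'   `p_bonferroni`, `neglog10_p`, `significant`.
#' @export
cog_enrichment <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  pos <- gene_positions(genome)
  letter <- cog_letter(genome$genes$cog_class)
  keep <- !is.na(letter) & letter %in% COG_CLASSES
  if (!any(keep)) stop_validation("no COG-annotated genes in genome %s",
                                  genome$accession)
  bin <- pos$bin[keep]
  letter <- letter[keep]
  n_tests <- length(COG_CLASSES) * length(BIN_LEVELS)  # 92
  rows <- list()
  for (b in BIN_LEVELS) {
    in_bin <- bin == b
    for (cl in intersect(COG_CLASSES, unique(letter))) {
      in_class <- letter == cl
      tbl <- matrix(c(sum(in_bin & in_class), sum(in_bin & !in_class),
                      sum(!in_bin & in_class), sum(!in_bin & !in_class)),
                    2, 2, byrow = TRUE)
      p <- fisher_2x2(tbl, "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, category = cl, direction = "enriched",
        n11 = tbl[1, 1], n12 = tbl[1, 2], n21 = tbl[2, 1], n22 = tbl[2, 2],
        p_raw = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * n_tests)
  out$neglog10_p <- -log10(out$p_bonferroni)
  out$significant <- out$neglog10_p >= 1.3
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Read horizontally-acquired-region coordinates (BED-like)
#'
#' Three-column tab-separated input with 0-based half-open intervals
#' (chrom, start, end); converted internally to 1-based inclusive.
#'
#' @param path Path to the BED-like TSV (no header).
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
read_hgt_regions <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop_validation("BED-like input needs 3 columns")
  start <- as.numeric(d[[2]]); end <- as.numeric(d[[3]])
  if (anyNA(start) || anyNA(end) || any(end <= start) || any(start < 0)) {
    stop_validation("malformed interval in BED-like input")
  }
  data.frame(start = start + 1, end = end, stringsAsFactors = FALSE)
}

#' Depletion of horizontally acquired genes per chromosomal bin
#'
#' Genes whose midpoint falls inside any predicted horizontally-acquired
#' region are flagged as HGT. Per bin, a one-sided Fisher's exact test for
#' depletion of HGT genes is run on the 2x2 table (in bin & HGT, in bin &
#' not HGT; out of bin & HGT, out of bin & not HGT), Bonferroni-corrected
#' over the 4 bins. Compositional HGT predictors are only reliable for
#' genomes of intermediate base composition, so genomes with GC content
#' outside 40-60% are skipped with an explicit status rather than tested.
#'
#' @param genome A [genome()] object. Its `gc_percent` field (or the
#'   `gc_percent` argument) gates eligibility; when both are `NULL` the
#'   genome is assumed eligible.
#' @param hgt_regions data.frame of 1-based inclusive intervals (`start`,
#'   `end`), e.g. from [read_hgt_regions()].
#' @param gc_percent Optional override of the genome's GC content.
#' @return List with `status` (`"ok"` or `"skipped_gc"`), `gc_percent`,
#'   and for eligible genomes `results`, an `enrichment_result` data.frame
#'   as in [cog_enrichment()] with `direction = "depleted"`.
#' @export
hgt_depletion <- function(genome, hgt_regions, gc_percent = NULL) {
  stopifnot(inherits(genome, "genome"))
  if (!is.data.frame(hgt_regions) || nrow(hgt_regions) == 0L ||
      !all(c("start", "end") %in% names(hgt_regions))) {
    stop_validation("hgt_regions must be a nonempty data.frame with start, end")
  }
  if (any(hgt_regions$end < hgt_regions$start) || any(hgt_regions$start < 1) ||
      any(hgt_regions$end > genome$length)) {
    stop_validation("malformed HGT interval (outside 1..length or end < start)")
  }
  gc <- gc_percent %||% genome$gc_percent
  if (!is.null(gc) && (gc < 40 || gc > 60)) {
    return(list(status = "skipped_gc", gc_percent = gc, results = NULL))
  }
  pos <- gene_positions(genome)
  mid <- pos$midpoint
  is_hgt <- vapply(mid, function(m) {
    any(m >= hgt_regions$start & m <= hgt_regions$end)
  }, logical(1))
  rows <- lapply(BIN_LEVELS, function(b) {
    in_bin <- pos$bin == b
    tbl <- matrix(c(sum(in_bin & is_hgt), sum(in_bin & !is_hgt),
                    sum(!in_bin & is_hgt), sum(!in_bin & !is_hgt)),
                  2, 2, byrow = TRUE)
    data.frame(
      bin = b, category = "HGT", direction = "depleted",
      n11 = tbl[1, 1], n12 = tbl[1, 2], n21 = tbl[2, 1], n22 = tbl[2, 2],
      p_raw = fisher_2x2(tbl, "less"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * length(BIN_LEVELS))
  out$neglog10_p <- -log10(out$p_bonferroni)
  out$significant <- out$neglog10_p >= 1.3
  class(out) <- c("enrichment_result", class(out))
  list(status = "ok", gc_percent = gc, results = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
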