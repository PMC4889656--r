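#' Construct a circular bacterial genome object
#'
#' A `genome` bundles a circular chromosome's length, its replication origin
#' (oriC) and terminus (ter) coordinates, and a table of protein-coding gene
#' records. All coordinates are 1-based and inclusive, as in NCBI annotation
#' tables; internal circular arithmetic converts to a 0-based frame.
#'
#' @param accession Chromosome accession (or any identifier).
#' @param length Chromosome length in bp.
#' @param oriC Replication origin coordinate (1..length).
#' @param ter Replication terminus coordinate (1..length); must differ from
#'   `oriC`. The bin system is anchored on oriC only, so `ter` is carried as
#'   metadata.
#' @param genes A data.frame of gene records with columns `gene_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), and optionally `protein_id`, `cog_class`,
#'   `product`, `wrapped`. `end < start` is only allowed when `wrapped` is
#'   `TRUE` (gene spanning the sequence origin).
#' @param rrna_16s_count Number of 16S rRNA genes (non-negative integer).
#' @param seq_16s Optional 16S rRNA nucleotide sequence (character scalar).
#' @param doubling_time_h Optional minimum doubling time in hours.
#' @param organism Optional organism name ("Genus species strain ...").
#' @param gc_percent Optional genomic GC content in percent.
#'
#' @return An object of class `genome`.
#' @examples
#' g <- genome("toy", length = 1000, oriC = 1000, ter = 500,
#'             genes = data.frame(gene_id = "g1", start = 190, end = 255,
#'                                strand = "+"))
#' g
#' @export
genome <- function(accession, length, oriC, ter, genes = NULL,
                   rrna_16s_count = 1L, seq_16s = NULL,
                   doubling_time_h = NULL, organism = NULL,
                   gc_percent = NULL) {
  check_scalar_positive(length, "length")
  check_scalar_positive(oriC, "oriC")
  check_scalar_positive(ter, "ter")
  if (oriC > length || ter > length) {
    stop_validation("oriC and ter must lie in 1..length")
  }
  if (oriC == ter) stop_validation("oriC and ter must differ")
  genes <- normalize_gene_table(genes, length)
  if (!is.null(doubling_time_h)) {
    check_scalar_positive(doubling_time_h, "doubling_time_h")
  }
  if (rrna_16s_count < 0) stop_validation("rrna_16s_count must be >= 0")
  structure(
    list(
      accession = as.character(accession),
      length = as.numeric(length),
      oriC = as.numeric(oriC),
      ter = as.numeric(ter),
      genes = genes,
      rrna_16s_count = as.integer(rrna_16s_count),
      seq_16s = if (is.null(seq_16s)) NULL else as.character(seq_16s),
      doubling_time_h = doubling_time_h,
      organism = if (is.null(organism)) NULL else as.character(organism),
      gc_percent = if (is.null(gc_percent)) NULL else as.numeric(gc_percent)
    ),
    class = "genome"
  )
}

# Validate and canonicalise a gene table; sorts by start coordinate.
normalize_gene_table <- function(genes, length) {
  if (is.null(genes) || nrow(genes) == 0L) {
    return(data.frame(
      gene_id = character(), start = numeric(), end = numeric(),
      strand = character(), protein_id = character(),
      cog_class = character(), product = character(), wrapped = logical(),
      stringsAsFactors = FALSE
    ))
  }
  required <- c("gene_id", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    stop_validation("gene table lacks column(s): %s",
                    paste(missing, collapse = ", "))
  }
  for (opt in c("protein_id", "cog_class", "product")) {
    if (is.null(genes[[opt]])) genes[[opt]] <- NA_character_
  }
  if (is.null(genes[["wrapped"]])) genes$wrapped <- FALSE
  genes$wrapped <- genes$wrapped | (genes$end < genes$start)
  bad <- which(genes$start < 1 | genes$start > length | genes$end < 1 |
                 genes$end > length)
  if (length(bad) > 0L) {
    stop_validation("gene coordinates outside 1..%d at row(s) %s",
                    as.integer(length), paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_validation("strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_validation("duplicated gene_id values in gene table")
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes[, c("gene_id", "start", "end", "strand", "protein_id",
            "cog_class", "product", "wrapped")]
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %d genes\n", x$accession,
              format(x$length, big.mark = ","), nrow(x$genes)))
  cat(sprintf("  oriC = %s, ter = %s", format(x$oriC, big.mark = ","),
              format(x$ter, big.mark = ",")))
  if (!is.null(x$organism)) cat("  (", x$organism, ")", sep = "")
  cat("\n")
  if (x$rrna_16s_count > 0) {
    cat(sprintf("  16S rRNA copies: %d%s\n", x$rrna_16s_count,
                if (is.null(x$seq_16s)) "" else " (sequence attached)"))
  }
  invisible(x)
}

#' Gene midpoints on the circle
#'
#' Midpoint of `start..end`, taking the short way around for genes that wrap
#' the sequence origin; result is reduced modulo the genome length into
#' (0, length].
#' @noRd
gene_midpoints <- function(genes, length) {
  end_eff <- ifelse(genes$wrapped, genes$end + length, genes$end)
  mid <- (genes$start + end_eff) / 2
  mid <- circ_mod(mid - 1, length) + 1
  mid
}

#' Read an NCBI PTT-style annotation table
#'
#' Parses the legacy NCBI protein table dialect: a tab-separated table whose
#' first column is `Location` formatted `a..b` (1-based inclusive), followed
#' by `Strand`, `Length`, `PID`, `Gene`, `Synonym`, `COG`, `Product` (the
#' two header lines and the column-name line are detected and skipped when
#' present). A COG value of `"-"` maps to missing.
#'
#' @param path Path to a PTT file (or a connection).
#' @param length Chromosome length in bp (used for validation).
#' @return A gene table data.frame suitable for [genome()].
#' @export
read_ptt <- function(path, length) {
  check_scalar_positive(length, "length")
  lines <- readLines(path, warn = FALSE)
  # Skip preamble: description line, "N proteins" line, header line.
  is_data <- grepl("^[0-9]+\\.\\.[0-9]+\t", lines)
  header_idx <- grep("^Location\t", lines)
  data_lines <- lines[is_data]
  if (length(data_lines) == 0L) {
    # Tolerate an annotation with no protein rows.
    return(normalize_gene_table(NULL, length))
  }
  first_data <- which(is_data)[1]
  junk <- setdiff(seq_len(length(lines)), c(which(is_data), header_idx))
  junk <- junk[junk > first_data & nzchar(trimws(lines[junk]))]
  if (length(junk) > 0L) {
    stop_validation("malformed PTT row at line %d: %s", junk[1],
                    substr(lines[junk[1]], 1, 60))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    bad_line <- which(is_data)[which(nf < 8L)[1]]
    stop_validation("malformed PTT row at line %d: expected 8 tab-separated fields",
                    bad_line)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:8))
  loc <- strsplit(m[, 1], "..", fixed = TRUE)
  start <- as.numeric(vapply(loc, `[`, "", 1L))
  end <- as.numeric(vapply(loc, `[`, "", 2L))
  if (anyNA(start) || anyNA(end)) {
    stop_validation("unparseable Location field in PTT input")
  }
  synonym <- m[, 6]
  gene_name <- m[, 5]
  gene_id <- ifelse(synonym != "-" & nzchar(synonym), synonym,
                    ifelse(gene_name != "-" & nzchar(gene_name),
                           gene_name, paste0("ptt_", seq_along(start))))
  normalize_gene_table(data.frame(
    gene_id = gene_id,
    start = start,
    end = end,
    strand = m[, 2],
    protein_id = ifelse(m[, 4] == "-", NA_character_, m[, 4]),
    cog_class = ifelse(m[, 7] == "-", NA_character_, m[, 7]),
    product = m[, 8],
    stringsAsFactors = FALSE
  ), length)
}

#' Read CDS features from a GFF3 annotation
#'
#' Extracts CDS features (1-based inclusive coordinates, per the GFF3
#' specification) into the same gene-table layout as [read_ptt()]. Gene
#' identifiers come from the `ID`/`locus_tag` attribute, protein identifiers
#' from `protein_id`, COG class from a `cog` attribute when present.
#'
#' @inheritParams read_ptt
#' @return A gene table data.frame suitable for [genome()].
#' @export
read_gff3 <- function(path, length) {
  check_scalar_positive(length, "length")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(normalize_gene_table(NULL, length))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop_validation("malformed GFF3 row at line %d: expected 9 columns",
                    which(nf != 9L)[1])
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "CDS"
  if (!any(keep)) return(normalize_gene_table(NULL, length))
  m <- m[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    val <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", attrs)
    ifelse(grepl(sprintf("(?:^|;)%s=", key), attrs), val, NA_character_)
  }
  ids <- attr_get(m[, 9], "ID")
  locus <- attr_get(m[, 9], "locus_tag")
  gene_id <- ifelse(!is.na(locus), locus,
                    ifelse(!is.na(ids), ids, paste0("gff_", seq_len(nrow(m)))))
  normalize_gene_table(data.frame(
    gene_id = gene_id,
    start = as.numeric(m[, 4]),
    end = as.numeric(m[, 5]),
    strand = m[, 7],
    protein_id = attr_get(m[, 9], "protein_id"),
    cog_class = attr_get(m[, 9], "cog"),
    product = attr_get(m[, 9], "product"),
    stringsAsFactors = FALSE
  ), length)
}

#' Read oriC/ter coordinates from a DoriC-style CSV
#'
#' Expects columns `accession`, `oriC_start`, `oriC_end`, `ter_start`,
#' `ter_end`; the point coordinate of each feature is the midpoint of its
#' interval (computed on the circle when the interval wraps the sequence
#' origin, which requires `length`).
#'
#' @param path CSV path.
#' @param length Optional named numeric vector of chromosome lengths by
#'   accession; needed only for wrapped intervals.
#' @return data.frame with columns `accession`, `oriC`, `ter`.
#' @export
read_doric <- function(path, length = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "oriC_start", "oriC_end", "ter_start", "ter_end")
  if (!all(need %in% names(d))) {
    stop_validation("DoriC CSV must have columns: %s",
                    paste(need, collapse = ", "))
  }
  midpoint <- function(a, b, acc) {
    wrap <- b < a
    if (any(wrap)) {
      if (is.null(length)) {
        stop_validation("wrapped oriC/ter interval needs chromosome `length`")
      }
      len <- length[acc]
      b <- ifelse(wrap, b + len, b)
      m <- (a + b) / 2
      ifelse(!is.na(len) & m > len, m - len, m)
    } else {
      (a + b) / 2
    }
  }
  data.frame(
    accession = d$accession,
    oriC = round(midpoint(d$oriC_start, d$oriC_end, d$accession)),
    ter = round(midpoint(d$ter_start, d$ter_end, d$accession)),
    stringsAsFactors = FALSE
  )
}

#' Write a genome's gene table as a PTT file
#'
#' Emits the NCBI PTT dialect consumed by [read_ptt()]; used so synthetic
#' genomes round-trip through the same readers as real annotations.
#'
#' @param x A [genome()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ptt <- function(x, path) {
  stopifnot(inherits(x, "genome"))
  g <- x$genes
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s - 1..%d", x$accession, as.integer(x$length)), con)
  writeLines(sprintf("%d proteins", nrow(g)), con)
  writeLines(paste("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                   "COG", "Product", sep = "\t"), con)
  if (nrow(g) > 0L) {
    aalen <- pmax(1L, as.integer((ifelse(g$wrapped, g$end + x$length, g$end) -
                                    g$start + 1) %/% 3 - 1L))
    writeLines(sprintf("%d..%d\t%s\t%d\t%s\t-\t%s\t%s\t%s",
                       as.integer(g$start), as.integer(g$end), g$strand, aalen,
                       ifelse(is.na(g$protein_id), "-", g$protein_id),
                       g$gene_id,
                       ifelse(is.na(g$cog_class), "-", g$cog_class),
                       ifelse(is.na(g$product), "-", g$product)), con)
  }
  invisible(path)
}
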