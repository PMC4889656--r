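#' Contact-frequency enrichment at translocated interreplichore loci
#'
#' Tests whether interreplichore locus pairs that show translocations have
#' higher chromosome contact frequencies than interreplichore locus pairs
#' that do not. For every translocated ortholog pair, two loci are placed
#' in the contact-map genome's coordinates: the gene's own position, and
#' its partner's normalized oriC distance projected onto the opposite
#' replichore of the same genome. Each locus maps (by midpoint) to a
#' matrix bin; the resulting unordered bin pairs form the test set. The
#' control set is every other interreplichore matrix-bin pair. A bin pair
#' touched by any translocated locus pair belongs to the test set only.
#' The two contact-frequency distributions are compared with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param contacts Square symmetric numeric matrix of normalized contact
#'   frequencies, bins in genome order starting at coordinate 1.
#' @param profile A [translocation_profile()] for a pair involving the
#'   contact-map genome as genome A.
#' @param genome The [genome()] the contact map belongs to.
#' @param bin_size Matrix bin width in bp; `nrow(contacts) * bin_size`
#'   must equal the genome length to within one bin.
#' @return List with `median_test`, `median_control`, `p_value`,
#'   `n_test`, `n_control`.
#' @export
contact_enrichment <- function(contacts, profile, genome, bin_size) {
  stopifnot(is.matrix(contacts), inherits(profile, "translocation_profile"),
            inherits(genome, "genome"))
  n <- nrow(contacts)
  if (ncol(contacts) != n) stop_validation("contact matrix must be square")
  if (!isTRUE(all.equal(contacts, t(contacts), tolerance = 1e-8))) {
    stop_validation("contact matrix must be symmetric")
  }
  check_scalar_positive(bin_size, "bin_size")
  if (abs(n * bin_size - genome$length) > bin_size) {
    stop_validation("bin_size x nrow(contacts) must match genome length within one bin")
  }
  coord_bin <- function(coord) pmin(n, floor((coord - 1) / bin_size) + 1)
  # Replichore label of each matrix bin, from its center coordinate.
  centers <- pmin(genome$length, (seq_len(n) - 0.5) * bin_size)
  bin_repl <- locate(centers, genome$oriC, genome$length)$replichore
  inter <- outer(bin_repl, bin_repl, "!=") & upper.tri(matrix(0, n, n), diag = FALSE)
  p <- profile$pairs
  if (nrow(p) == 0L) stop_validation("empty translocation profile")
  coord_a <- position_to_coord(p$d_a, p$repl_a, genome$oriC, genome$length)
  # Partner position projected onto this genome: same d_norm, the partner's
  # replichore label (opposite to repl_a for every profile entry).
  coord_b <- position_to_coord(p$d_b, p$repl_b, genome$oriC, genome$length)
  bi <- coord_bin(coord_a); bj <- coord_bin(coord_b)
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  test_mask <- matrix(FALSE, n, n)
  test_mask[cbind(lo, hi)] <- TRUE
  test_mask <- test_mask & inter
  control_mask <- inter & !test_mask
  test <- contacts[test_mask]
  control <- contacts[control_mask]
  if (length(test) == 0L || length(control) == 0L) {
    stop_validation("empty test or control set for contact enrichment")
  }
  wt <- stats::wilcox.test(test, control, alternative = "two.sided",
                           correct = TRUE, exact = FALSE)
  list(
    median_test = stats::median(test),
    median_control = stats::median(control),
    p_value = wt$p.value,
    n_test = length(test),
    n_control = length(control)
  )
}

#' Write / read a contact matrix as dense TSV
#'
#' The header row carries the 1-based start coordinate of each bin.
#'
#' @param contacts Square numeric matrix.
#' @param path TSV path.
#' @param bin_size Bin width in bp.
#' @return `write_contact_matrix`: invisibly `path`;
#'   `read_contact_matrix`: list with `contacts`, `bin_size`.
#' @export
write_contact_matrix <- function(contacts, path, bin_size) {
  starts <- (seq_len(nrow(contacts)) - 1) * bin_size + 1
  colnames(contacts) <- starts
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  starts <- as.numeric(colnames(d))
  m <- as.matrix(d)
  dimnames(m) <- NULL
  bin_size <- if (length(starts) > 1) starts[2] - starts[1] else NA_real_
  list(contacts = m, bin_size = bin_size)
}
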