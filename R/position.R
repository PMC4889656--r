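BIN_LEVELS <- c("O", "R", "T", "L")

#' Locate coordinates in the oriC-anchored replichore system
#'
#' Maps genomic coordinates on a circular chromosome onto the coordinate
#' system used throughout the package: the normalized distance from the
#' replication origin (`d_norm`, the shorter of the two circular arc
#' distances from oriC divided by half the genome length, so 0 at oriC and
#' 1 at the point antipodal to oriC), the replichore (`R` when the shorter
#' arc runs in the increasing-coordinate direction, `L` otherwise; the
#' exactly antipodal point is assigned to `R`), and the chromosomal bin.
#'
#' Bins partition the circle into four equal quarters anchored on oriC
#' only: `O` is the quarter centered on oriC, `R` the next quarter in the
#' increasing-coordinate direction, `T` the quarter containing the point
#' antipodal to oriC, and `L` the remaining quarter. When the two
#' replichores are of unequal physical length (ter not antipodal to oriC),
#' ter may sit off-center within the `T` bin; the bins deliberately do not
#' depend on ter.
#'
#' @param coord Numeric vector of coordinates, 1-based, in `1..length`.
#' @param oriC oriC coordinate (1..length).
#' @param length Chromosome length in bp.
#' @return A data.frame with columns `d_norm`, `replichore`, `bin`.
#' @examples
#' locate(c(1000, 500, 200), oriC = 1000, length = 1000)
#' @export
locate <- function(coord, oriC, length) {
  check_scalar_positive(length, "length")
  check_scalar_positive(oriC, "oriC")
  if (oriC > length) stop_validation("oriC must lie in 1..length")
  if (any(!is.finite(coord)) || any(coord <= 0) || any(coord > length)) {
    stop_validation("coordinates must lie in (0, length]")
  }
  half <- length / 2
  delta <- circ_mod(coord - oriC, length)   # arc from oriC, increasing direction
  on_R <- delta <= half                      # antipodal tie -> R
  d <- ifelse(on_R, delta, length - delta)
  bin <- character(length(delta))
  bin[delta < length / 8 | delta >= 7 * length / 8] <- "O"
  bin[delta >= length / 8 & delta < 3 * length / 8] <- "R"
  bin[delta >= 3 * length / 8 & delta < 5 * length / 8] <- "T"
  bin[delta >= 5 * length / 8 & delta < 7 * length / 8] <- "L"
  data.frame(
    d_norm = d / half,
    replichore = ifelse(on_R, "R", "L"),
    bin = bin,
    stringsAsFactors = FALSE
  )
}

#' Positions of all genes of a genome
#'
#' Genes are represented by the midpoint of their coordinate span (computed
#' on the circle for genes wrapping the sequence origin), a strand-neutral
#' anchor.
#'
#' @param x A [genome()] object.
#' @return data.frame with `gene_id`, `midpoint`, `d_norm`, `replichore`,
#'   `bin`, `strand`, `leading` (`TRUE` when transcription is co-directional
#'   with replication-fork movement on the gene's replichore).
#' @export
gene_positions <- function(x) {
  stopifnot(inherits(x, "genome"))
  g <- x$genes
  if (nrow(g) == 0L) {
    return(data.frame(gene_id = character(), midpoint = numeric(),
                      d_norm = numeric(), replichore = character(),
                      bin = character(), strand = character(),
                      leading = logical(), stringsAsFactors = FALSE))
  }
  mid <- gene_midpoints(g, x$length)
  pos <- locate(mid, x$oriC, x$length)
  data.frame(
    gene_id = g$gene_id,
    midpoint = mid,
    pos,
    strand = g$strand,
    leading = is_leading(g$strand, pos$replichore),
    stringsAsFactors = FALSE
  )
}

# A gene is on the leading strand when its coding strand is co-directional
# with the replication fork on its replichore: "+" on R, "-" on L.
is_leading <- function(strand, replichore) {
  (strand == "+" & replichore == "R") | (strand == "-" & replichore == "L")
}

#' Convert a replichore position back to a genomic coordinate
#'
#' Inverse of [locate()] for the (`d_norm`, `replichore`) part.
#'
#' @param d_norm Normalized oriC distance in `[0, 1]`.
#' @param replichore `"R"` or `"L"` (vectorised).
#' @inheritParams locate
#' @return Numeric coordinate vector in `(0, length]`.
#' @export
position_to_coord <- function(d_norm, replichore, oriC, length) {
  if (any(d_norm < 0 | d_norm > 1)) stop_validation("d_norm must lie in [0, 1]")
  if (!all(replichore %in% c("R", "L"))) {
    stop_validation("replichore must be 'R' or 'L'")
  }
  sgn <- ifelse(replichore == "R", 1, -1)
  circ_mod(oriC + sgn * d_norm * length / 2 - 1, length) + 1
}

# Single-letter COG class from a cog_class field that may hold either a
# bare class letter or a COG identifier with appended class letter(s).
cog_letter <- function(cog) {
  out <- rep(NA_character_, length(cog))
  single <- !is.na(cog) & grepl("^[A-Z]$", cog)
  out[single] <- cog[single]
  tagged <- !is.na(cog) & grepl("^COG[0-9]+[A-Z]", cog)
  out[tagged] <- sub("^COG[0-9]+([A-Z]).*$", "\\1", cog[tagged])
  out
}

# The 23 single-letter COG functional classes considered for positional
# enrichment (information storage and processing; cellular processes and
# signaling; metabolism).
COG_CLASSES <- c("J", "A", "K", "L", "B",
                 "D", "Y", "V", "T", "M", "N", "Z", "W", "U", "O",
                 "C", "G", "E", "F", "H", "I", "P", "Q")
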