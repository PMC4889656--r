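#' Chromosome replication time
#'
#' Time for one full round of bidirectional replication: half the genome
#' length divided by the average in vivo replication-fork speed. The default
#' fork speed of 600 nt/s is a deliberate simplification applied uniformly
#' across organisms; override it per organism when better data exist.
#'
#' @param genome_length Chromosome length in bp.
#' @param fork_speed Replication fork speed in nt/s.
#' @return Replication time in seconds.
#' @examples
#' replication_time(4.6e6)  # ~3833 s
#' @export
replication_time <- function(genome_length, fork_speed = 600) {
  check_scalar_positive(genome_length, "genome_length")
  check_scalar_positive(fork_speed, "fork_speed")
  (genome_length / 2) / fork_speed
}

#' R-factor: replication cycles per cell division
#'
#' The R-factor `R_f = T_R / T_D` relates replication time `T_R` to the
#' minimum doubling time `T_D`. Organisms with `R_f > 1` initiate more than
#' one round of replication per division on average ("fast-growing"), which
#' steepens the oriC-to-ter gene-dosage gradient.
#'
#' @param T_R Replication time in seconds (see [replication_time()]).
#' @param T_D Minimum doubling time in seconds.
#' @return Object of class `growth_profile`: list with `T_R`, `T_D`, `R_f`,
#'   `fast` (strict `R_f > 1`).
#' @examples
#' r_factor(replication_time(4.6e6), T_D = 1200)
#' @export
r_factor <- function(T_R, T_D) {
  check_scalar_positive(T_R, "T_R")
  check_scalar_positive(T_D, "T_D")
  R_f <- T_R / T_D
  structure(list(T_R = T_R, T_D = T_D, R_f = R_f, fast = R_f > 1),
            class = "growth_profile")
}

#' @export
print.growth_profile <- function(x, ...) {
  cat(sprintf("<growth_profile> T_R = %.1f s, T_D = %.1f s, R_f = %.3f (%s-growing)\n",
              x$T_R, x$T_D, x$R_f, if (x$fast) "fast" else "slow"))
  invisible(x)
}

#' Estimate minimum doubling time from rRNA copy number
#'
#' rRNA operon count predicts growth rate (fast growers carry more copies).
#' Given a reference table of organisms with known minimum doubling times,
#' the estimate for a copy number present in the table is the median
#' doubling time of that copy-number class; for an absent copy number the
#' estimate is log-linear interpolation of class medians between the
#' nearest observed copy numbers (clamped to the nearest class beyond the
#' observed range).
#'
#' @param copy_number 16S rRNA copy number (integer >= 1).
#' @param reference data.frame with columns `copy_number`, `doubling_time_h`.
#' @return Estimated minimum doubling time in hours.
#' @examples
#' ref <- data.frame(copy_number = c(7, 7, 2), doubling_time_h = c(0.4, 0.6, 8))
#' doubling_time_from_rrna(7, ref)  # 0.5
#' @export
doubling_time_from_rrna <- function(copy_number, reference) {
  if (!is.numeric(copy_number) || length(copy_number) != 1L ||
      is.na(copy_number) || copy_number < 1) {
    stop_validation("copy_number must be a single integer >= 1")
  }
  if (!is.data.frame(reference) || nrow(reference) == 0L ||
      !all(c("copy_number", "doubling_time_h") %in% names(reference))) {
    stop_validation("reference must be a nonempty data.frame with copy_number and doubling_time_h")
  }
  med <- tapply(reference$doubling_time_h, reference$copy_number, stats::median)
  cls <- as.numeric(names(med))
  if (copy_number %in% cls) {
    return(unname(med[as.character(copy_number)]))
  }
  lo <- max(cls[cls < copy_number], -Inf)
  hi <- min(cls[cls > copy_number], Inf)
  if (!is.finite(lo)) return(unname(med[as.character(hi)]))
  if (!is.finite(hi)) return(unname(med[as.character(lo)]))
  w <- (copy_number - lo) / (hi - lo)
  exp((1 - w) * log(med[as.character(lo)]) + w * log(med[as.character(hi)]))[[1]]
}
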