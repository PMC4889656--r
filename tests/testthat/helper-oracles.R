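# Independent oracles used across the test suite. These re-derive expected
# values by brute force or closed form and must stay independent of the
# implementation paths they check.

# Affine-gap (Gotoh) global alignment oracle. Scores are doubled internally
# so that all arithmetic is exact integer arithmetic (match 5, mismatch -4,
# gap open 10, gap extension 0.5 per residue => 10 / -8 / 20 / 1 doubled).
# Returns the optimal score and the full set of percent identities
# achievable by ANY optimal-score global alignment, computed by dynamic
# programming over the DAG of optimal-path edges. Any correct
# implementation must return an identity from this set.
nw_oracle <- function(a, b, match = 10, mismatch = -8, go = 20, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  sub <- function(i, j) if (A[i] == B[j]) match else mismatch
  # Forward DP. States: 1 = M (aligned pair), 2 = X (gap in b), 3 = Y (gap in a).
  # Row-major fill: X[.,i+1,j] needs row i, Y[.,i,j+1] needs column j.
  Fw <- array(NEG, c(3, n + 1, m + 1))
  Fw[1, 1, 1] <- 0
  for (i in seq_len(n)) Fw[2, i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Fw[3, 1, j + 1] <- -(go + ge * j)
  for (i in 0:n) for (j in 0:m) {
    if (i > 0 && j > 0) {
      Fw[1, i + 1, j + 1] <- max(Fw[, i, j]) + sub(i, j)
    }
    if (i > 0 && j > 0) {
      Fw[2, i + 1, j + 1] <- max(Fw[1, i, j + 1] - go - ge,
                                 Fw[2, i, j + 1] - ge,
                                 Fw[3, i, j + 1] - go - ge)
      Fw[3, i + 1, j + 1] <- max(Fw[1, i + 1, j] - go - ge,
                                 Fw[3, i + 1, j] - ge,
                                 Fw[2, i + 1, j] - go - ge)
    }
  }
  total <- max(Fw[, n + 1, m + 1])
  # Backward DP: best score from each node to the terminal node.
  Bw <- array(NEG, c(3, n + 1, m + 1))
  Bw[, n + 1, m + 1] <- 0
  for (i in (n + 1):1) for (j in (m + 1):1) {
    if (i == n + 1 && j == m + 1) next
    for (s in 1:3) {
      best <- NEG
      if (i <= n && j <= m) {       # into M
        best <- max(best, Bw[1, i + 1, j + 1] + sub(i, j))
      }
      if (i <= n) {                 # into X (consume A[i])
        cost <- if (s == 2) ge else go + ge
        best <- max(best, Bw[2, i + 1, j] - cost)
      }
      if (j <= m) {                 # into Y (consume B[j])
        cost <- if (s == 3) ge else go + ge
        best <- max(best, Bw[3, i, j + 1] - cost)
      }
      Bw[s, i, j] <- best
    }
  }
  # Set of (matches, length) pairs over optimal paths, encoded matches*1000+len.
  enc <- function(mt, ln) mt * 1000 + ln
  sets <- array(vector("list", 3 * (n + 1) * (m + 1)), c(3, n + 1, m + 1))
  sets[[1, 1, 1]] <- enc(0, 0)
  on_opt <- function(s, i, j) Fw[s, i, j] > NEG / 2 &&
    Fw[s, i, j] + Bw[s, i, j] == total
  for (i in 1:(n + 1)) for (j in 1:(m + 1)) for (s in 1:3) {
    cur <- sets[[s, i, j]]
    if (is.null(cur) || !on_opt(s, i, j)) next
    if (i <= n && j <= m) {
      sc <- sub(i, j)
      if (Fw[s, i, j] + sc == Fw[1, i + 1, j + 1]) {
        add <- enc(as.integer(A[i] == B[j]), 1)
        sets[[1, i + 1, j + 1]] <- unique(c(sets[[1, i + 1, j + 1]], cur + add))
      }
    }
    if (i <= n) {
      cost <- if (s == 2) ge else go + ge
      if (Fw[s, i, j] - cost == Fw[2, i + 1, j]) {
        sets[[2, i + 1, j]] <- unique(c(sets[[2, i + 1, j]], cur + enc(0, 1)))
      }
    }
    if (j <= m) {
      cost <- if (s == 3) ge else go + ge
      if (Fw[s, i, j] - cost == Fw[3, i, j + 1]) {
        sets[[3, i, j + 1]] <- unique(c(sets[[3, i, j + 1]], cur + enc(0, 1)))
      }
    }
  }
  final <- unique(unlist(sets[cbind(1:3, n + 1, m + 1)][
    vapply(1:3, function(s) Fw[s, n + 1, m + 1] == total, TRUE)]))
  pids <- vapply(final, function(e) 100 * (e %/% 1000) / (e %% 1000), 0)
  list(score = total / 2, pids = sort(unique(pids)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Brute-force one-sided Fisher p-values from the hypergeometric law, for a
# 2x2 table given as matrix(c(a, b, c, d), 2, 2, byrow = TRUE) with rows
# summing the condition of interest.
hyper_p <- function(tbl, alternative) {
  a <- tbl[1, 1]
  m1 <- tbl[1, 1] + tbl[1, 2]   # row 1 total (draws)
  k1 <- tbl[1, 1] + tbl[2, 1]   # col 1 total (successes in urn)
  N <- sum(tbl)
  xs <- max(0, m1 + k1 - N):min(m1, k1)
  probs <- stats::dhyper(xs, k1, N - k1, m1)
  if (alternative == "greater") sum(probs[xs >= a])
  else sum(probs[xs <= a])
}

# Small helper building a genome with width-1 genes at exactly the given
# midpoints, so position arithmetic in tests is exact.
toy_genome <- function(midpoints, strands = NULL, cogs = NULL,
                       length = 1000, oriC = 1000, ter = 500,
                       gene_width = 1, accession = "TOY") {
  n <- length(midpoints)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(cogs)) cogs <- rep(NA_character_, n)
  start <- ((round(midpoints) - 1) %% length) + 1
  end <- start + gene_width - 1
  wrapped <- end > length
  end[wrapped] <- end[wrapped] - length
  genome(accession, length = length, oriC = oriC, ter = ter,
         genes = data.frame(
           gene_id = sprintf("t%03d", seq_len(n)),
           start = start, end = end, strand = strands,
           protein_id = sprintf("tp%03d", seq_len(n)),
           cog_class = cogs, wrapped = wrapped,
           stringsAsFactors = FALSE))
}

# Identity ortholog map between two toy genomes sharing gene identifiers:
# genes correspond by id, not by coordinate rank.
toy_map <- function(ga, gb) {
  ids <- ga$genes$gene_id
  stopifnot(setequal(ids, gb$genes$gene_id))
  ortholog_map(data.frame(gene_a = ids, gene_b = ids,
                          stringsAsFactors = FALSE),
               genome_a = ga, genome_b = gb)
}
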