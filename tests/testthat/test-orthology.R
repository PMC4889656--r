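test_that("global-alignment identity handles the canonical cases", {
  expect_equal(as.numeric(nw_identity(strrep("ACGTATTGCA", 1),
                                      strrep("ACGTATTGCA", 1))), 100)
  expect_equal(as.numeric(nw_identity("ACGTACGTAC", "ACGTACGTAA")), 90)
  expect_equal(as.numeric(nw_identity("AAAA", "TTTT")), 0)
  expect_error(nw_identity("", "ACGT"), "nonempty")
  expect_error(nw_identity("ACGU", "ACGT"), "A, C, G, T, N")
  expect_silent(nw_identity("ACGTN", "ACGTN"))
})

test_that("identity and score agree with the exhaustive affine-gap oracle", {
  set.seed(42)
  for (k in 1:200) {
    a <- random_dna(sample(3:20, 1))
    b <- random_dna(sample(3:20, 1))
    o <- nw_oracle(a, b)
    impl <- nw_identity(a, b)
    expect_equal(attr(impl, "score"), o$score, tolerance = 1e-9,
                 info = paste(a, b))
    expect_true(min(abs(as.numeric(impl) - o$pids)) < 1e-6,
                info = paste(a, b))
  }
})

# A scripted scorer for exercising the best-hit contract without alignment.
matrix_scorer <- function(score_ab, evalue_ab, score_ba, evalue_ba) {
  function(query, target) {
    if (identical(names(query), rownames(score_ab))) {
      list(score = score_ab, evalue = evalue_ab)
    } else {
      list(score = score_ba, evalue = evalue_ba)
    }
  }
}

test_that("identical proteomes map onto themselves one-to-one", {
  set.seed(7)
  prot <- setNames(vapply(1:12, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "K"), 60, TRUE),
          collapse = "")
  }, ""), sprintf("p%02d", 1:12))
  m <- best_hits(prot, prot)
  expect_equal(nrow(m$pairs), 12L)
  expect_equal(m$pairs$gene_a, m$pairs$gene_b)
})

test_that("non-mutual best hits are dropped and the E-value cutoff is strict", {
  # A1's best is B1, but B1's best is A2 -> A1 unpaired; A2-B1 mutual.
  s_ab <- matrix(c(10, 1, 9, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("A1", "A2"), c("B1", "B2")))
  s_ba <- matrix(c(5, 8, 1, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("B1", "B2"), c("A1", "A2")))
  e_ab <- matrix(1e-20, 2, 2, dimnames = dimnames(s_ab))
  e_ba <- matrix(1e-20, 2, 2, dimnames = dimnames(s_ba))
  m <- best_hits(setNames(c("AA", "AA"), c("A1", "A2")),
                 setNames(c("CC", "CC"), c("B1", "B2")),
                 scorer = matrix_scorer(s_ab, e_ab, s_ba, e_ba))
  expect_false("A1" %in% m$pairs$gene_a)
  expect_true(all(c("A2") %in% m$pairs$gene_a))
  expect_equal(m$pairs$gene_b[m$pairs$gene_a == "A2"], "B1")
  # Mutual best with evalue 1e-9 at cutoff 1e-10 -> excluded.
  e_ab2 <- e_ab; e_ab2["A2", "B1"] <- 1e-9
  m2 <- best_hits(setNames(c("AA", "AA"), c("A1", "A2")),
                  setNames(c("CC", "CC"), c("B1", "B2")),
                  scorer = matrix_scorer(s_ab, e_ab2, s_ba, e_ba))
  expect_false("A2" %in% m2$pairs$gene_a)
})

test_that("best-hit mapping is symmetric under swapping the genomes", {
  set.seed(99)
  alph <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  prot_a <- setNames(vapply(1:10, function(i)
    paste(sample(alph, 50, TRUE), collapse = ""), ""), sprintf("a%02d", 1:10))
  prot_b <- prot_a
  # Perturb a few residues so the two sets differ but remain best hits.
  set.seed(100)
  prot_b[] <- vapply(prot_a, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[sample(50, 3)] <- sample(alph, 3, TRUE)
    paste(ch, collapse = "")
  }, "")
  names(prot_b) <- sprintf("b%02d", 1:10)
  fwd <- best_hits(prot_a, prot_b)
  rev <- best_hits(prot_b, prot_a)
  expect_equal(fwd$pairs$gene_a,
               rev$pairs$gene_b[match(fwd$pairs$gene_b, rev$pairs$gene_a)])
})

test_that("pair selection enforces every study filter", {
  base16s <- random_dna(800)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- chartr("ACGT", "TACG", ch[idx])
    paste(ch, collapse = "")
  }
  meta <- data.frame(
    accession = c("NC_1", "NC_2", "NC_3", "NC_4", "NC_5"),
    organism = c("Escherichia coli K12", "Salmonella enterica LT2",
                 "Escherichia coli O157", "Caulobacter crescentus NA1000",
                 "Buchnera aphidicola Sg"),
    seq_16s = c(base16s, mutate_at(base16s, 8), mutate_at(base16s, 2),
                mutate_at(base16s, 100), mutate_at(base16s, 4)),
    rrna_16s_count = c(7, 7, 7, 2, 7),
    length = c(4.6e6, 4.8e6, 5.4e6, 4.0e6, 0.64e6),
    stringsAsFactors = FALSE
  )
  audit <- select_pairs(meta)
  row_of <- function(a, b) {
    audit[(audit$accession_a == a & audit$accession_b == b) |
            (audit$accession_a == b & audit$accession_b == a), ]
  }
  # E. coli - Salmonella: identity 99% , same copies, big genomes -> accepted.
  expect_true(row_of("NC_1", "NC_2")$accepted)
  # Same species strains rejected despite near-identical 16S.
  expect_false(row_of("NC_1", "NC_3")$accepted)
  expect_true(row_of("NC_1", "NC_3")$same_species_strains)
  # Different copy number rejected (and identity below 97 as well here).
  expect_false(row_of("NC_1", "NC_4")$accepted)
  expect_false(row_of("NC_1", "NC_4")$same_copy_number)
  # Reduced genome (< 1.3 Mb) rejected even at high identity.
  expect_false(row_of("NC_1", "NC_5")$accepted)
  expect_false(row_of("NC_1", "NC_5")$min_genome_size_ok)
  # Identity just below threshold is rejected.
  low <- meta[1:2, ]
  low$seq_16s[2] <- mutate_at(base16s, 26)  # 774/800 = 96.75%
  audit_low <- select_pairs(low)
  expect_lt(audit_low$identity_16s[1], 97)
  expect_false(audit_low$accepted[1])
  # De-duplication keeps exactly one pair per species pair.
  dup <- rbind(meta[1:2, ], within(meta[2, ], accession <- "NC_0"))
  dup$organism[3] <- "Salmonella enterica DT104"
  audit_dup <- select_pairs(dup)
  kept <- audit_dup[audit_dup$kept_after_dedup, ]
  expect_equal(nrow(kept), 1L)
  expect_equal(sort(c(kept$accession_a, kept$accession_b)),
               c("NC_0", "NC_1"))
  # Missing 16S -> skipped with a warning, not an error.
  mis <- meta[1:3, ]
  mis$seq_16s[3] <- NA
  w <- capture_warnings(audit_mis <- select_pairs(mis))
  expect_length(w, 2)  # both pairs touching NC_3 are skipped
  expect_match(w, "missing 16S", all = TRUE)
  expect_equal(nrow(audit_mis), 1L)
})
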