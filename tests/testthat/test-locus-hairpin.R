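test_that("perfect-match loci are found on both strands", {
  set.seed(21)
  m <- "UGAGAAAGGACUGCAUCAUCU"
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  # plant on the minus strand at 1001..1021
  substr(g, 1001, 1021) <- revcomp(as_dna(m))
  genome <- seq_set("chr1", g, "dna")
  loci <- find_perfect_loci(seq_set("m", m, "rna"), genome)
  hit <- loci[loci$start == 1001, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "-")
  expect_equal(hit$end, 1021)

  empty <- find_perfect_loci(seq_set("m", m, "rna"),
                             seq_set("chr1", random_rna(500), "rna") |>
                               (\(x) seq_set("chr1", as_dna(x$seq), "dna"))())
  expect_equal(nrow(empty), 0)
  expect_error(find_perfect_loci(
    seq_set("m", "UGAGAAAGGACUGCAUCAUCN", "rna"), genome), "N")
})

test_that("loci match a naive full-scan oracle on random plantings", {
  set.seed(22)
  m <- random_rna(21)
  md <- as_dna(m)
  n <- 100000L
  g <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  spots <- seq(50, n - 50, by = 997)[1:60]
  strands <- sample(c("+", "-"), length(spots), replace = TRUE)
  for (i in seq_along(spots))
    substr(g, spots[i], spots[i] + 20) <-
      if (strands[i] == "+") md else revcomp(md)
  loci <- find_perfect_loci(seq_set("m", m, "rna"),
                            seq_set("chr", g, "dna"))
  # naive oracle: compare every length-21 substring
  subs <- substring(g, 1:(n - 20), 21:n)
  plus <- which(subs == md)
  minus <- which(subs == revcomp(md))
  expect_setequal(loci$start[loci$strand == "+"], plus)
  expect_setequal(loci$start[loci$strand == "-"], minus)
  expect_true(all(spots %in% loci$start))
})

test_that("find_perfect_loci is strand-symmetric", {
  set.seed(23)
  m <- random_rna(21)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  substr(g, 500, 520) <- as_dna(m)
  substr(g, 1200, 1220) <- revcomp(as_dna(m))
  n <- nchar(g)
  fwd <- find_perfect_loci(seq_set("m", m, "rna"), seq_set("c", g, "dna"))
  rev <- find_perfect_loci(seq_set("m", m, "rna"),
                           seq_set("c", revcomp(g), "dna"))
  # reverse-complementing the genome swaps strands and mirrors coordinates
  mirrored <- data.frame(strand = ifelse(fwd$strand == "+", "-", "+"),
                         start = n - fwd$end + 1L, end = n - fwd$start + 1L)
  expect_setequal(paste(rev$strand, rev$start, rev$end),
                  paste(mirrored$strand, mirrored$start, mirrored$end))
})

test_that("unpairable and forced-stem sequences fold as expected", {
  f <- fold_hairpin(strrep("A", 60))
  expect_equal(f$dG, 0)
  expect_equal(f$structure, strrep(".", 60))

  # G20 + GAAA + C20: a fully stacked GC stem; the MFE register pairs
  # G2..G21 with C25..C44 (hairpin loop AAA), an independent energy sum
  gc <- paste0(strrep("G", 20), "GAAA", strrep("C", 20))
  f <- fold_hairpin(gc, min_len = 40)
  stk <- oracle_energy_tables()$stack
  expected <- 19 * stk["GC", "GC"] + oracle_loop_pen("hairpin", 3)
  expect_equal(f$dG, expected, tolerance = 1e-9)

  # extending a perfect GC stem by 5 bp strictly decreases dG
  arm <- "GCGGCGGCGC"
  short <- paste0(arm, "AAAA", revcomp(arm))
  long <- paste0("GCGCG", arm, "AAAA", revcomp(arm), "CGCGC")
  expect_lt(fold_hairpin(long, min_len = 20)$dG,
            fold_hairpin(short, min_len = 20)$dG)

  expect_error(fold_hairpin(strrep("N", 60)), "all-N")
  expect_error(fold_hairpin("ACGU"), "shorter")
})

test_that("hairpin DP equals exhaustive structure enumeration (<=30 nt)", {
  set.seed(24)
  for (rep in 1:12) {
    n <- sample(15:26, 1)
    s <- random_rna(n)
    expect_equal(fold_hairpin(s, min_len = 10)$dG, oracle_fold_min(s),
                 tolerance = 1e-9, info = s)
  }
})

test_that("folding dG is never positive", {
  set.seed(25)
  for (rep in 1:10)
    expect_lte(fold_hairpin(random_rna(80))$dG, 0)
})

test_that("precursor evaluation accepts planted inverted repeats", {
  set.seed(26)
  m <- random_rna(21)
  arm <- paste0(m, random_rna(19))
  pre <- paste0(arm, random_rna(8), revcomp(arm))
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  substr(g, 1000, 1000 + nchar(pre) - 1) <- as_dna(pre)
  genome <- seq_set("chr1", g, "dna")
  locus <- find_perfect_loci(seq_set("m", m, "rna"), genome)
  locus <- locus[locus$start == 1000, ]
  cand <- evaluate_precursor(locus, genome)
  expect_false(is.null(cand))
  expect_lt(cand$dG, -30)
  expect_equal(cand$mature_arm, "5p")
  expect_gte(cand$mature_paired_fraction, 0.6)
})

test_that("a mature planted in unstructured sequence fails the dG filter", {
  set.seed(27)
  fails <- 0
  for (rep in 1:10) {
    m <- random_rna(21)
    g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    substr(g, 900, 920) <- as_dna(m)
    genome <- seq_set("chr1", g, "dna")
    locus <- find_perfect_loci(seq_set("m", m, "rna"), genome)
    locus <- locus[locus$start == 900 & locus$strand == "+", ]
    if (is.null(evaluate_precursor(locus, genome,
                                   flank_grid = c(40L, 80L))))
      fails <- fails + 1
  }
  expect_gte(fails, 8)   # random context almost never folds below -30
})

test_that("a mature straddling the terminal loop fails the one-arm rule", {
  set.seed(28)
  # build a hairpin whose loop sits inside the mature: stem from the
  # mature's flanks, loop across its middle
  m <- random_rna(21)
  left <- paste0(random_rna(40), substr(m, 1, 9))
  pre <- paste0(left, substr(m, 10, 12), revcomp(left))
  # the mature's first 9 nt sit at the end of the 5' arm, its middle in
  # the loop: full mature spans the terminal loop
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  at <- 800L
  substr(g, at, at + nchar(pre) - 1) <- as_dna(pre)
  mstart <- at + 40L
  locus <- data.frame(mirna_id = "m", chrom = "chr1", strand = "+",
                      start = mstart, end = mstart + 20L,
                      stringsAsFactors = FALSE)
  genome <- seq_set("chr1", g, "dna")
  cand_all <- evaluate_precursor(locus, genome, all_candidates = TRUE,
                                 flank_grid = c(40L, 80L))
  strong <- cand_all[cand_all$dG < -30, , drop = FALSE]
  expect_true(nrow(strong) > 0)
  expect_true(all(strong$mature_arm == "loop"))
  expect_false(any(strong$pass))
})
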