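MIR <- "UGAGAAAGGACUGCAUCAUCU"   # 21 nt

test_that("perfect reverse complement scores zero with 21 WC pairs", {
  a <- score_duplex(MIR, revcomp(MIR))
  expect_equal(a$score, 0)
  expect_equal(a$pairing, strrep("W", 21))
  expect_equal(a$bulge_count, 0)
})

test_that("single substitutions score by position and pair class", {
  site <- revcomp(MIR)
  # substitution opposite miRNA position 15 (site index 21 - 15 + 1 = 7):
  # non-core mismatch, penalty 1.0
  s2 <- site
  substr(s2, 7, 7) <- setdiff(c("A", "C", "G", "U"),
                              c(substr(site, 7, 7), "U",
                                chartr("ACGU", "UGCA", substr(MIR, 15, 15))))[1]
  expect_equal(score_duplex(MIR, s2)$score, 1)
  # G:U wobble opposite a core position: 0.5 doubled = 1.0
  gpos <- which(strsplit(MIR, "")[[1]][2:13] %in% c("G", "U"))[1] + 1
  s3 <- site
  substr(s3, 21 - gpos + 1, 21 - gpos + 1) <-
    if (substr(MIR, gpos, gpos) == "G") "U" else "G"
  expect_equal(score_duplex(MIR, s3)$score, 1)
  expect_true(grepl("G", score_duplex(MIR, s3)$pairing))
})

test_that("banded DP equals exhaustive enumeration on random instances", {
  set.seed(11)
  for (rep in 1:40) {
    L <- sample(19:22, 1)
    m <- random_rna(L)
    v <- sample((L - 1):(L + 1), 1)
    s <- random_rna(v)
    expect_equal(score_duplex(m, s)$score, duplex_oracle_1bulge(m, s),
                 info = paste(m, s))
  }
})

test_that("DP matches the recursive enumeration oracle with two bulges", {
  set.seed(12)
  for (rep in 1:10) {
    m <- random_rna(20)
    v <- sample(18:22, 1)
    s <- random_rna(v)
    expect_equal(score_duplex(m, s, max_bulges = 2)$score,
                 duplex_oracle_enum(m, s, B = 2), info = paste(m, s))
  }
})

test_that("adding a mismatch never decreases the optimal score", {
  set.seed(13)
  for (rep in 1:20) {
    m <- random_rna(21)
    s <- revcomp(m)
    base <- score_duplex(m, s)$score
    pos <- sample(21, 1)
    cur <- substr(s, pos, pos)
    mpos <- 21 - pos + 1
    bad <- c(cur, chartr("ACGU", "UGCA", substr(m, mpos, mpos)))
    repl <- setdiff(c("A", "C", "G", "U"), bad)[1]
    substr(s, pos, pos) <- repl
    expect_gte(score_duplex(m, s)$score, base)
  }
})

test_that("score is invariant under swapping guide and target roles", {
  # the physical duplex is symmetric: treating the (reversed-complemented)
  # site as the guide with the core window remapped yields the same score
  set.seed(14)
  for (rep in 1:10) {
    m <- random_rna(21)
    s <- random_rna(21)
    a <- score_duplex(m, s, max_bulges = 0)$score
    b <- score_duplex(s, m, max_bulges = 0,
                      penalties = list(core_start = 21 - 13 + 1,
                                       core_end = 21 - 2 + 1))$score
    expect_equal(a, b)
  }
})

test_that("cleavage coordinate comes from the pairing walk", {
  a <- score_duplex(MIR, revcomp(MIR))
  expect_equal(predict_cleavage(a, 101, 121), 112)
  expect_equal(predict_cleavage(a, 1, 21), 12)
  # target-side bulge 5' of the cleavage position (between miRNA
  # positions 14 and 15, i.e. left of the paired coordinate on the site)
  site <- revcomp(MIR)
  bulged <- paste0(substr(site, 1, 6), "A", substr(site, 7, 21))
  ab <- score_duplex(MIR, bulged)
  expect_equal(ab$bulge_count, 1)
  # oracle walk: miRNA position 10 pairs site coordinate counted from the
  # 3' end through the ops string
  ops <- strsplit(ab$pairing, "")[[1]]
  pos <- 22 + 1; i <- 0; expected <- NA
  for (op in ops) {
    if (op %in% c("W", "G", "M")) { i <- i + 1; pos <- pos - 1 }
    else if (op == "o") pos <- pos - 1
    else i <- i + 1
    if (i == 10) { expected <- pos; break }
  }
  expect_equal(predict_cleavage(ab, 1, 22), expected)
})

test_that("region labels follow the CDS annotation", {
  ann <- transcript_annotation("t", 100, 400)
  site <- function(s, e) data.frame(transcript_id = "t", site_start = s,
                                    site_end = e)
  expect_equal(classify_region(site(10, 30), ann), "5UTR")
  expect_equal(classify_region(site(150, 170), ann), "CDS")
  expect_equal(classify_region(site(95, 115), ann), "spanning")
  expect_equal(classify_region(site(420, 440), ann), "3UTR")
  expect_warning(
    out <- classify_region(data.frame(transcript_id = "zz",
                                      site_start = 1, site_end = 21), ann),
    "no annotation")
  expect_equal(out, "unknown")
})

test_that("scanner recovers a planted perfect site at its coordinates", {
  set.seed(15)
  tseq <- random_rna(300)
  substr(tseq, 140, 160) <- revcomp(MIR)
  sites <- scan_transcriptome(seq_set("m", MIR, "rna"),
                              seq_set("t", tseq, "rna"))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_start, 140)
  expect_equal(sites$site_end, 160)
  expect_equal(sites$score, 0)
})

test_that("cutoff is strict by default, inclusive on request", {
  set.seed(16)
  # a site engineered to raw score exactly 4.0: two core mismatches
  site <- strsplit(revcomp(MIR), "")[[1]]
  m <- strsplit(MIR, "")[[1]]
  for (i in c(3, 7)) {
    bad <- c(chartr("ACGU", "UGCA", m[i]),
             if (m[i] == "G") "U" else if (m[i] == "U") "G" else NULL,
             site[21 - i + 1])
    site[21 - i + 1] <- setdiff(c("A", "C", "G", "U"), bad)[1]
  }
  site <- paste(site, collapse = "")
  expect_equal(score_duplex(MIR, site)$score, 4)
  tseq <- random_rna(300)
  substr(tseq, 100, 120) <- site
  mirnas <- seq_set("m", MIR, "rna")
  tx <- seq_set("t", tseq, "rna")
  expect_equal(nrow(scan_transcriptome(mirnas, tx)), 0)
  got <- scan_transcriptome(mirnas, tx, inclusive = TRUE)
  expect_equal(got$score, 4)
})

test_that("empty transcript set warns and returns nothing", {
  expect_warning(out <- scan_transcriptome(
    seq_set("m", MIR, "rna"),
    seq_set(character(0), character(0), "rna")[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("sites with ambiguous bases are skipped with a warning", {
  expect_warning(out <- score_duplex(MIR, paste0("N", substr(revcomp(MIR), 2, 21))),
                 "ambiguous")
  expect_null(out)
})
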