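test_that("profiles accumulate 5'-end counts at exact matches", {
  set.seed(31)
  tseq <- random_rna(200)
  tx <- seq_set("t", tseq, "rna")
  lib <- srna_library("d", substr(tseq, 50, 69), 7)
  prof <- build_profile(lib, tx)
  expect_equal(prof$counts, c("50" = 7))

  # two distinct reads sharing a 5' end sum at that position
  lib2 <- srna_library("d", c(substr(tseq, 50, 69), substr(tseq, 50, 71)),
                       c(3, 4))
  expect_equal(build_profile(lib2, tx)$counts, c("50" = 7))

  # a read occurring twice increments both positions
  rep_t <- paste0(substr(tseq, 1, 60), substr(tseq, 31, 60), random_rna(40))
  tx2 <- seq_set("t2", rep_t, "rna")
  lib3 <- srna_library("d", substr(rep_t, 31, 50), 5)
  prof3 <- build_profile(lib3, tx2)
  expect_equal(length(prof3$occupied), 2)
  expect_true(all(prof3$counts == 5))
})

test_that("T-plot categories follow the classification rule", {
  p <- function(pos, cnt) degradome_profile("t", pos, cnt)
  expect_equal(classify_category(p(50, 5), 50), 0)                 # unique max
  expect_equal(classify_category(p(c(50, 60), c(1, 7)), 50), 4)    # single read
  expect_equal(classify_category(p(c(10, 50, 70), c(9, 9, 2)), 50), 1)
  expect_equal(classify_category(p(c(10, 50, 70, 90),
                                   c(10, 5, 2, 1)), 50), 2)  # mean 4.5 < 5
  expect_equal(classify_category(p(c(10, 50, 70, 90),
                                   c(10, 3, 2, 1)), 50), 3)  # 3 <= mean 4
  expect_error(classify_category(p(50, 5), 60), "not occupied")
})

test_that("categories agree with a brute-force rule transcription", {
  set.seed(32)
  for (rep in 1:400) {
    k <- sample(1:12, 1)
    pos <- sample(500, k)
    cnt <- sample(1:10, k, replace = TRUE)
    prof <- degradome_profile("t", pos, cnt)
    for (q in prof$occupied)
      expect_equal(classify_category(prof, q),
                   oracle_category(prof$counts, q))
  }
})

test_that("every occupied position gets exactly one category", {
  set.seed(33)
  prof <- degradome_profile("t", sample(300, 40), sample(1:20, 40,
                                                         replace = TRUE))
  cats <- vapply(prof$occupied, function(q) classify_category(prof, q),
                 integer(1))
  expect_true(all(cats %in% 0:4))
  expect_equal(length(cats), length(prof$occupied))
})

test_that("rank p-values enumerate at-least-as-abundant positions", {
  prof <- degradome_profile("t", c(10, 50, 70, 90), c(10, 5, 2, 1))
  expect_equal(cleavage_pvalue(prof, 10), 0.25)
  expect_equal(cleavage_pvalue(prof, 90), 1.0)
  expect_equal(cleavage_pvalue(degradome_profile("t", 5, 3), 5), 1.0)
})

test_that("p-value is antitone in count; unique max attains 1/occupied", {
  set.seed(34)
  prof <- degradome_profile("t", 1:30, c(50, sample(1:20, 29, replace = TRUE)))
  pv <- vapply(prof$occupied, function(q) cleavage_pvalue(prof, q),
               numeric(1))
  cnts <- as.numeric(prof$counts)
  ord <- order(cnts, decreasing = TRUE)
  expect_true(all(diff(pv[ord]) >= 0))
  expect_equal(min(pv), 1 / length(prof$occupied))
  expect_equal(pv[which.max(cnts)], 1 / 30)
})

test_that("target validation applies the union-over-libraries rule", {
  set.seed(35)
  tseq <- random_rna(300)
  tx <- seq_set("t", tseq, "rna")
  sites <- data.frame(mirna_id = "m", transcript_id = "t",
                      cleavage_pos = 120, stringsAsFactors = FALSE)
  # library A: strong unique peak at 120 over 20 weak noise positions
  noise_pos <- seq(10, 105, by = 5)
  libA <- srna_library("A", c(substr(tseq, 120, 139),
                              substring(tseq, noise_pos, noise_pos + 19)),
                       c(30, rep(1, length(noise_pos))))
  # library B: no reads on this transcript
  libB <- srna_library("B", random_rna(20), 10)
  out <- validate_targets(sites, list(A = libA, B = libB), tx)
  expect_true(out$validated[1])
  expect_equal(nrow(out$calls), 1)        # library B yields no call
  expect_equal(out$calls$category, 0)
  expect_equal(out$calls$library, "A")
  expect_equal(out$summary$categories, "1(0)")
})

test_that("degradome simulation recovers planted peaks as category 0", {
  set.seed(36)
  n_cat0 <- 0; n_sig <- 0; null_fp <- 0; n_null <- 0
  for (rep in 1:60) {
    noise_pos <- sample(setdiff(1:500, 250), 30)
    noise_cnt <- rpois(30, 2)
    keep <- noise_cnt > 0
    prof <- degradome_profile("t", c(250, noise_pos[keep]),
                              c(max(1, rpois(1, 20)), noise_cnt[keep]))
    if (classify_category(prof, 250) == 0) n_cat0 <- n_cat0 + 1
    if (cleavage_pvalue(prof, 250) <= 0.05) n_sig <- n_sig + 1
    # matched null: no planted peak, query a random occupied position
    nprof <- degradome_profile("t", noise_pos[keep], noise_cnt[keep])
    q <- sample(nprof$occupied, 1)
    n_null <- n_null + 1
    if (cleavage_pvalue(nprof, q) <= 0.05) null_fp <- null_fp + 1
  }
  expect_gte(n_cat0 / 60, 0.95)
  expect_gte(n_sig / 60, 0.95)
  expect_lte(null_fp / n_null, 0.05)
})
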