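test_that("phase score follows its closed form and degenerate cases", {
  expect_equal(phase_score(100, 5, 2), 0)      # k < 3
  expect_equal(phase_score(0, 5, 10), 0)       # no phased abundance
  expect_equal(phase_score(100, 0, 5), 3 * log(1001), tolerance = 1e-12)
  expect_error(phase_score(-1, 0, 5), "negative")
  # strictly increasing in k at fixed P > 0, U
  sc <- vapply(3:10, function(k) phase_score(50, 10, k), numeric(1))
  expect_true(all(diff(sc) > 0))
})

test_that("a clean five-cycle register forms one cluster", {
  prof <- stranded_profile("t", c(100, 121, 142, 163, 184),
                           rep(21L, 5), rep("sense", 5), rep(10, 5))
  cl <- detect_phased_clusters(prof, transcript_length = 600)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$k, 5)
  expect_equal(cl$P, 50)
  expect_equal(cl$U, 0)
  expect_equal(cl$score, 3 * log(501), tolerance = 1e-12)
  expect_equal(cl$register, 100 %% 21)
})

test_that("antisense reads join the register via the +2 overhang", {
  prof <- stranded_profile("t", c(100, 121, 142, 119),
                           rep(21L, 4),
                           c("sense", "sense", "sense", "antisense"),
                           rep(10, 4))
  cl <- detect_phased_clusters(prof, min_score = 5,
                               transcript_length = 400)
  expect_equal(nrow(cl), 1)
  # 119 + 2 = 121 == 100 (mod 21): the antisense read is phased
  expect_equal(cl$P, 40)
  expect_equal(cl$k, 3)   # effective coordinates 100, 121 (twice), 142
})

test_that("unphased abundance lowers, phased abundance raises the score", {
  base <- stranded_profile("t", c(100, 121, 142, 163), rep(21L, 4),
                           rep("sense", 4), rep(10, 4))
  s0 <- detect_phased_clusters(base, min_score = 1,
                               transcript_length = 400)$score
  plusU <- stranded_profile("t", c(100, 121, 142, 163, 110, 130),
                            c(rep(21L, 4), 22L, 20L),
                            rep("sense", 6), c(rep(10, 4), 8, 8))
  sU <- detect_phased_clusters(plusU, min_score = 1,
                               transcript_length = 400)$score
  expect_lt(sU, s0)
  plusP <- stranded_profile("t", c(100, 121, 142, 163, 184), rep(21L, 5),
                            rep("sense", 5), rep(10, 5))
  sP <- detect_phased_clusters(plusP, min_score = 1,
                               transcript_length = 400)$score
  expect_gt(sP, s0)
})

test_that("detector equals the brute-force all-windows scan", {
  set.seed(41)
  for (rep in 1:15) {
    n_reads <- sample(5:25, 1)
    prof <- stranded_profile(
      "t", sample(500, n_reads, replace = TRUE),
      sample(18:26, n_reads, replace = TRUE, prob = c(1, 1, 1, 5, 1, 1, 1, 1, 1)),
      sample(c("sense", "antisense"), n_reads, replace = TRUE),
      sample(1:20, n_reads, replace = TRUE))
    got <- detect_phased_clusters(prof, min_score = 0.0001,
                                  transcript_length = 700)
    best_naive <- oracle_best_phase_score(prof, 700)
    if (nrow(got) == 0) expect_lte(best_naive, 0.0001)
    else expect_equal(max(got$score), best_naive, tolerance = 1e-9)
  }
})

test_that("planted eight-cycle clusters beat the threshold; nulls do not", {
  set.seed(42)
  hits <- 0; null_hits <- 0; nsim <- 60
  for (rep in seq_len(nsim)) {
    cl0 <- sample(100:150, 1)
    pos <- cl0 + 21 * (0:7)
    cnt <- pmax(1, round(10 * 0.8^(0:7)))
    P <- sum(cnt)
    # unphased filler at ~10% of the window abundance (phased fraction 0.9)
    upos <- sample(cl0:(cl0 + 140), 4)
    ucnt <- rep(ceiling(P * (1 - 0.9) / 0.9 / 4), 4)
    prof <- stranded_profile("t", c(pos, upos),
                             c(rep(21L, 8), rep(20L, 4)),
                             rep("sense", 12), c(cnt, ucnt))
    got <- detect_phased_clusters(prof, transcript_length = 600)
    if (nrow(got) > 0) hits <- hits + 1
    # null: same reads, uniform placement
    nprof <- stranded_profile("t", sample(550, 12, replace = TRUE),
                              c(rep(21L, 8), rep(20L, 4)),
                              rep("sense", 12), c(cnt, ucnt))
    ngot <- detect_phased_clusters(nprof, transcript_length = 600)
    if (nrow(ngot) > 0) null_hits <- null_hits + 1
  }
  expect_gte(hits / nsim, 0.95)
  expect_lte(null_hits / nsim, 0.05)
})

test_that("cluster registers align with the triggering cleavage site", {
  prof <- stranded_profile("t", 112 + 21 * (0:5), rep(21L, 6),
                           rep("sense", 6), rep(12, 6))
  cl <- detect_phased_clusters(prof, transcript_length = 600)
  expect_equal(phase_register_of_cleavage(cl[1, ], 112), 0)
  expect_equal(phase_register_of_cleavage(cl[1, ], 111), 1)
})

test_that("short transcripts fall back to one truncated window", {
  prof <- stranded_profile("t", c(10, 31, 52), rep(21L, 3),
                           rep("sense", 3), rep(20, 3))
  expect_warning(cl <- detect_phased_clusters(prof, min_score = 1,
                                              transcript_length = 100),
                 "shorter than window")
  expect_equal(nrow(cl), 1)
})
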