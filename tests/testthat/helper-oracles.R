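# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive reimplementations (enumeration, closed forms) that
# never share code with the package's dynamic programs.

RNTS <- c("A", "C", "G", "U")

oracle_pair_penalty <- function(a, b, mismatch = 1, wobble = 0.5) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, 0, ifelse(gu, wobble, mismatch))
}

oracle_core_mult <- function(pos, core = c(2, 13), mult = 2) {
  ifelse(pos >= core[1] & pos <= core[2], mult, 1)
}

# Exhaustive enumeration of all <=1-bulge pairings of a miRNA against one
# site window (sense orientation), via explicit gap placement.
duplex_oracle_1bulge <- function(mirna, site) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  r <- rev(strsplit(site, "", fixed = TRUE)[[1]])
  L <- length(m); S <- length(r)
  best <- Inf
  if (S == L) {
    best <- sum(oracle_pair_penalty(m, r) * oracle_core_mult(seq_len(L)))
  } else if (S == L + 1) {
    # one target-side bulge after g consumed miRNA positions (g in 0..L);
    # attributed to miRNA position min(g+1, L)
    for (g in 0:L) {
      j <- c(seq_len(g), if (g < L) (g + 2):(S) else integer(0))
      pens <- oracle_pair_penalty(m, r[j]) * oracle_core_mult(seq_len(L))
      bp <- 1 * oracle_core_mult(min(g + 1, L))
      best <- min(best, sum(pens) + bp)
    }
  } else if (S == L - 1) {
    # one miRNA-side bulge at miRNA position g
    for (g in seq_len(L)) {
      mi <- setdiff(seq_len(L), g)
      pens <- oracle_pair_penalty(m[mi], r) * oracle_core_mult(mi)
      best <- min(best, sum(pens) + 1 * oracle_core_mult(g))
    }
  }
  best
}

# Recursive enumeration over every alignment with <= B bulges (small
# inputs only).  State: next miRNA index i, next reversed-site index j.
duplex_oracle_enum <- function(mirna, site, B = 1) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  r <- rev(strsplit(site, "", fixed = TRUE)[[1]])
  L <- length(m); S <- length(r)
  rec <- function(i, j, b) {
    if (i > L && j > S) return(0)
    best <- Inf
    if (i <= L && j <= S)
      best <- oracle_pair_penalty(m[i], r[j]) * oracle_core_mult(i) +
        rec(i + 1, j + 1, b)
    if (b < B && i <= L)
      best <- min(best, oracle_core_mult(i) + rec(i + 1, j, b + 1))
    if (b < B && j <= S)
      best <- min(best, oracle_core_mult(min(i, L)) + rec(i, j + 1, b + 1))
    best
  }
  rec(1, 1, 0)
}

# all DP window scores of one miRNA against one transcript (lengths L-1,
# L, L+1), as (start, len, score) rows -- used to cross multiple windows
dp_all_window_scores <- function(mirna, transcript, max_bulges = 1) {
  res <- resistomir:::duplex_scan_cpp(
    mirna, transcript, as.integer(max_bulges), Inf, TRUE, 1, 0.5, 1, 2,
    2L, 13L)
  as.data.frame(res)
}

# ---- folding oracle ---------------------------------------------------------

oracle_energy_tables <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    stk <- as.matrix(read.table(
      system.file("extdata", "nn_stacking.tsv", package = "resistomir"),
      header = TRUE, sep = "\t", row.names = 1))
    colnames(stk) <- rownames(stk)
    lp <- read.table(
      system.file("extdata", "nn_loops.tsv", package = "resistomir"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    tabs <<- list(stack = stk, loops = lp)
    tabs
  }
})

oracle_pair_name <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("AU", "UA", "GC", "CG", "GU", "UG")) key else NA_character_
}

oracle_loop_pen <- function(type, size) {
  lp <- oracle_energy_tables()$loops
  tab <- lp[lp$loop_type == type, ]
  if (size %in% tab$size) return(tab$dG[tab$size == size])
  last <- max(tab$size)
  tab$dG[tab$size == last] + 1.75 * 0.6159 * log(size / last)
}

# Exhaustive search over all single-stem structures of a short sequence:
# chains of nested pairs with stacks/bulges/internal loops and one
# terminal loop (>= 3 nt).  Returns the minimum energy (0 = open chain).
oracle_fold_min <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  stk <- oracle_energy_tables()$stack
  rec <- function(i, j) {
    best <- oracle_loop_pen("hairpin", j - i - 1)
    for (p in (i + 1):(j - 1)) {
      if (p + 4 > j - 1) break
      for (q in (p + 4):(j - 1)) {
        pn <- oracle_pair_name(ch[p], ch[q])
        if (is.na(pn)) next
        l1 <- p - i - 1; l2 <- j - q - 1
        cost <- if (l1 == 0 && l2 == 0)
          stk[oracle_pair_name(ch[i], ch[j]), pn]
        else if (l1 == 0 || l2 == 0) oracle_loop_pen("bulge", l1 + l2)
        else oracle_loop_pen("internal", l1 + l2)
        best <- min(best, cost + rec(p, q))
      }
    }
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i - 1 < 3) next
    if (is.na(oracle_pair_name(ch[i], ch[j]))) next
    best <- min(best, rec(i, j))
  }
  best
}

# Altschul-Erikson dinucleotide shuffle (random Eulerian trail on the
# dinucleotide multigraph, retried until the trail uses every edge)
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  repeat {
    succ <- split(ch[-1], factor(ch[-n], levels = RNTS))
    succ <- lapply(succ, sample)
    out <- character(n)
    out[1] <- ch[1]
    ok <- TRUE
    for (k in 2:n) {
      cur <- out[k - 1]
      nxt <- succ[[cur]]
      if (length(nxt) == 0) { ok <- FALSE; break }
      out[k] <- nxt[1]
      succ[[cur]] <- nxt[-1]
    }
    if (ok && sum(lengths(succ)) == 0) return(paste(out, collapse = ""))
  }
}

# ---- degradome oracle -------------------------------------------------------

# direct transcription of the T-plot category text
oracle_category <- function(counts, position) {
  cnt <- counts[[as.character(position)]]
  if (cnt == 1) return(4L)
  mx <- max(counts)
  n_at_max <- sum(counts == mx)
  if (cnt == mx && n_at_max == 1) return(0L)
  if (cnt == mx) return(1L)
  if (cnt > mean(counts)) return(2L)
  3L
}

# ---- phasing oracle ---------------------------------------------------------

# naive all-windows/all-registers scan returning the best score found
oracle_best_phase_score <- function(profile, tlen, phase = 21,
                                    window = 189) {
  eff <- ifelse(profile$strand == "antisense", profile$position + 2L,
                profile$position)
  best <- 0
  for (ws in seq_len(max(1L, tlen - window + 1L))) {
    we <- ws + window - 1L
    for (r in 0:(phase - 1)) {
      inw <- profile$position >= ws & profile$position <= we &
        profile$length >= 18 & profile$length <= 26
      ph <- inw & profile$length == 21 & (eff %% phase) == r
      P <- sum(profile$count[ph])
      U <- sum(profile$count[inw & !ph])
      k <- length(unique(eff[ph]))
      sc <- if (k >= 3 && P > 0) (k - 2) * log(1 + 10 * P / (1 + U)) else 0
      best <- max(best, sc)
    }
  }
  best
}

# ---- Dollo oracle -----------------------------------------------------------

oracle_tip_set <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tip_set, phy = phy))
}

# count maximal all-absent subtrees beneath a candidate gain node
oracle_loss_count <- function(phy, gain, pres) {
  ntip <- ape::Ntip(phy)
  count <- 0
  recurse <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (k in kids) {
      leaves <- phy$tip.label[oracle_tip_set(phy, k)]
      if (!any(pres[leaves])) count <<- count + 1
      else if (k > ntip) recurse(k)
    }
  }
  if (gain > ntip) recurse(gain)
  count
}

# brute force over all single-gain placements covering the present tips
oracle_dollo <- function(phy, pres) {
  ntip <- ape::Ntip(phy)
  present_tips <- which(pres[phy$tip.label])
  best <- NULL
  for (gain in seq_len(ntip + phy$Nnode)) {
    covered <- all(present_tips %in% oracle_tip_set(phy, gain))
    if (!covered) next
    nl <- oracle_loss_count(phy, gain, pres)
    if (is.null(best) || nl < best$losses) best <- list(gain = gain,
                                                        losses = nl)
  }
  best
}

# ---- misc -------------------------------------------------------------------

random_rna <- function(n) paste(sample(RNTS, n, replace = TRUE),
                                collapse = "")

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
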