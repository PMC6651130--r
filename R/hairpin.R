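# Genome locus mapping and precursor hairpin validation.
#
# Mature miRNAs are mapped to genomes by exact match on both strands
# ("equal length, 100% identity" under T/U equivalence); candidate
# precursors around each locus are folded with a hairpin-restricted
# nearest-neighbor energy model and filtered on dG.

.energy_env <- new.env(parent = emptyenv())

energy_params <- function() {
  if (!is.null(.energy_env$params)) return(.energy_env$params)
  stk <- read.table(system.file("extdata", "nn_stacking.tsv",
                                package = "resistomir"),
                    header = TRUE, sep = "\t", row.names = 1)
  stack6 <- as.matrix(stk)
  colnames(stack6) <- rownames(stack6)
  lp <- read.table(system.file("extdata", "nn_loops.tsv",
                               package = "resistomir"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  # Jacobson-Stockmayer extrapolation beyond tabulated sizes: 1.75*RT*ln(n/n0)
  rt175 <- 1.75 * 0.6159
  nmax <- 500L
  extrap <- function(type, n0) {
    tab <- lp[lp$loop_type == type, ]
    v <- rep(NA_real_, nmax)
    v[tab$size] <- tab$dG
    last <- max(tab$size)
    n <- (last + 1):nmax
    v[n] <- v[last] + rt175 * log(n / last)
    # sizes below the smallest tabulated size are not admissible; keep Inf
    v[seq_len(min(tab$size) - 1)] <- Inf
    v
  }
  .energy_env$params <- list(
    stack = stack6,
    hairpin = extrap("hairpin", 3L),
    bulge = extrap("bulge", 1L),
    internal = extrap("internal", 2L))
  .energy_env$params
}

# ---- perfect-match genome loci ----------------------------------------------

#' Map a mature miRNA to a genome by perfect match
#'
#' Finds every exact, full-length occurrence of the mature sequence on both
#' genome strands, treating T and U as equivalent.  Coordinates are 1-based
#' inclusive on the forward strand; a minus-strand locus means the reverse
#' complement of the genomic substring equals the mature sequence.
#'
#' @param mirna a single-row `seq_set` (RNA) or a named character scalar.
#' @param genome a `seq_set` in DNA alphabet.
#' @return data frame `mirna_id`, `chrom`, `strand`, `start`, `end`,
#'   `matched_seq`, ordered by (chrom, start, strand).
#' @export
find_perfect_loci <- function(mirna, genome) {
  if (inherits(mirna, "seq_set")) {
    stopifnot(nrow(mirna) == 1)
    mid <- mirna$id; mseq <- mirna$seq
  } else {
    mid <- names(mirna); mseq <- as_rna(unname(mirna))
    if (is.null(mid)) mid <- "mirna"
  }
  if (grepl("N", mseq, fixed = TRUE))
    stop("mature sequence contains N; exact matching is undefined")
  pat <- Biostrings::DNAString(as_dna(mseq))
  rcp <- Biostrings::reverseComplement(pat)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    subj <- Biostrings::DNAString(genome$seq[i])
    for (str in c("+", "-")) {
      hits <- Biostrings::matchPattern(if (str == "+") pat else rcp, subj)
      if (length(hits) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = mid, chrom = genome$id[i], strand = str,
        start = Biostrings::start(hits), end = Biostrings::end(hits),
        matched_seq = as.character(hits), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), matched_seq = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- hairpin folding --------------------------------------------------------

#' Fold an RNA sequence into its minimum-free-energy stem-loop
#'
#' Dynamic program over stem-loop structures only: one terminal loop,
#' nested pairs connected by stacks, bulges and internal loops; multibranch
#' loops are excluded because only hairpin precursors are of interest.
#' Admissible pairs are AU/UA/GC/CG/GU/UG with a minimum terminal loop of
#' 3 nt.  Energies are nearest-neighbor stacking free energies plus
#' loop-length penalties (kcal/mol, 37 degrees C) from the bundled tables,
#' with Jacobson-Stockmayer extrapolation for long loops.  An unpairable
#' sequence folds to the open chain at dG = 0; dG is never positive.
#'
#' @param seq RNA sequence, 50-400 nt (shorter allowed via `min_len`).
#' @param max_interior cap on total unpaired bases in one internal
#'   loop/bulge (default 30, the usual nearest-neighbor convention).
#' @param min_len minimal accepted sequence length.
#' @return list `structure` (dot-bracket), `dG` (kcal/mol), `pairs`
#'   (two-column matrix of paired positions, outermost first).
#' @export
fold_hairpin <- function(seq, max_interior = 30L, min_len = 50L) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n < min_len) stop("sequence shorter than ", min_len, " nt")
  if (n > 400) stop("sequence longer than 400 nt")
  if (gsub("N", "", seq) == "") stop("all-N sequence cannot be folded")
  p <- energy_params()
  r <- fold_hairpin_cpp(seq, p$stack, p$hairpin[seq_len(n)],
                        p$bulge[seq_len(n)], p$internal[seq_len(n)],
                        3L, as.integer(max_interior))
  list(structure = r$structure, dG = r$dG,
       pairs = cbind(i = r$pair_i, j = r$pair_j))
}

#' Evaluate precursor candidates around a genome locus
#'
#' Excises windows `(flank5, flank3)` around the mature locus from the
#' genome, folds each window, and applies the precursor filter: dG below
#' `dg_max`, mature contained in one hairpin arm, and at least `min_paired`
#' of mature positions paired.  Returns the best (minimum-dG) passing
#' candidate, or `NULL`.
#'
#' @param locus one row of [find_perfect_loci()] output.
#' @param genome the `seq_set` the locus refers to.
#' @param dg_max dG pass threshold in kcal/mol (default -30).
#' @param min_paired minimum paired fraction of mature positions
#'   (default 0.6); set 0 to disable.
#' @param require_one_arm require the mature inside a single arm
#'   (default TRUE); set FALSE to filter on dG alone.
#' @param flank_grid integer vector of candidate flank lengths applied on
#'   each side (all combinations with precursor length <= 400 are tried).
#' @param all_candidates return every candidate with its verdict instead
#'   of the single best passing one.
#' @return a `hairpin_candidate` list (or data frame of candidates when
#'   `all_candidates = TRUE`), or `NULL` if nothing passes.
#' @export
evaluate_precursor <- function(locus, genome, dg_max = -30,
                               min_paired = 0.6, require_one_arm = TRUE,
                               flank_grid = c(40L, 80L, 120L, 160L, 200L, 240L),
                               all_candidates = FALSE) {
  chrom_seq <- get_seq(genome, locus$chrom)
  glen <- nchar(chrom_seq)
  mlen <- locus$end - locus$start + 1L
  grid <- expand.grid(flank5 = flank_grid, flank3 = flank_grid)
  grid <- grid[mlen + grid$flank5 + grid$flank3 <= 400L, , drop = FALSE]
  cands <- list()
  for (k in seq_len(nrow(grid))) {
    f5 <- grid$flank5[k]; f3 <- grid$flank3[k]
    # flanks are in mature orientation: swap genomic sides on the minus strand
    if (locus$strand == "+") { a <- locus$start - f5; b <- locus$end + f3 }
    else                     { a <- locus$start - f3; b <- locus$end + f5 }
    if (a < 1 || b > glen) {
      warning("locus at contig edge; window (", f5, ",", f3, ") truncated")
      a <- max(1L, a); b <- min(glen, b)
    }
    pre_dna <- substr(chrom_seq, a, b)
    if (locus$strand == "-") pre_dna <- revcomp(pre_dna)
    pre <- as_rna(pre_dna)
    if (nchar(pre) < 50) next
    fr <- fold_hairpin(pre)
    # mature coordinates within the precursor (5'->3' of the mature)
    m1 <- if (locus$strand == "+") locus$start - a + 1L else b - locus$end + 1L
    m2 <- m1 + mlen - 1L
    verdict <- hairpin_verdict(fr, m1, m2, dg_max, min_paired,
                               require_one_arm)
    cands[[length(cands) + 1L]] <- c(list(
      flank5 = f5, flank3 = f3, precursor_seq = pre,
      structure = fr$structure, dG = fr$dG,
      mature_start = m1, mature_end = m2), verdict)
  }
  if (length(cands) == 0) return(NULL)
  if (all_candidates) {
    return(do.call(rbind, lapply(cands, function(cc)
      data.frame(flank5 = cc$flank5, flank3 = cc$flank3, dG = cc$dG,
                 mature_arm = cc$mature_arm,
                 mature_paired_fraction = cc$mature_paired_fraction,
                 pass = cc$pass, stringsAsFactors = FALSE))))
  }
  passing <- Filter(function(cc) cc$pass, cands)
  if (length(passing) == 0) return(NULL)
  best <- passing[[which.min(vapply(passing, `[[`, numeric(1), "dG"))]]
  best$locus <- locus
  class(best) <- "hairpin_candidate"
  best
}

hairpin_verdict <- function(fold, m1, m2, dg_max, min_paired,
                            require_one_arm) {
  pairs <- fold$pairs
  if (nrow(pairs) == 0)
    return(list(mature_arm = "none", mature_paired_fraction = 0,
                pass = FALSE))
  inner <- pairs[nrow(pairs), ]            # hairpin-closing pair
  arm <- if (m2 <= inner[1]) "5p" else if (m1 >= inner[2]) "3p" else "loop"
  paired_pos <- c(pairs[, 1], pairs[, 2])
  frac <- mean(seq(m1, m2) %in% paired_pos)
  pass <- fold$dG < dg_max && frac >= min_paired &&
    (!require_one_arm || arm %in% c("5p", "3p"))
  list(mature_arm = arm, mature_paired_fraction = frac, pass = pass)
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin_candidate: dG =", round(x$dG, 2), "kcal/mol, arm =",
      x$mature_arm, ", paired fraction =",
      round(x$mature_paired_fraction, 2), "\n")
  cat(" precursor length", nchar(x$precursor_seq), "nt, flanks (",
      x$flank5, ",", x$flank3, ")\n")
  invisible(x)
}
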