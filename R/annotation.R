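# Lightweight NB-LRR / coiled-coil domain annotation and target-site
# conservation profiling.
#
# The detectors are deliberately simple motif scans -- enough to label
# NB-LRR-like proteins in a controlled study: P-loop, kinase-2 and GLPL
# motifs for the nucleotide-binding (NB) module, L..L.L repeats for the
# LRR block, and a heptad hydrophobicity score for coiled-coil (CC)
# windows.  They are not substitutes for profile-HMM searches on real
# proteomes.

#' Scan a protein for NB, LRR and CC signatures
#'
#' Motifs: P-loop `[AG]-x(4)-G-K-[ST]`; kinase-2 `[LIVMF](3)-[DE]-D`;
#' GLPL `G-L-P-L`; LRR `L-x-x-L-x-L`.  Coiled-coil score per 28-residue
#' window is the best over the 7 heptad frames of the fraction of a/d
#' positions occupied by L/I/V/M/F/A; windows scoring at least
#' `cc_threshold` count as CC.
#'
#' Class rules: `N` needs a P-loop plus (kinase-2 or GLPL); `NL`
#' additionally at least `min_lrr` LRR motifs; `CNL` additionally at
#' least one CC window; anything else is `none`.
#'
#' @param protein protein sequence string or single-row `seq_set`.
#' @param cc_threshold coiled-coil score threshold (default 0.6).
#' @param min_lrr LRR motif count needed for the LRR block (default 3).
#' @return a `domain_call` list: `motifs` (data frame of hits with
#'   positions), `lrr_motif_count`, `cc_windows`, `class`.
#' @export
scan_domains <- function(protein, cc_threshold = 0.6, min_lrr = 3L) {
  if (inherits(protein, "seq_set")) {
    pid <- protein$id[1]; seq <- protein$seq[1]
  } else { pid <- "protein"; seq <- toupper(protein) }
  if (grepl("\\*", sub("\\*$", "", seq)))
    warning("internal stop codon in protein ", pid, "; scan continues")
  pats <- c(p_loop = "[AG].{4}GK[ST]", kinase2 = "[LIVMF]{3}[DE]D",
            glpl = "GLPL", lrr = "L..L.L")
  hit_rows <- list()
  for (nm in names(pats)) {
    m <- gregexpr(pats[[nm]], seq, perl = TRUE)[[1]]
    if (m[1] != -1)
      hit_rows[[nm]] <- data.frame(motif = nm, start = as.integer(m),
                                   end = as.integer(m) + attr(m, "match.length") - 1L,
                                   stringsAsFactors = FALSE)
  }
  motifs <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0))
  rownames(motifs) <- NULL
  cc <- cc_windows(seq, threshold = cc_threshold)
  lrr_n <- sum(motifs$motif == "lrr")
  has_ploop <- any(motifs$motif == "p_loop")
  has_k2_or_glpl <- any(motifs$motif %in% c("kinase2", "glpl"))
  class <- "none"
  if (has_ploop && has_k2_or_glpl) {
    class <- "N"
    if (lrr_n >= min_lrr) {
      class <- "NL"
      if (nrow(cc) >= 1) class <- "CNL"
    }
  }
  structure(list(protein_id = pid, motifs = motifs,
                 lrr_motif_count = lrr_n, cc_windows = cc, class = class),
            class = "domain_call")
}

#' @export
print.domain_call <- function(x, ...) {
  cat("domain_call '", x$protein_id, "': class ", x$class, " (",
      nrow(x$motifs), " motif hits, ", x$lrr_motif_count, " LRR, ",
      nrow(x$cc_windows), " CC windows)\n", sep = "")
  invisible(x)
}

# best-of-7-frames heptad a/d hydrophobic occupancy per 28-residue window
cc_windows <- function(seq, window = 28L, threshold = 0.6) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hydro <- chars %in% c("L", "I", "V", "M", "F", "A")
  out <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  if (n < window) return(out)
  for (st in seq_len(n - window + 1L)) {
    idx <- st:(st + window - 1L)
    best <- 0
    for (f in 0:6) {
      ad <- ((idx - st + f) %% 7) %in% c(0L, 3L)   # heptad a and d slots
      best <- max(best, mean(hydro[idx][ad]))
    }
    if (best >= threshold)
      out <- rbind(out, data.frame(start = st, end = st + window - 1L,
                                   score = best))
  }
  # merge touching windows into maximal intervals
  if (nrow(out) > 1) {
    grp <- cumsum(c(1, as.integer(out$start[-1] > cummax(out$end)[-nrow(out)])))
    out <- do.call(rbind, lapply(split(out, grp), function(g)
      data.frame(start = min(g$start), end = max(g$end),
                 score = max(g$score))))
    rownames(out) <- NULL
  }
  out
}

#' Scan a protein seq_set for domain classes
#' @param proteins `seq_set` (protein alphabet).
#' @param ... passed to [scan_domains()].
#' @return data frame `protein_id`, `class`, `lrr_motif_count`,
#'   `n_cc_windows`.
#' @export
annotate_proteins <- function(proteins, ...) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    dc <- scan_domains(proteins[i, ], ...)
    data.frame(protein_id = dc$protein_id, class = dc$class,
               lrr_motif_count = dc$lrr_motif_count,
               n_cc_windows = nrow(dc$cc_windows), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Information-content profile of target sites versus flanks
#'
#' Stacks the (bulge-free) target-site sequences of one miRNA by miRNA
#' position and computes the per-column information content
#' `IC = 2 + sum_b f_b log2 f_b` (bits, 0..2); equal-length windows
#' immediately up- and downstream serve as the flank comparison.  Target
#' sites are expected to be markedly more conserved than their flanks
#' when one miRNA captures a gene family.
#'
#' @param sites rows of [scan_transcriptome()] output for one miRNA
#'   (>= 2 bulge-free sites required).
#' @param transcripts `seq_set` holding the target transcripts.
#' @param flank flank window length (default 21).
#' @return list `site_ic`, `flank_ic` (per-column bits), `mean_site_ic`,
#'   `mean_flank_ic`, `n_sites`; or `NULL` when fewer than two usable
#'   sites exist.
#' @export
site_conservation <- function(sites, transcripts, flank = 21L) {
  sites <- sites[sites$bulge_count == 0, , drop = FALSE]
  if (nrow(sites) < 2) return(NULL)
  site_rows <- character(0); up_rows <- character(0); dn_rows <- character(0)
  for (i in seq_len(nrow(sites))) {
    tseq <- get_seq(transcripts, sites$transcript_id[i])
    s <- sites$site_start[i]; e <- sites$site_end[i]
    if (s - flank < 1 || e + flank > nchar(tseq)) next
    site_rows <- c(site_rows, substr(tseq, s, e))
    up_rows <- c(up_rows, substr(tseq, s - flank, s - 1))
    dn_rows <- c(dn_rows, substr(tseq, e + 1, e + flank))
  }
  if (length(site_rows) < 2) return(NULL)
  # stack by miRNA position: all bulge-free sites share the site length
  L <- min(nchar(site_rows))
  site_ic <- column_ic(substr(site_rows, 1, L))
  flank_ic <- c(column_ic(up_rows), column_ic(dn_rows))
  list(site_ic = site_ic, flank_ic = flank_ic,
       mean_site_ic = mean(site_ic), mean_flank_ic = mean(flank_ic),
       n_sites = length(site_rows))
}

column_ic <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  apply(mat, 2, function(col) {
    f <- table(col) / length(col)
    2 + sum(f * log2(f))
  })
}
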