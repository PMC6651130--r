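# miRNA target prediction by antisense duplex penalty scoring.
#
# The canonical plant-target scheme: mismatch 1.0, G:U wobble 0.5, each
# single-nucleotide bulge 1.0, all penalties doubled in the core (miRNA
# positions 2-13 from the 5' end).  The reported score is the minimum over
# admissible pairings, computed by a banded dynamic program; sites scoring
# strictly below the cutoff (default 4) are reported.

DUPLEX_DEFAULTS <- list(mismatch = 1, wobble = 0.5, bulge = 1,
                        core_mult = 2, core_start = 2L, core_end = 13L)

#' Score a miRNA:target-site duplex
#'
#' The miRNA pairs antiparallel with the site: miRNA position 1 (5' end)
#' faces the last base of the site.  A target-side bulge between miRNA
#' positions i and i+1 is attributed to position i+1 for the core-doubling
#' rule.  Ties between equal-score pairings are broken towards fewer
#' bulges, then more Watson-Crick pairs.
#'
#' @param mirna mature miRNA sequence (RNA, 5'->3'), 19-25 nt, or a
#'   single-row `seq_set`.
#' @param site_seq target-site sequence on the transcript sense strand
#'   (5'->3'); length within miRNA length +/- `max_bulges`.
#' @param max_bulges maximum bulged nucleotides over both strands.
#' @param penalties list overriding entries of the default scheme
#'   (`mismatch`, `wobble`, `bulge`, `core_mult`, `core_start`, `core_end`).
#' @return a `duplex_alignment` list: `score`, `pairing` (one symbol per
#'   duplex column from the miRNA 5' end: `W` Watson-Crick, `G` G:U,
#'   `M` mismatch, `x` miRNA-side bulge, `o` target-side bulge),
#'   `bulge_count`, `wc_count`, `mirna_len`, `site_len`.  `score` is
#'   `Inf` when the lengths are incompatible with `max_bulges`.
#' @export
score_duplex <- function(mirna, site_seq, max_bulges = 1L,
                         penalties = list()) {
  if (inherits(mirna, "seq_set")) mirna <- mirna$seq[1]
  m <- as_rna(mirna); s <- as_rna(site_seq)
  if (nchar(m) < 19 || nchar(m) > 25)
    stop("miRNA length must be 19-25 nt")
  if (grepl("N", s, fixed = TRUE)) {
    warning("site contains ambiguous nucleotides (N); skipped")
    return(NULL)
  }
  p <- utils::modifyList(DUPLEX_DEFAULTS, penalties)
  r <- duplex_dp_cpp(m, s, as.integer(max_bulges), p$mismatch, p$wobble,
                     p$bulge, p$core_mult, as.integer(p$core_start),
                     as.integer(p$core_end))
  structure(list(score = r$score, pairing = r$ops,
                 bulge_count = if (is.finite(r$score)) r$bulges else NA_integer_,
                 wc_count = if (is.finite(r$score)) r$wc else NA_integer_,
                 mirna_len = nchar(m), site_len = nchar(s)),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex_alignment: score", x$score, "| pairing", x$pairing,
      "|", x$bulge_count, "bulge(s)\n")
  invisible(x)
}

#' Predict the slicer cleavage coordinate of a duplex site
#'
#' Cleavage falls between miRNA positions 10 and 11; the returned value is
#' the transcript coordinate paired with miRNA position 10 (for a
#' bulge-free 21-nt site spanning `[s, e]` this is `e - 9`).  With bulges
#' the coordinate is obtained by walking the pairing string, never by
#' arithmetic.
#'
#' @param aln a `duplex_alignment` from [score_duplex()].
#' @param site_start,site_end 1-based transcript coordinates of the site.
#' @return the transcript coordinate paired with miRNA position 10.
#' @export
predict_cleavage <- function(aln, site_start, site_end) {
  ops <- strsplit(aln$pairing, "", fixed = TRUE)[[1]]
  if (sum(ops %in% c("W", "G", "M")) < 10)
    stop("fewer than 10 paired miRNA positions")
  pos <- site_end + 1L   # walking 3'->5' along the site
  i <- 0L
  for (op in ops) {
    if (op %in% c("W", "G", "M")) { i <- i + 1L; pos <- pos - 1L }
    else if (op == "o") pos <- pos - 1L     # extra target base
    else i <- i + 1L                        # miRNA bulge: no site movement
    if (i == 10L) {
      if (op == "x") {
        warning("miRNA position 10 is bulged; no paired coordinate")
        return(NA_real_)
      }
      return(pos)
    }
  }
  stop("pairing string exhausted before miRNA position 10")
}

#' Scan a transcriptome for miRNA target sites
#'
#' Slides each miRNA over every transcript window whose length is within
#' `max_bulges` of the miRNA length, scores the duplex, and reports sites
#' with score strictly below `cutoff` (set `inclusive = TRUE` for the <=
#' convention).  Overlapping windows describing the same underlying site
#' are collapsed to the best-scoring window (ties towards fewer bulges,
#' then leftmost).
#'
#' @param mirnas `seq_set` of mature miRNAs (RNA).
#' @param transcripts `seq_set` of transcripts (RNA).
#' @param cutoff score cutoff (default 4).
#' @param max_bulges maximum bulges per duplex (default 1).
#' @param inclusive use score <= cutoff instead of strict <.
#' @param annotation optional [transcript_annotation()] for region labels.
#' @param penalties passed to [score_duplex()].
#' @return data frame of target sites: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end`, `score`, `pairing`, `bulge_count`,
#'   `cleavage_pos`, `region`, sorted by (transcript, site_start).
#' @export
scan_transcriptome <- function(mirnas, transcripts, cutoff = 4,
                               max_bulges = 1L, inclusive = FALSE,
                               annotation = NULL, penalties = list()) {
  stopifnot(cutoff > 0)
  if (nrow(transcripts) == 0) {
    warning("empty transcript set")
    return(empty_sites())
  }
  p <- utils::modifyList(DUPLEX_DEFAULTS, penalties)
  hits <- list()
  for (mi in seq_len(nrow(mirnas))) {
    m <- mirnas$seq[mi]
    for (ti in seq_len(nrow(transcripts))) {
      tseq <- transcripts$seq[ti]
      cand <- duplex_scan_cpp(m, tseq, as.integer(max_bulges), cutoff,
                              inclusive, p$mismatch, p$wobble, p$bulge,
                              p$core_mult, as.integer(p$core_start),
                              as.integer(p$core_end))
      if (nrow(cand) == 0) next
      # full DP with traceback only on the few windows below the cutoff
      for (ci in seq_len(nrow(cand))) {
        st <- cand$site_start[ci]; v <- cand$site_len[ci]
        r <- duplex_dp_cpp(m, substr(tseq, st, st + v - 1L),
                           as.integer(max_bulges), p$mismatch, p$wobble,
                           p$bulge, p$core_mult, as.integer(p$core_start),
                           as.integer(p$core_end))
        hits[[length(hits) + 1L]] <- data.frame(
          mirna_id = mirnas$id[mi], transcript_id = transcripts$id[ti],
          site_start = st, site_end = st + v - 1L, score = r$score,
          pairing = r$ops, bulge_count = r$bulges,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(empty_sites())
  sites <- do.call(rbind, hits)
  sites <- collapse_overlapping_sites(sites)
  sites$cleavage_pos <- vapply(seq_len(nrow(sites)), function(i) {
    aln <- list(pairing = sites$pairing[i])
    predict_cleavage(aln, sites$site_start[i], sites$site_end[i])
  }, numeric(1))
  sites$region <- if (is.null(annotation)) "unknown" else
    vapply(seq_len(nrow(sites)), function(i)
      classify_region(sites[i, ], annotation), character(1))
  sites <- sites[order(sites$transcript_id, sites$site_start), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_sites <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             site_start = integer(0), site_end = integer(0),
             score = numeric(0), pairing = character(0),
             bulge_count = integer(0), cleavage_pos = numeric(0),
             region = character(0), stringsAsFactors = FALSE)
}

# Keep, per (miRNA, transcript), only local optima among mutually
# overlapping windows: a shifted window over a real site scores higher and
# would otherwise duplicate the hit.
collapse_overlapping_sites <- function(sites) {
  keep <- logical(0)
  out <- list()
  for (key in unique(paste(sites$mirna_id, sites$transcript_id))) {
    g <- sites[paste(sites$mirna_id, sites$transcript_id) == key, ,
               drop = FALSE]
    g <- g[order(g$score, g$bulge_count, g$site_start), , drop = FALSE]
    chosen <- g[0, ]
    for (i in seq_len(nrow(g))) {
      overlaps <- nrow(chosen) > 0 &&
        any(g$site_start[i] <= chosen$site_end &
            g$site_end[i] >= chosen$site_start)
      if (!overlaps) chosen <- rbind(chosen, g[i, ])
    }
    out[[key]] <- chosen
  }
  do.call(rbind, out)
}

#' Label a target site by transcript region
#'
#' @param site one row of [scan_transcriptome()] output (needs
#'   `transcript_id`, `site_start`, `site_end`).
#' @param annotation a [transcript_annotation()].
#' @return one of `"5UTR"`, `"CDS"`, `"3UTR"`, `"spanning"`, `"unknown"`.
#' @export
classify_region <- function(site, annotation) {
  i <- match(site$transcript_id, annotation$transcript_id)
  if (is.na(i)) {
    warning("no annotation for transcript ", site$transcript_id)
    return("unknown")
  }
  cs <- annotation$cds_start[i]; ce <- annotation$cds_end[i]
  if (site$site_end < cs) return("5UTR")
  if (site$site_start > ce) return("3UTR")
  if (site$site_start >= cs && site$site_end <= ce) return("CDS")
  "spanning"
}
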