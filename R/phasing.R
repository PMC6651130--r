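# 21-nt phased siRNA (phasiRNA) cluster detection on target transcripts.
#
# Slicer cleavage by 21/22-nt miRNAs can convert a transcript into a
# substrate for RDR6/DCL4 processing, yielding siRNAs in head-to-tail
# 21-nt registers downstream of the cleavage site.  Registers are scored
# with a log-scale phase score and clusters above the threshold (15) are
# reported.

#' Phase score of a window/register
#'
#' `score = (k - 2) * ln(1 + 10 * P / (1 + U))` for `k >= 3` and `P > 0`,
#' else 0 -- where `P` is phased abundance, `U` unphased abundance and `k`
#' the number of distinct occupied phase positions.
#'
#' @param P phased abundance (>= 0).
#' @param U unphased abundance (>= 0).
#' @param k occupied phase positions (integer >= 0).
#' @return non-negative score.
#' @export
phase_score <- function(P, U, k) {
  if (any(c(P, U, k) < 0)) stop("negative inputs to phase_score")
  if (k < 3 || P == 0) return(0)
  (k - 2) * log(1 + 10 * P / (1 + U))
}

#' Construct a stranded small RNA alignment profile
#'
#' @param transcript_id transcript name.
#' @param position 5'-end positions (1-based transcript coordinates).
#' @param length read lengths (nt).
#' @param strand `"sense"` or `"antisense"` per read.
#' @param count abundances (>= 1).
#' @return a `stranded_profile` data frame.
#' @export
stranded_profile <- function(transcript_id, position, length, strand,
                             count) {
  stopifnot(all(strand %in% c("sense", "antisense")), all(count >= 1),
            all(position >= 1))
  out <- data.frame(position = as.integer(position),
                    length = as.integer(length),
                    strand = strand, count = as.numeric(count),
                    stringsAsFactors = FALSE)
  attr(out, "transcript_id") <- transcript_id
  class(out) <- c("stranded_profile", "data.frame")
  out
}

#' Align a small RNA library to a transcript as a stranded profile
#'
#' Exact-match placement of 15-34-nt reads on both the transcript and its
#' reverse complement; antisense positions are reported as the transcript
#' coordinate of the read's 5' end (its rightmost transcript base).
#'
#' @param library an [srna_library()].
#' @param transcript single-row `seq_set` (RNA).
#' @return a [stranded_profile()].
#' @export
align_library_to_transcript <- function(library, transcript) {
  stopifnot(nrow(transcript) == 1)
  tseq <- transcript$seq
  pos <- integer(0); len <- integer(0); strand <- character(0)
  cnt_v <- numeric(0)
  for (i in seq_len(nrow(library$reads))) {
    rs <- library$reads$seq[i]
    cnt <- library$reads$count[i]
    hits <- exact_match_starts(rs, tseq)
    if (length(hits)) {
      pos <- c(pos, hits); len <- c(len, rep(nchar(rs), length(hits)))
      strand <- c(strand, rep("sense", length(hits)))
      cnt_v <- c(cnt_v, rep(cnt, length(hits)))
    }
    rc_hits <- exact_match_starts(revcomp(rs), tseq)
    if (length(rc_hits)) {
      # antisense 5' end sits at the match's right edge on the transcript
      pos <- c(pos, rc_hits + nchar(rs) - 1L)
      len <- c(len, rep(nchar(rs), length(rc_hits)))
      strand <- c(strand, rep("antisense", length(rc_hits)))
      cnt_v <- c(cnt_v, rep(cnt, length(rc_hits)))
    }
  }
  df <- data.frame(position = pos, length = len, strand = strand,
                   count = cnt_v, stringsAsFactors = FALSE)
  stranded_profile(transcript$id, df$position, df$length, df$strand,
                   df$count)
}

# effective phase coordinate of a read: antisense reads carry the 2-nt
# 3' overhang of the duplex, so their 5' end sits 2 nt 3' of the register
phase_coordinate <- function(position, strand) {
  ifelse(strand == "antisense", position + 2L, position)
}

#' Detect 21-nt phased siRNA clusters
#'
#' Slides a window (default 189 nt = 9 phase cycles) along the transcript.
#' Within a window, 21-nt reads whose effective phase coordinate (sense 5'
#' position; antisense 5' position + 2 for the two-nt overhang) is
#' congruent to register `r` (mod 21) are phased; all other 18-26-nt read
#' abundance is unphased.  Windows whose best register scores above
#' `min_score` are merged into maximal clusters, each reporting its
#' best-scoring window.
#'
#' @param profile a [stranded_profile()].
#' @param phase phase length (default 21).
#' @param window window size, a multiple of `phase` (default 189).
#' @param min_score cluster emission threshold (default 15; strictly >).
#' @param transcript_length optional; defaults to the largest read end.
#' @return data frame of clusters: `transcript_id`, `window_start`,
#'   `window_end`, `register`, `P`, `U`, `k`, `score`.
#' @export
detect_phased_clusters <- function(profile, phase = 21L, window = 189L,
                                   min_score = 15,
                                   transcript_length = NULL) {
  stopifnot(window %% phase == 0)
  tid <- attr(profile, "transcript_id")
  empty <- data.frame(transcript_id = character(0), window_start = integer(0),
                      window_end = integer(0), register = integer(0),
                      P = numeric(0), U = numeric(0), k = integer(0),
                      score = numeric(0))
  if (nrow(profile) == 0) return(empty)
  if (is.null(transcript_length))
    transcript_length <- max(profile$position + profile$length - 1L)
  if (transcript_length < window) {
    warning("transcript shorter than window; using one truncated window")
    starts <- 1L
    window <- transcript_length
  } else {
    starts <- seq.int(1L, transcript_length - window + 1L)
  }
  eff <- phase_coordinate(profile$position, profile$strand)
  is21 <- profile$length == 21L
  in_range <- profile$length >= 18L & profile$length <= 26L
  best <- data.frame(window_start = starts, window_end = starts + window - 1L,
                     register = NA_integer_, P = 0, U = 0, k = 0L, score = 0)
  for (wi in seq_along(starts)) {
    ws <- starts[wi]; we <- ws + window - 1L
    inw <- profile$position >= ws & profile$position <= we & in_range
    if (!any(inw)) next
    tot <- sum(profile$count[inw])
    regs <- eff[inw & is21] %% phase
    if (length(regs) == 0) next
    for (r in unique(regs)) {
      sel <- inw & is21 & (eff %% phase) == r
      P <- sum(profile$count[sel])
      k <- length(unique(eff[sel]))
      U <- tot - P
      sc <- phase_score(P, U, k)
      if (sc > best$score[wi]) {
        best$register[wi] <- r; best$P[wi] <- P; best$U[wi] <- U
        best$k[wi] <- k; best$score[wi] <- sc
      }
    }
  }
  qual <- best[best$score > min_score, , drop = FALSE]
  if (nrow(qual) == 0) return(empty)
  # merge overlapping qualifying windows into maximal clusters
  qual <- qual[order(qual$window_start), , drop = FALSE]
  grp <- cumsum(c(1, as.integer(
    qual$window_start[-1] > cummax(qual$window_end)[-nrow(qual)] )))
  out <- lapply(split(qual, grp), function(g) {
    bi <- which.max(g$score)
    data.frame(transcript_id = tid,
               window_start = g$window_start[bi],
               window_end = g$window_end[bi],
               register = g$register[bi], P = g$P[bi], U = g$U[bi],
               k = g$k[bi], score = g$score[bi], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phase offset between a cluster and a predicted cleavage site
#'
#' `(register - cleavage_pos) mod phase`; 0 means the cluster registers
#' exactly in phase with the cleavage site, as expected when cleavage set
#' the phasing frame.
#'
#' @param cluster one row of [detect_phased_clusters()] output.
#' @param cleavage_pos predicted cleavage coordinate on the same transcript.
#' @param phase phase length (default 21).
#' @return integer offset in `0..phase-1`.
#' @export
phase_register_of_cleavage <- function(cluster, cleavage_pos, phase = 21L) {
  as.integer((cluster$register - cleavage_pos) %% phase)
}
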