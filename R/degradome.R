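# Degradome (PARE) cleavage validation.
#
# Degradome reads mark uncapped mRNA 5' ends; a strong, transcript-wide
# maximal peak at the predicted slicer coordinate (miRNA position 10)
# evidences cleavage.  Peaks are ranked T-plot style into categories 0-4
# and given a rank-based p-value under a uniform null over occupied
# positions.

#' Build a per-transcript degradome 5'-end profile
#'
#' Each read contributes its count at the 1-based coordinate of its 5' end
#' at every exact occurrence in the transcript (multi-mapping within the
#' transcript counts every match).  Unmatched reads are dropped and
#' tallied.
#'
#' @param library an [srna_library()] of degradome reads (>= 15 nt).
#' @param transcript a single-row `seq_set` (RNA) or sequence string named
#'   by `transcript_id`.
#' @param transcript_id id used when `transcript` is a bare string.
#' @return a `degradome_profile`: list with `transcript_id`, `counts`
#'   (named numeric vector, names = positions), `occupied`, `max_count`,
#'   `mean_count` (arithmetic mean over occupied positions), and
#'   `unmatched` (total count of reads without a hit).
#' @export
build_profile <- function(library, transcript, transcript_id = NULL) {
  if (inherits(transcript, "seq_set")) {
    stopifnot(nrow(transcript) == 1)
    tid <- transcript$id; tseq <- transcript$seq
  } else {
    tid <- if (is.null(transcript_id)) "transcript" else transcript_id
    tseq <- as_rna(transcript)
  }
  counts <- numeric(0)
  unmatched <- 0
  for (i in seq_len(nrow(library$reads))) {
    rs <- library$reads$seq[i]
    if (nchar(rs) < 15) next
    starts <- exact_match_starts(rs, tseq)
    if (length(starts) == 0) {
      unmatched <- unmatched + library$reads$count[i]
      next
    }
    for (st in starts) {
      key <- as.character(st)
      counts[key] <- (if (key %in% names(counts)) counts[key] else 0) +
        library$reads$count[i]
    }
  }
  counts <- counts[order(as.integer(names(counts)))]
  structure(list(
    transcript_id = tid, counts = counts,
    occupied = as.integer(names(counts)),
    max_count = if (length(counts)) max(counts) else 0,
    mean_count = if (length(counts)) mean(counts) else 0,
    unmatched = unmatched), class = "degradome_profile")
}

#' Construct a degradome profile directly from position counts
#'
#' Convenience constructor for simulation and testing: positions with
#' their 5'-end counts, no read matching involved.
#'
#' @param transcript_id transcript name.
#' @param positions integer positions.
#' @param counts positive counts, one per position.
#' @return a `degradome_profile`.
#' @export
degradome_profile <- function(transcript_id, positions, counts) {
  stopifnot(length(positions) == length(counts), all(counts >= 1))
  agg <- tapply(counts, positions, sum)
  cnt <- as.numeric(agg)
  names(cnt) <- names(agg)
  cnt <- cnt[order(as.integer(names(cnt)))]
  structure(list(
    transcript_id = transcript_id, counts = cnt,
    occupied = as.integer(names(cnt)),
    max_count = max(cnt), mean_count = mean(cnt), unmatched = 0),
    class = "degradome_profile")
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat("degradome_profile '", x$transcript_id, "': ",
      length(x$occupied), " occupied positions, max ", x$max_count,
      ", mean ", round(x$mean_count, 2), "\n", sep = "")
  invisible(x)
}

#' Classify a degradome position into T-plot category 0-4
#'
#' Decision order: a single read gives category 4; a count equal to the
#' transcript maximum gives 0 when the maximum is unique and 1 when tied;
#' above the average depth gives 2; otherwise 3.  "Average depth" is the
#' arithmetic mean over occupied positions (`mean_all = TRUE` switches to
#' the mean over all transcript positions, requiring `transcript_length`).
#'
#' @param profile a `degradome_profile`.
#' @param position an occupied transcript coordinate.
#' @param mean_all use the all-positions mean instead of the
#'   occupied-positions mean.
#' @param transcript_length needed when `mean_all = TRUE`.
#' @return integer category in 0..4.
#' @export
classify_category <- function(profile, position, mean_all = FALSE,
                              transcript_length = NULL) {
  key <- as.character(position)
  if (!key %in% names(profile$counts))
    stop("position ", position, " is not occupied; no category call")
  cnt <- profile$counts[[key]]
  if (cnt == 1) return(4L)
  mx <- profile$max_count
  if (cnt == mx) {
    ties <- sum(profile$counts == mx)
    return(if (ties == 1) 0L else 1L)
  }
  avg <- if (mean_all) {
    if (is.null(transcript_length)) stop("transcript_length required")
    sum(profile$counts) / transcript_length
  } else profile$mean_count
  if (cnt > avg) 2L else 3L
}

#' Rank-based cleavage p-value
#'
#' Under a uniform-choice null over occupied positions, the probability of
#' drawing a position at least as abundant as the queried one:
#' `p = #\{q occupied : count(q) >= count(position)\} / #occupied`.
#'
#' @param profile a `degradome_profile`.
#' @param position an occupied transcript coordinate.
#' @return p-value in (0, 1].
#' @export
cleavage_pvalue <- function(profile, position) {
  key <- as.character(position)
  if (length(profile$counts) == 0) stop("empty profile; no call")
  if (!key %in% names(profile$counts))
    stop("position ", position, " is not occupied; no call")
  cnt <- profile$counts[[key]]
  sum(profile$counts >= cnt) / length(profile$counts)
}

#' Validate predicted target sites against degradome libraries
#'
#' For every (site, library) pair with degradome signal at the predicted
#' cleavage coordinate, emits a cleavage call with category and p-value.
#' A site is validated when any library yields `p <= max_p` (union rule).
#'
#' @param sites data frame from [scan_transcriptome()] (needs `mirna_id`,
#'   `transcript_id`, `cleavage_pos`).
#' @param libraries named list of [srna_library()] degradome libraries.
#' @param transcripts `seq_set` of target transcripts (RNA).
#' @param max_p validation threshold (default 0.05).
#' @param tolerance positions around the predicted coordinate also
#'   accepted as signal (default 0 = exact).
#' @return list with `calls` (one row per site x library with signal:
#'   `mirna_id`, `transcript_id`, `position`, `library`, `count`,
#'   `category`, `p_value`), `validated` (per site: logical), and
#'   `summary` (per miRNA x library, counts in "n(category)" notation).
#' @export
validate_targets <- function(sites, libraries, transcripts, max_p = 0.05,
                             tolerance = 0L) {
  calls <- list()
  validated <- rep(FALSE, nrow(sites))
  profiles <- list()
  for (lib_name in names(libraries)) {
    lib <- libraries[[lib_name]]
    for (i in seq_len(nrow(sites))) {
      tid <- sites$transcript_id[i]
      if (!tid %in% transcripts$id) {
        warning("transcript ", tid, " absent from transcript set; skipped")
        next
      }
      pkey <- paste(lib_name, tid)
      if (is.null(profiles[[pkey]]))
        profiles[[pkey]] <- build_profile(lib, transcripts[transcripts$id == tid, ])
      prof <- profiles[[pkey]]
      if (length(prof$occupied) == 0) next
      cand <- sites$cleavage_pos[i] + seq.int(-tolerance, tolerance)
      cand <- cand[cand %in% prof$occupied]
      if (length(cand) == 0) next
      # with a tolerance window, use the strongest position in it
      pos <- cand[which.max(prof$counts[as.character(cand)])]
      cat_ <- classify_category(prof, pos)
      pv <- cleavage_pvalue(prof, pos)
      calls[[length(calls) + 1L]] <- data.frame(
        mirna_id = sites$mirna_id[i], transcript_id = tid,
        position = pos, library = lib_name,
        count = prof$counts[[as.character(pos)]],
        category = cat_, p_value = pv, stringsAsFactors = FALSE)
      if (pv <= max_p) validated[i] <- TRUE
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               position = numeric(0), library = character(0),
               count = numeric(0), category = integer(0),
               p_value = numeric(0))
  list(calls = calls, validated = validated,
       summary = summarize_cleavage_calls(calls, max_p))
}

# Per miRNA x library tallies in the "n(category)" notation of degradome
# reports, restricted to calls passing the p threshold.
summarize_cleavage_calls <- function(calls, max_p = 0.05) {
  ok <- calls[calls$p_value <= max_p, , drop = FALSE]
  if (nrow(ok) == 0)
    return(data.frame(mirna_id = character(0), library = character(0),
                      n_validated = integer(0), categories = character(0)))
  out <- list()
  for (m in unique(ok$mirna_id)) for (l in unique(ok$library)) {
    g <- ok[ok$mirna_id == m & ok$library == l, , drop = FALSE]
    if (nrow(g) == 0) next
    tab <- table(g$category)
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = m, library = l, n_validated = nrow(g),
      categories = paste(sprintf("%d(%s)", as.integer(tab), names(tab)),
                         collapse = "; "),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export T-plot data for one transcript profile
#'
#' @param profile a `degradome_profile`.
#' @param predicted numeric vector of predicted cleavage coordinates.
#' @return data frame `position`, `count`, `is_predicted`.
#' @export
tplot_data <- function(profile, predicted = numeric(0)) {
  data.frame(position = profile$occupied,
             count = as.numeric(profile$counts),
             is_predicted = profile$occupied %in% predicted)
}
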