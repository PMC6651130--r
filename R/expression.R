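# TPM normalization of small RNA abundances and stress-response calling.

#' Exact-match abundance of a mature miRNA in a library
#'
#' Counts only reads exactly equal to the mature sequence (T/U
#' equivalent); isomiRs and length variants are not counted, matching the
#' perfect-match mapping philosophy used throughout the pipeline.
#'
#' @param library an [srna_library()].
#' @param mirna mature sequence (string) or single-row `seq_set`.
#' @return numeric raw count (0 when absent).
#' @export
mirna_abundance <- function(library, mirna) {
  if (inherits(mirna, "seq_set")) mirna <- mirna$seq[1]
  m <- as_rna(mirna)
  i <- match(m, library$reads$seq)
  if (is.na(i)) 0 else library$reads$count[i]
}

#' TPM-normalize per-library feature counts
#'
#' `tpm = raw_count * 1e6 / total_count` with the library's total read
#' count as denominator.
#'
#' @param counts named numeric vector of raw counts for one library.
#' @param total_count library total read count (> 0).
#' @param library name recorded in the output.
#' @return data frame `feature_id`, `library`, `raw_count`, `tpm`.
#' @export
tpm_normalize <- function(counts, total_count, library = "library") {
  if (total_count <= 0) stop("zero-read library: TPM undefined")
  data.frame(feature_id = names(counts), library = library,
             raw_count = as.numeric(counts),
             tpm = as.numeric(counts) * 1e6 / total_count,
             stringsAsFactors = FALSE)
}

#' Build a miRNA x library TPM matrix
#'
#' @param mirnas `seq_set` of mature miRNAs.
#' @param libraries named list of [srna_library()] objects.
#' @return list with `raw` and `tpm` matrices (miRNAs x libraries).
#' @export
expression_matrix <- function(mirnas, libraries) {
  raw <- sapply(libraries, function(lib)
    vapply(seq_len(nrow(mirnas)), function(i)
      mirna_abundance(lib, mirnas$seq[i]), numeric(1)))
  raw <- matrix(raw, nrow = nrow(mirnas),
                dimnames = list(mirnas$id, names(libraries)))
  totals <- vapply(libraries, `[[`, numeric(1), "total_count")
  tpm <- sweep(raw, 2, totals, "/") * 1e6
  list(raw = raw, tpm = tpm)
}

#' Call an expression response between mock and stress
#'
#' `log2fc = log2((tpm_stress + pseudocount) / (tpm_mock + pseudocount))`;
#' strictly greater than 1 is `up`, strictly less than -1 is `down`,
#' otherwise `nc`.
#'
#' @param tpm_mock,tpm_stress TPM values (>= 0).
#' @param pseudocount added to both arms (default 1 TPM).
#' @return list `log2fc`, `call`.
#' @export
call_response <- function(tpm_mock, tpm_stress, pseudocount = 1) {
  if (pseudocount < 0) stop("negative pseudocount")
  if (any(c(tpm_mock, tpm_stress) < 0)) stop("negative TPM")
  lfc <- log2((tpm_stress + pseudocount) / (tpm_mock + pseudocount))
  call <- if (lfc > 1) "up" else if (lfc < -1) "down" else "nc"
  list(log2fc = lfc, call = call)
}

#' Flag a target gene as upregulated under pathogen stress
#'
#' Fold change is computed on pooled replicates
#' (sum of stress TPMs over sum of mock TPMs plus a pseudocount); the gene
#' is flagged when the ratio exceeds `min_fc` and the stress-arm mean TPM
#' exceeds `min_tpm`.
#'
#' @param tpm_mock,tpm_stress numeric vectors of replicate TPMs (>= 1
#'   replicate each).
#' @param min_tpm stress-mean TPM floor (default 5).
#' @param min_fc fold-change threshold (default 2; 1.5 is the other
#'   convention in circulation).
#' @param pseudocount stabilizer for all-zero mock arms (default 1).
#' @return list `fold_change`, `stress_mean`, `upregulated`.
#' @export
call_target_upregulation <- function(tpm_mock, tpm_stress, min_tpm = 5,
                                     min_fc = 2, pseudocount = 1) {
  stopifnot(length(tpm_mock) >= 1, length(tpm_stress) >= 1)
  fc <- sum(tpm_stress) / (sum(tpm_mock) + pseudocount)
  sm <- mean(tpm_stress)
  list(fold_change = fc, stress_mean = sm,
       upregulated = fc > min_fc && sm > min_tpm)
}
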