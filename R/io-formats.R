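#' @useDynLib resistomir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rpois runif rbinom
#' @importFrom utils read.table write.table head tail
NULL

# ---- sequence alphabets -----------------------------------------------------

.ALPHABETS <- list(
  rna     = c("A", "C", "G", "U", "N"),
  dna     = c("A", "C", "G", "T", "N"),
  protein = c(LETTERS, "*")
)

#' Convert a nucleotide string between DNA and RNA alphabets
#'
#' Internal storage convention: mature miRNAs and transcripts are RNA (U),
#' genomes are DNA (T).  Conversion happens at module boundaries.
#'
#' @param x character vector of sequences.
#' @return character vector in the requested alphabet, upper case.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse-complement a nucleotide sequence
#'
#' Works on either alphabet; the output stays in the input alphabet.
#'
#' @param x character vector of DNA or RNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rna <- grepl("U", toupper(s), fixed = TRUE)
    comp <- if (rna) chartr("ACGUN", "UGCAN", toupper(s))
            else     chartr("ACGTN", "TGCAN", toupper(s))
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all start positions of exact (possibly overlapping) occurrences of a
# plain pattern in a single subject string
exact_match_starts <- function(pattern, subject) {
  out <- integer(0)
  from <- 1L
  n <- nchar(subject); m <- nchar(pattern)
  while (from + m - 1L <= n) {
    hit <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (hit == -1L) break
    st <- from + as.integer(hit) - 1L
    out <- c(out, st)
    from <- st + 1L
  }
  out
}

# ---- seq_set: the internal sequence container -------------------------------

#' Construct a sequence set
#'
#' A `seq_set` is a data frame with columns `id` and `seq` plus an
#' `alphabet` attribute; it is the single internal representation for
#' genomes, transcripts, proteins and mature miRNAs.
#'
#' @param id character vector of record identifiers (no whitespace).
#' @param seq character vector of sequences.
#' @param alphabet one of `"rna"`, `"dna"`, `"protein"`.
#' @return a `seq_set` data frame.
#' @export
seq_set <- function(id, seq, alphabet = c("rna", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  seq <- toupper(seq)
  if (alphabet == "rna") seq <- as_rna(seq)
  if (alphabet == "dna") seq <- as_dna(seq)
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("sequence ids must be non-empty and contain no whitespace")
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for id(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  ok <- .ALPHABETS[[alphabet]]
  bad <- vapply(seq, function(s)
    !all(strsplit(s, "", fixed = TRUE)[[1]] %in% ok), logical(1))
  if (any(bad))
    stop("illegal ", alphabet, " character in record(s): ",
         paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set (", attr(x, "alphabet"), "): ", nrow(x), " record(s)\n", sep = "")
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    s <- x$seq[i]
    cat("  ", x$id[i], "  ",
        if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s,
        " (", nchar(s), " nt/aa)\n", sep = "")
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Fetch one sequence from a seq_set by id
#' @param x a `seq_set`.
#' @param id record identifier.
#' @return the sequence string.
#' @export
get_seq <- function(x, id) {
  i <- match(id, x$id)
  if (is.na(i)) stop("no record with id '", id, "'")
  x$seq[i]
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file into a seq_set
#'
#' Case is folded to upper; `T` is rewritten to `U` for RNA (and `U` to `T`
#' for DNA).  Malformed records are reported with their id and the line
#' number where the problem was seen.
#'
#' The parser is deliberately line-based so that validation errors
#' (duplicate ids, illegal characters, sequence-before-header) can name
#' the offending line; downstream heavy lifting on the parsed sequences
#' is done with Biostrings.
#'
#' @param path FASTA file path.
#' @param alphabet one of `"rna"`, `"dna"`, `"protein"`.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L || !any(grepl("^>", lines)))
    stop("empty or headerless FASTA: ", path)
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur <- character(0); id_line <- integer(0)
  flush <- function() {
    if (!is.null(cur_id)) {
      ids <<- c(ids, cur_id)
      seqs <<- c(seqs, paste(cur, collapse = ""))
    }
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, ">")) {
      flush()
      cur_id <- sub("\\s.*$", "", sub("^>", "", line))
      if (!nzchar(cur_id)) stop("empty FASTA header at line ", ln)
      if (cur_id %in% ids)
        stop("duplicate FASTA id '", cur_id, "' at line ", ln)
      id_line <- c(id_line, ln)
      cur <- character(0)
    } else {
      if (is.null(cur_id))
        stop("sequence data before first header at line ", ln)
      tok <- gsub("\\s", "", line)
      ok <- .ALPHABETS[[alphabet]]
      norm <- toupper(tok)
      if (alphabet == "rna") norm <- as_rna(norm)
      if (alphabet == "dna") norm <- as_dna(norm)
      chars <- strsplit(norm, "", fixed = TRUE)[[1]]
      if (!all(chars %in% ok))
        stop("illegal ", alphabet, " character in record '", cur_id,
             "' at line ", ln, ": ",
             paste(unique(chars[!chars %in% ok]), collapse = ""))
      cur <- c(cur, norm)
    }
  }
  flush()
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1]
    stop("record '", ids[i], "' (line ", id_line[i], ") has no sequence")
  }
  seq_set(ids, seqs, alphabet)
}

#' Write a seq_set as FASTA
#' @param x a `seq_set`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- small RNA libraries ----------------------------------------------------

#' Construct a small RNA library
#'
#' Reads are unique sequences with positive integer counts; duplicate
#' sequences are merged by summing counts.  Read lengths must lie in
#' 15-34 nt, the usual trimmed small-RNA range.
#'
#' @param name library name (token).
#' @param seq character vector of read sequences (RNA alphabet enforced).
#' @param count integer vector of abundances.
#' @return an `srna_library` list with `name`, `reads` (data frame of
#'   `seq`, `count`) and `total_count`.
#' @export
srna_library <- function(name, seq, count) {
  stopifnot(length(seq) == length(count))
  if (any(count != round(count)) || any(count <= 0))
    stop("read counts must be positive integers")
  seq <- as_rna(seq)
  lens <- nchar(seq)
  if (any(lens < 15 | lens > 34))
    stop("read length outside [15, 34] nt: ",
         paste(head(seq[lens < 15 | lens > 34], 3), collapse = ", "))
  agg <- tapply(as.numeric(count), seq, sum)
  reads <- data.frame(seq = names(agg), count = as.numeric(agg),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$seq), , drop = FALSE]
  rownames(reads) <- NULL
  out <- list(name = name, reads = reads, total_count = sum(reads$count))
  class(out) <- "srna_library"
  out
}

#' @export
print.srna_library <- function(x, ...) {
  cat("srna_library '", x$name, "': ", nrow(x$reads),
      " unique reads, total count ", format(x$total_count), "\n", sep = "")
  invisible(x)
}

#' Read a collapsed small RNA library
#'
#' Two dialects: `collapsed_fasta` with abundance encoded as a trailing
#' `_x<INT>` in the header token (e.g. `>r1_x5`), and `tsv` with two
#' columns `sequence<TAB>count` and no header.
#'
#' @param path input file.
#' @param dialect `"collapsed_fasta"` or `"tsv"`.
#' @param name library name; defaults to the file base name.
#' @return an [srna_library()].
#' @export
read_small_rna_library <- function(path,
                                   dialect = c("collapsed_fasta", "tsv"),
                                   name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.(fa|fasta|tsv|txt)$", "", basename(path))
  if (dialect == "collapsed_fasta") {
    fa <- read_fasta(path, alphabet = "rna")
    m <- regmatches(fa$id, regexec("_x([0-9]+)$", fa$id))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad))
      stop("collapsed-FASTA header without trailing _x<INT> count: ",
           paste(head(fa$id[bad], 3), collapse = ", "))
    counts <- as.integer(vapply(m, `[`, character(1), 2L))
    if (any(counts <= 0)) stop("non-positive read count in header: ",
                               paste(fa$id[counts <= 0], collapse = ", "))
    srna_library(name, fa$seq, counts)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) != 2L))
      stop("TSV line without exactly two fields at line ",
           which(vapply(parts, length, integer(1)) != 2L)[1])
    seqs <- vapply(parts, `[`, character(1), 1L)
    cnt_s <- vapply(parts, `[`, character(1), 2L)
    if (any(!grepl("^[0-9]+$", cnt_s)))
      stop("non-integer count at line ", which(!grepl("^[0-9]+$", cnt_s))[1],
           ": '", cnt_s[!grepl("^[0-9]+$", cnt_s)][1], "'")
    counts <- as.integer(cnt_s)
    if (any(counts <= 0))
      stop("zero/negative count at line ", which(counts <= 0)[1])
    srna_library(name, seqs, counts)
  }
}

#' Write a small RNA library
#' @param lib an `srna_library`.
#' @param path output path.
#' @param dialect `"collapsed_fasta"` or `"tsv"`.
#' @export
write_small_rna_library <- function(lib, path,
                                    dialect = c("collapsed_fasta", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "collapsed_fasta") {
    ids <- sprintf("%s_r%d_x%d", lib$name, seq_len(nrow(lib$reads)),
                   as.integer(lib$reads$count))
    write_fasta(seq_set(ids, lib$reads$seq, "rna"), path)
  } else {
    writeLines(paste(lib$reads$seq, as.integer(lib$reads$count), sep = "\t"),
               path)
  }
  invisible(path)
}

# ---- annotated species trees ------------------------------------------------

#' Read a Newick tree with optional node-age annotations
#'
#' Internal nodes may carry a comment of the form `[&age=lo-hi]` giving a
#' divergence-time interval in million years (mya).  Topology parsing is
#' delegated to \pkg{ape}; the age comments are lifted into node labels
#' before parsing and decoded afterwards.
#'
#' @param path Newick file.
#' @return an `annotated_tree`: list with `phylo` (an [ape::read.tree()]
#'   tree) and `ages` (data frame `node`, `min_mya`, `max_mya`).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  annotated_tree_from_string(txt)
}

#' Build an annotated tree from a Newick string
#' @param txt Newick string, optionally with `[&age=lo-hi]` node comments.
#' @return an `annotated_tree`.
#' @export
annotated_tree_from_string <- function(txt) {
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  # basic balance check before handing to ape
  op <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  cl <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (op != cl) stop("unbalanced parentheses in Newick input")
  txt2 <- gsub("\\[&age=([0-9.]+)-([0-9.]+)\\]", "AGE_\\1_\\2", txt)
  phy <- ape::read.tree(text = txt2)
  if (is.null(phy)) stop("could not parse Newick input")
  ages <- data.frame(node = integer(0), min_mya = numeric(0),
                     max_mya = numeric(0))
  if (!is.null(phy$node.label)) {
    m <- regmatches(phy$node.label,
                    regexec("^AGE_([0-9.]+)_([0-9.]+)$", phy$node.label))
    hit <- vapply(m, length, integer(1)) == 3L
    if (any(hit)) {
      nodes <- ape::Ntip(phy) + which(hit)
      lo <- as.numeric(vapply(m[hit], `[`, character(1), 2L))
      hi <- as.numeric(vapply(m[hit], `[`, character(1), 3L))
      if (any(lo > hi)) stop("age interval with lo > hi in Newick input")
      ages <- data.frame(node = nodes, min_mya = lo, max_mya = hi)
      phy$node.label[hit] <- ""
    }
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf names in tree")
  out <- list(phylo = phy, ages = ages)
  class(out) <- "annotated_tree"
  validate_annotated_tree(out)
  out
}

validate_annotated_tree <- function(tr) {
  if (nrow(tr$ages) == 0) return(invisible(tr))
  if (any(tr$ages$min_mya < 0)) stop("negative node age")
  # child upper bound must not exceed parent's upper bound
  phy <- tr$phylo
  for (i in seq_len(nrow(tr$ages))) {
    node <- tr$ages$node[i]
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(parent) == 1) {
      j <- match(parent, tr$ages$node)
      if (!is.na(j) && tr$ages$max_mya[i] > tr$ages$max_mya[j])
        stop("child node age interval exceeds its parent's")
    }
  }
  invisible(tr)
}

#' Write an annotated tree as Newick
#' @param tr an `annotated_tree`.
#' @param path output path.
#' @export
write_newick <- function(tr, path) {
  phy <- tr$phylo
  ntip <- ape::Ntip(phy)
  if (nrow(tr$ages) > 0) {
    lab <- rep("", phy$Nnode)
    lab[tr$ages$node - ntip] <-
      sprintf("AGE_%g_%g", tr$ages$min_mya, tr$ages$max_mya)
    phy$node.label <- lab
  } else phy$node.label <- NULL
  txt <- ape::write.tree(phy)
  txt <- gsub("AGE_([0-9.]+)_([0-9.]+)", "[&age=\\1-\\2]", txt)
  writeLines(txt, path)
  invisible(path)
}

# ---- transcript annotation --------------------------------------------------

#' Construct a transcript CDS annotation table
#'
#' @param transcript_id character vector of transcript ids.
#' @param cds_start,cds_end 1-based inclusive transcript coordinates of the
#'   coding region.
#' @param transcript_length optional lengths for bound checking.
#' @return data frame with class `transcript_annotation`.
#' @export
transcript_annotation <- function(transcript_id, cds_start, cds_end,
                                  transcript_length = NULL) {
  if (any(cds_start < 1) || any(cds_start >= cds_end))
    stop("require 1 <= cds_start < cds_end")
  if (!is.null(transcript_length) && any(cds_end > transcript_length))
    stop("cds_end exceeds transcript length")
  out <- data.frame(transcript_id = transcript_id,
                    cds_start = as.integer(cds_start),
                    cds_end = as.integer(cds_end),
                    stringsAsFactors = FALSE)
  class(out) <- c("transcript_annotation", "data.frame")
  out
}

#' Read a transcript annotation TSV (transcript_id, cds_start, cds_end)
#' @param path TSV with header.
#' @return a [transcript_annotation()].
#' @export
read_transcript_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  transcript_annotation(df$transcript_id, df$cds_start, df$cds_end)
}

# ---- tabular / GFF3 output --------------------------------------------------

#' Write a report table as TSV
#'
#' Header row, UTF-8, tab separated, no quoting.
#'
#' @param rows a data frame.
#' @param path output path.
#' @export
write_report_tsv <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a report TSV written by [write_report_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_report_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "")
}

#' Write genome loci as GFF3
#'
#' Coordinates are 1-based inclusive on the forward strand of the named
#' sequence, as everywhere in this package.
#'
#' @param loci data frame with columns `mirna_id`, `chrom`, `strand`,
#'   `start`, `end` (as returned by [find_perfect_loci()]).
#' @param path output path.
#' @export
write_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci) > 0) {
    writeLines(sprintf("%s\tresistomir\tmiRNA_locus\t%d\t%d\t.\t%s\t.\tID=%s.%d;mirna=%s",
                       loci$chrom, loci$start, loci$end, loci$strand,
                       loci$mirna_id, seq_len(nrow(loci)), loci$mirna_id),
               con)
  }
  invisible(path)
}

#' Read a miRNA-locus GFF3 written by [write_gff3()]
#' @param path GFF3 path.
#' @return data frame with `mirna_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gff3_loci <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(mirna_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, integer(1)) != 9L)) stop("malformed GFF3 line")
  data.frame(
    mirna_id = sub(".*mirna=([^;]+).*", "\\1", vapply(f, `[`, character(1), 9L)),
    chrom = vapply(f, `[`, character(1), 1L),
    strand = vapply(f, `[`, character(1), 7L),
    start = as.integer(vapply(f, `[`, character(1), 4L)),
    end = as.integer(vapply(f, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
}
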