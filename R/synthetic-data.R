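# Seeded generator of a complete toy study: genomes with planted miRNA
# hairpins, NB-LRR-like target transcripts and proteins, degradome and
# small RNA libraries, expression contrasts, and a species presence
# pattern -- together with a ground-truth manifest so that every pipeline
# stage can be checked against what was planted.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n, bases) paste(sample(bases, n, replace = TRUE),
                                     collapse = "")

# sample one element of x, safe for length-1 vectors
pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Default simulation configuration
#'
#' The defaults describe the study conditions every recovery test runs
#' under: six grass species on a dated tree, five mature miRNAs (21-22
#' nt), four NB-LRR-like targets each with planted duplex scores below 4,
#' degradome peaks of Poisson(20) signal over Poisson(2) noise at 30
#' positions, eight-cycle phased clusters with 90% phased abundance and
#' geometric 3' decay (ratio 0.8), and a mock/stress contrast with
#' planted log2 fold changes.
#'
#' @param seed RNG seed; the full output is a pure function of the config.
#' @param ... overrides for any default field.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    species = c("maize", "sorghum", "rice", "Brachypodium", "barley",
                "wheat"),
    tree_newick = paste0("(((maize,sorghum)[&age=10-15],rice)[&age=40-54],",
                         "(Brachypodium,(barley,wheat)[&age=10-15])",
                         "[&age=32-39])[&age=45-60];"),
    genome_length = 20000L,
    n_mirnas = 5L,
    mirna_lengths = c(21L, 22L),
    n_targets_per_mirna = 4L,
    transcript_length = 600L,
    cds = c(101L, 520L),
    score_choices = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
    stem_extension = 19L,       # stem = mature + extension base pairs
    loop_length = 8L,
    max_copies = 3L,
    loss_prob = 0.2,            # per-leaf loss under the planted origin
    lambda_signal = 20,
    lambda_noise = 2,
    n_noise_positions = 30L,
    phased_cycles = 8L,
    phased_fraction = 0.9,
    phased_decay = 0.8,
    phased_base_count = 10,
    mirna_base_count = 100,
    log2fc_choices = c(-2, 0, 2),
    n_background_reads = 40L,
    n_replicates = 3L,
    protein_length = 360L,
    nblrr_fraction = 0.9)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$lambda_signal > cfg$lambda_noise,
            cfg$phased_fraction > 0, cfg$phased_fraction <= 1,
            all(cfg$score_choices >= 0), all(cfg$score_choices < 4))
  class(cfg) <- "simulation_config"
  cfg
}

# ---- duplex-score-controlled site mutation ----------------------------------

# Plant a target site with a chosen optimal duplex score by inverting the
# scoring rule: start from the perfect reverse complement and add core
# mismatches (2.0), non-core mismatches (1.0), core wobbles (1.0) and
# non-core wobbles (0.5) until the score is reached.  Site position j
# faces miRNA position L - j + 1 in a bulge-free duplex.
mutate_site_to_score <- function(mirna, target_score) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  site <- strsplit(revcomp(mirna), "", fixed = TRUE)[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  core <- function(i) i >= 2 && i <= 13
  # avoid miRNA positions 9-11 so the cleavage-flank pairing stays intact
  usable <- setdiff(seq_len(L), 9:11)
  half <- round(target_score * 2)
  used <- integer(0)
  add_mm <- function(i) {
    # a base that neither Watson-Crick nor G:U pairs with m[i]
    bad <- c(comp[[m[i]]],
             if (m[i] == "G") "U" else if (m[i] == "U") "G" else NULL,
             site[L - i + 1])
    site[L - i + 1] <<- pick1(setdiff(RNA_BASES, bad))
  }
  add_gu <- function(i) site[L - i + 1] <<- if (m[i] == "G") "U" else "G"
  while (half > 0) {
    open_core <- setdiff(Filter(core, usable), used)
    open_noncore <- setdiff(Filter(Negate(core), usable), used)
    gu_noncore <- open_noncore[m[open_noncore] %in% c("G", "U")]
    gu_core <- open_core[m[open_core] %in% c("G", "U")]
    if (half >= 4 && length(open_core)) {
      i <- pick1(open_core); add_mm(i); half <- half - 4
    } else if (half >= 2 && length(open_noncore)) {
      i <- pick1(open_noncore); add_mm(i); half <- half - 2
    } else if (half >= 2 && length(gu_core)) {
      i <- pick1(gu_core); add_gu(i); half <- half - 2
    } else if (half >= 1 && length(gu_noncore)) {
      i <- pick1(gu_noncore); add_gu(i); half <- half - 1
    } else {
      stop("cannot realize duplex score ", target_score, " for this miRNA")
    }
    used <- c(used, i)
  }
  paste(site, collapse = "")
}

# matures need wobble-capable non-core positions for half-point scores
draw_mature <- function(len) {
  repeat {
    m <- rand_seq(len, RNA_BASES)
    chars <- strsplit(m, "", fixed = TRUE)[[1]]
    noncore <- chars[setdiff(seq_len(len), c(2:13, 9:11))]
    if (sum(noncore %in% c("G", "U")) >= 2 && !grepl("(.)\\1{4}", m))
      return(m)
  }
}

# ---- protein construction ---------------------------------------------------

CC_BLOCK <- paste(rep("LAELEQK", 5), collapse = "")    # heptad a/d all L
P_LOOP <- "GAPSVGKT"
KINASE2 <- "LLVDD"
GLPL <- "GLPL"
LRR_UNIT <- "LRVLDLSGN"

# spacer alphabet excludes the hydrophobic set and K so that no spacer can
# complete a motif or a coiled-coil window by chance: planted domain labels
# stay unambiguous ground truth
SPACER_AA <- setdiff(AA20, c("A", "L", "I", "V", "M", "F", "K"))

build_protein <- function(class, total_len) {
  parts <- list(rand_seq(25, SPACER_AA))
  if (class == "CNL") parts <- c(parts, CC_BLOCK, rand_seq(12, SPACER_AA))
  if (class %in% c("N", "NL", "CNL"))
    parts <- c(parts, P_LOOP, rand_seq(18, SPACER_AA), KINASE2,
               rand_seq(15, SPACER_AA), GLPL, rand_seq(10, SPACER_AA))
  if (class %in% c("NL", "CNL"))
    parts <- c(parts, paste(rep(paste0(LRR_UNIT, "QT"), 4), collapse = ""))
  seq <- paste(unlist(parts), collapse = "")
  pad <- total_len - nchar(seq)
  if (pad < 0) stop("protein_length too small for planted domains")
  paste0(seq, rand_seq(pad, SPACER_AA))
}

# ---- the generator ----------------------------------------------------------

#' Simulate a complete miRNA/NB-LRR study with known ground truth
#'
#' Emits, under `out_dir`: per-species genome FASTA with mature miRNAs
#' embedded in constructed inverted-repeat hairpins following the planted
#' presence pattern; target transcript FASTA with CDS annotations and
#' sites whose duplex scores follow the configured distribution; protein
#' FASTA with planted NB/LRR/CC motifs; degradome libraries with Poisson
#' signal peaks at the predicted cleavage coordinates over Poisson noise;
#' small RNA libraries with mature reads at the planted fold changes plus
#' 21-nt phased reads downstream of each cleavage site (geometric decay,
#' antisense +2 offset) and random background; a dated species tree; an
#' expression contrast table; and `manifest.json` recording everything
#' planted.  The same config (including seed) gives byte-identical output.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return invisibly, a list with `dir`, `manifest`, and the in-memory
#'   objects (`mirnas`, `transcripts`, `annotation`, `proteins`,
#'   `genomes`, `srna_libs`, `deg_libs`, `tree`).
#' @export
simulate_study <- function(config = simulation_config(), out_dir) {
  cfg <- config
  if (cfg$transcript_length < max(cfg$cds) + 60)
    stop("infeasible config: transcript too short for CDS and sites")
  set.seed(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("genomes", "srna", "degradome"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  tree <- annotated_tree_from_string(cfg$tree_newick)
  stopifnot(setequal(tree$phylo$tip.label, cfg$species))

  # -- matures ---------------------------------------------------------------
  mir_len <- sample(cfg$mirna_lengths, cfg$n_mirnas, replace = TRUE)
  mir_seq <- vapply(mir_len, draw_mature, character(1))
  mir_id <- sprintf("syn-miR%02d", seq_len(cfg$n_mirnas))
  mirnas <- seq_set(mir_id, mir_seq, "rna")

  # -- presence pattern: one origin clade per miRNA, with sporadic losses ----
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  presence <- matrix(0L, cfg$n_mirnas, length(cfg$species),
                     dimnames = list(mir_id, cfg$species))
  for (i in seq_len(cfg$n_mirnas)) {
    origin <- sample(ntip + seq_len(phy$Nnode), 1)   # internal node
    leaves <- clade_tips_labels(phy, origin)
    keep <- leaves[runif(length(leaves)) > cfg$loss_prob]
    if (length(keep) == 0) keep <- sample(leaves, 1)
    presence[i, keep] <- sample(seq_len(cfg$max_copies), length(keep),
                                replace = TRUE)
  }

  # -- genomes with planted hairpins -----------------------------------------
  genomes <- list()
  loci_rows <- list()
  for (s in cfg$species) {
    g <- rand_seq(cfg$genome_length, DNA_BASES)
    slot <- 1L
    for (i in seq_len(cfg$n_mirnas)) {
      ncopy <- presence[i, s]
      if (ncopy == 0) next
      for (cp in seq_len(ncopy)) {
        arm5 <- paste0(mir_seq[i],
                       rand_seq(cfg$stem_extension, RNA_BASES))
        loop <- rand_seq(cfg$loop_length, RNA_BASES)
        # the 3' arm is a near-complement: a few substitutions opposite
        # the mature (as in real miRNA* arms) so that the mature itself
        # is the only perfect-match locus the hairpin contributes
        arm3 <- strsplit(revcomp(arm5), "", fixed = TRUE)[[1]]
        star_off <- length(arm3) - mir_len[i]
        for (mpos in c(4L, 11L, 18L)) {
          at3 <- star_off + mir_len[i] - mpos + 1L
          arm3[at3] <- pick1(setdiff(RNA_BASES, arm3[at3]))
        }
        pre <- paste0(arm5, loop, paste(arm3, collapse = ""))
        pre_dna <- as_dna(pre)
        plen <- nchar(pre_dna)
        at <- 500L + (slot - 1L) * 1200L
        slot <- slot + 1L
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") pre_dna else revcomp(pre_dna)
        substr(g, at, at + plen - 1L) <- ins
        mstart <- if (strand == "+") at else at + plen - mir_len[i]
        loci_rows[[length(loci_rows) + 1L]] <- data.frame(
          mirna_id = mir_id[i], species = s, chrom = paste0(s, "_chr1"),
          strand = strand, start = mstart,
          end = mstart + mir_len[i] - 1L, stringsAsFactors = FALSE)
      }
    }
    genomes[[s]] <- seq_set(paste0(s, "_chr1"), g, "dna")
  }
  planted_loci <- do.call(rbind, loci_rows)

  # -- target transcripts, sites, proteins -----------------------------------
  tx_rows <- list(); site_rows <- list(); prot_rows <- list()
  for (i in seq_len(cfg$n_mirnas)) {
    for (t in seq_len(cfg$n_targets_per_mirna)) {
      tid <- sprintf("%s_target%02d", mir_id[i], t)
      tseq <- rand_seq(cfg$transcript_length, RNA_BASES)
      v <- sample(cfg$score_choices, 1)
      site <- mutate_site_to_score(mir_seq[i], v)
      slen <- nchar(site)
      smin <- cfg$cds[1] + 60L
      smax <- cfg$cds[2] - slen - 60L
      sstart <- sample(seq.int(smin, smax), 1)
      send <- sstart + slen - 1L
      substr(tseq, sstart, send) <- site
      cleave <- send - 9L
      klass <- if (runif(1) < cfg$nblrr_fraction)
        sample(c("CNL", "NL", "N"), 1, prob = c(0.5, 0.3, 0.2)) else "none"
      tx_rows[[tid]] <- data.frame(
        transcript_id = tid, seq = tseq, stringsAsFactors = FALSE)
      site_rows[[tid]] <- data.frame(
        mirna_id = mir_id[i], transcript_id = tid, site_start = sstart,
        site_end = send, score = v, cleavage_pos = cleave,
        domain_class = klass, stringsAsFactors = FALSE)
      prot_rows[[tid]] <- data.frame(
        protein_id = paste0(tid, "_prot"),
        seq = build_protein(klass, cfg$protein_length),
        class = klass, stringsAsFactors = FALSE)
    }
  }
  tx <- do.call(rbind, tx_rows)
  planted_sites <- do.call(rbind, site_rows)
  prot <- do.call(rbind, prot_rows)
  rownames(tx) <- rownames(planted_sites) <- rownames(prot) <- NULL
  transcripts <- seq_set(tx$transcript_id, tx$seq, "rna")
  proteins <- seq_set(prot$protein_id, prot$seq, "protein")
  annotation <- transcript_annotation(tx$transcript_id,
                                      rep(cfg$cds[1], nrow(tx)),
                                      rep(cfg$cds[2], nrow(tx)),
                                      rep(cfg$transcript_length, nrow(tx)))

  # -- degradome libraries ---------------------------------------------------
  deg_libs <- list()
  deg_truth <- list()
  for (lib_name in c("deg_control", "deg_stress")) {
    seqs <- character(0); cnts <- numeric(0)
    for (r in seq_len(nrow(planted_sites))) {
      tseq <- get_seq(transcripts, planted_sites$transcript_id[r])
      cl <- planted_sites$cleavage_pos[r]
      sig <- max(1L, rpois(1, cfg$lambda_signal))
      seqs <- c(seqs, substr(tseq, cl, cl + 19L)); cnts <- c(cnts, sig)
      cand <- setdiff(seq_len(nchar(tseq) - 19L), cl)
      npos <- sample(cand, cfg$n_noise_positions)
      ncnt <- rpois(cfg$n_noise_positions, cfg$lambda_noise)
      keep <- ncnt > 0
      seqs <- c(seqs, substring(tseq, npos[keep], npos[keep] + 19L))
      cnts <- c(cnts, ncnt[keep])
      deg_truth[[length(deg_truth) + 1L]] <- data.frame(
        library = lib_name, transcript_id = planted_sites$transcript_id[r],
        peak_pos = cl, signal_count = sig, stringsAsFactors = FALSE)
    }
    deg_libs[[lib_name]] <- srna_library(lib_name, seqs, cnts)
  }

  # -- small RNA libraries with planted expression and phasing ---------------
  lfc <- sample(cfg$log2fc_choices, cfg$n_mirnas, replace = TRUE)
  names(lfc) <- mir_id
  lib_names <- c(paste0("mock_r", seq_len(cfg$n_replicates)),
                 paste0("stress_r", seq_len(cfg$n_replicates)))
  srna_libs <- list()
  phase_truth <- list()
  for (lib_name in lib_names) {
    stressed <- startsWith(lib_name, "stress")
    seqs <- character(0); cnts <- numeric(0)
    for (i in seq_len(cfg$n_mirnas)) {
      cnt <- round(cfg$mirna_base_count * if (stressed) 2^lfc[i] else 1)
      if (cnt >= 1) { seqs <- c(seqs, mir_seq[i]); cnts <- c(cnts, cnt) }
    }
    for (r in seq_len(nrow(planted_sites))) {
      tseq <- get_seq(transcripts, planted_sites$transcript_id[r])
      cl <- planted_sites$cleavage_pos[r]
      ptot <- 0
      for (cyc in 0:(cfg$phased_cycles - 1L)) {
        p <- cl + 21L * cyc
        if (p + 20L > nchar(tseq)) break
        cc <- max(1, round(cfg$phased_base_count * cfg$phased_decay^cyc))
        seqs <- c(seqs, substr(tseq, p, p + 20L)); cnts <- c(cnts, cc)
        ptot <- ptot + cc
        # antisense partner: 5' end two nt 3' of the register
        as_cc <- max(1, round(cc / 2))
        if (p - 1L >= 1) {
          seqs <- c(seqs, revcomp(substr(tseq, p - 1L, p + 19L)))
          cnts <- c(cnts, as_cc)
          ptot <- ptot + as_cc
        }
      }
      u_target <- ptot * (1 - cfg$phased_fraction) / cfg$phased_fraction
      nu <- max(1L, round(u_target / 4))
      upos <- sample(seq.int(cl, min(cl + 21L * cfg$phased_cycles - 22L,
                                     nchar(tseq) - 23L)), nu,
                     replace = TRUE)
      for (q in upos) {
        seqs <- c(seqs, substr(tseq, q + 3L, q + 3L + 19L))  # 20-nt, off-register
        cnts <- c(cnts, max(1, round(u_target / nu)))
      }
      if (lib_name == lib_names[1])
        phase_truth[[length(phase_truth) + 1L]] <- data.frame(
          transcript_id = planted_sites$transcript_id[r],
          register = cl %% 21L, cluster_start = cl,
          cycles = cfg$phased_cycles, stringsAsFactors = FALSE)
    }
    bg <- replicate(cfg$n_background_reads,
                    rand_seq(sample(18:26, 1), RNA_BASES))
    seqs <- c(seqs, bg); cnts <- c(cnts, rpois(length(bg), 4) + 1)
    srna_libs[[lib_name]] <- srna_library(lib_name, seqs, cnts)
  }

  contrasts <- data.frame(
    contrast = "stress_vs_mock",
    mock_libs = paste(lib_names[seq_len(cfg$n_replicates)], collapse = ","),
    stress_libs = paste(lib_names[cfg$n_replicates + seq_len(cfg$n_replicates)],
                        collapse = ","), stringsAsFactors = FALSE)

  # -- write files -----------------------------------------------------------
  write_fasta(mirnas, file.path(out_dir, "mirnas.fa"))
  write_fasta(transcripts, file.path(out_dir, "transcripts.fa"))
  write_fasta(proteins, file.path(out_dir, "proteins.fa"))
  write_report_tsv(as.data.frame(annotation),
                   file.path(out_dir, "annotation.tsv"))
  for (s in cfg$species)
    write_fasta(genomes[[s]], file.path(out_dir, "genomes",
                                        paste0(s, ".fa")))
  for (nm in names(srna_libs))
    write_small_rna_library(srna_libs[[nm]],
                            file.path(out_dir, "srna", paste0(nm, ".fa")))
  for (nm in names(deg_libs))
    write_small_rna_library(deg_libs[[nm]],
                            file.path(out_dir, "degradome",
                                      paste0(nm, ".fa")))
  writeLines(cfg$tree_newick, file.path(out_dir, "tree.nwk"))
  write_report_tsv(contrasts, file.path(out_dir, "contrasts.tsv"))

  manifest <- list(
    seed = cfg$seed,
    mirnas = data.frame(mirna_id = mir_id, seq = mir_seq,
                        length = mir_len, log2fc = as.numeric(lfc),
                        stringsAsFactors = FALSE),
    presence = data.frame(
      mirna_id = rep(rownames(presence), times = ncol(presence)),
      species = rep(colnames(presence), each = nrow(presence)),
      copies = as.integer(presence), stringsAsFactors = FALSE),
    loci = planted_loci,
    sites = planted_sites,
    degradome_peaks = do.call(rbind, deg_truth),
    phased_clusters = do.call(rbind, phase_truth),
    domain_classes = prot[, c("protein_id", "class")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  invisible(list(dir = out_dir, manifest = manifest, mirnas = mirnas,
                 transcripts = transcripts, annotation = annotation,
                 proteins = proteins, genomes = genomes,
                 srna_libs = srna_libs, deg_libs = deg_libs, tree = tree,
                 presence = presence, contrasts = contrasts))
}

#' Read a simulation manifest back from disk
#' @param path `manifest.json` path.
#' @return the manifest list (data frames restored).
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' The six mature wheat miRNAs of the worked example
#'
#' Bundles the mature sequences of the six disease-resistance-associated
#' wheat miRNAs used throughout the documentation: tae-miR3117a/b (21 nt,
#' differing at a single position), tae-miR3084a (22 nt), tae-miR5071a
#' (21 nt), tae-miR7757a (22 nt) and tae-miR9863a (22 nt).
#'
#' @return an RNA `seq_set` with six records.
#' @export
worked_fixture <- function() {
  read_fasta(system.file("extdata", "tae_mature_mirnas.fa",
                         package = "resistomir"), alphabet = "rna")
}
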