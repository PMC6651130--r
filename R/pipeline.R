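# End-to-end pipeline: target scan -> locus mapping -> hairpin folding ->
# degradome validation -> phasing -> expression -> annotation -> evolution,
# with one TSV per stage and a per-miRNA summary.

#' Default pipeline configuration
#'
#' Collects every stage threshold in one validated list: duplex score
#' cutoff 4 (strict), precursor dG threshold -30 kcal/mol, cleavage
#' p-value 0.05, phase score 15, response |log2fc| 1, target TPM floor 5
#' and fold change 2.
#'
#' @param input_dir directory holding the study inputs (layout as written
#'   by [simulate_study()]).
#' @param ... overrides for any field.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    cutoff = 4, max_bulges = 1L, inclusive_cutoff = FALSE,
    dg_max = -30, min_paired = 0.6,
    flank_grid = c(40L, 80L, 120L, 160L, 200L, 240L),
    max_p = 0.05, min_phase_score = 15,
    log2fc_threshold = 1, min_tpm = 5, min_fc = 2,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$cutoff > 0, cfg$max_p > 0, cfg$max_p <= 1,
            cfg$dg_max < 0, cfg$min_phase_score > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with an `input_dir` key plus threshold overrides.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir)) stop("config must set input_dir")
  do.call(pipeline_config, y)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[resistomir] %-12s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full discovery pipeline
#'
#' Executes every stage on the inputs under `config$input_dir` and writes
#' one TSV (or GFF3) per stage plus a per-miRNA `summary.tsv` to
#' `out_dir`.  Rerunning with the same inputs and config reproduces the
#' outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir report directory (created if needed).
#' @return invisibly, a list with every stage result and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ind <- cfg$input_dir
  need <- c("mirnas.fa", "transcripts.fa", "annotation.tsv", "tree.nwk",
            "contrasts.tsv")
  for (f in need)
    if (!file.exists(file.path(ind, f)))
      stop("missing input file: ", file.path(ind, f))
  t0 <- as.numeric(Sys.time())

  mirnas <- read_fasta(file.path(ind, "mirnas.fa"), "rna")
  transcripts <- read_fasta(file.path(ind, "transcripts.fa"), "rna")
  annotation <- read_transcript_annotation(file.path(ind, "annotation.tsv"))
  tree <- read_newick(file.path(ind, "tree.nwk"))
  genomes <- load_genome_dir(file.path(ind, "genomes"))
  deg_libs <- load_library_dir(file.path(ind, "degradome"))
  srna_libs <- load_library_dir(file.path(ind, "srna"))
  contrasts <- read_report_tsv(file.path(ind, "contrasts.tsv"))

  # scan ----------------------------------------------------------------
  sites <- scan_transcriptome(mirnas, transcripts, cutoff = cfg$cutoff,
                              max_bulges = cfg$max_bulges,
                              inclusive = cfg$inclusive_cutoff,
                              annotation = annotation)
  write_report_tsv(sites, file.path(out_dir, "sites.tsv"))
  stage_msg("scan", t0)

  # map-loci ------------------------------------------------------------
  presence <- build_presence_matrix(mirnas, genomes)
  all_loci <- do.call(rbind, lapply(names(genomes), function(s) {
    rows <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i)
      find_perfect_loci(mirnas[i, ], genomes[[s]])))
    if (!is.null(rows) && nrow(rows) > 0) rows$species <- s
    rows
  }))
  if (is.null(all_loci)) all_loci <- data.frame()
  write_gff3(all_loci, file.path(out_dir, "loci.gff3"))
  stage_msg("map-loci", t0)

  # fold ----------------------------------------------------------------
  prec_rows <- list()
  if (nrow(all_loci) > 0) for (i in seq_len(nrow(all_loci))) {
    locus <- all_loci[i, ]
    genome <- genomes[[locus$species]]
    cand <- evaluate_precursor(locus, genome, dg_max = cfg$dg_max,
                               min_paired = cfg$min_paired,
                               flank_grid = cfg$flank_grid)
    prec_rows[[i]] <- data.frame(
      mirna_id = locus$mirna_id, species = locus$species,
      chrom = locus$chrom, strand = locus$strand, start = locus$start,
      end = locus$end,
      flank5 = if (is.null(cand)) NA_integer_ else cand$flank5,
      flank3 = if (is.null(cand)) NA_integer_ else cand$flank3,
      dG = if (is.null(cand)) NA_real_ else cand$dG,
      pass = !is.null(cand), stringsAsFactors = FALSE)
  }
  precursors <- if (length(prec_rows)) do.call(rbind, prec_rows) else
    data.frame()
  write_report_tsv(precursors, file.path(out_dir, "precursors.tsv"))
  stage_msg("fold", t0)

  # degradome -----------------------------------------------------------
  deg <- validate_targets(sites, deg_libs, transcripts, max_p = cfg$max_p)
  write_report_tsv(deg$calls, file.path(out_dir, "cleavage.tsv"))
  stage_msg("degradome", t0)

  # phase ---------------------------------------------------------------
  cluster_rows <- list()
  for (lib_name in names(srna_libs)) {
    for (ti in seq_len(nrow(transcripts))) {
      prof <- align_library_to_transcript(srna_libs[[lib_name]],
                                          transcripts[ti, ])
      cl <- detect_phased_clusters(prof, min_score = cfg$min_phase_score,
                                   transcript_length =
                                     nchar(transcripts$seq[ti]))
      if (nrow(cl) > 0) { cl$library <- lib_name
        cluster_rows[[length(cluster_rows) + 1L]] <- cl }
    }
  }
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    data.frame(transcript_id = character(0), window_start = integer(0),
               window_end = integer(0), register = integer(0),
               P = numeric(0), U = numeric(0), k = integer(0),
               score = numeric(0), library = character(0))
  write_report_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  stage_msg("phase", t0)

  # express -------------------------------------------------------------
  em <- expression_matrix(mirnas, srna_libs)
  expr_df <- data.frame(mirna_id = rownames(em$tpm),
                        round(em$tpm, 3), check.names = FALSE)
  write_report_tsv(expr_df, file.path(out_dir, "expression.tsv"))
  resp_rows <- list()
  for (ci in seq_len(nrow(contrasts))) {
    mock <- strsplit(contrasts$mock_libs[ci], ",", fixed = TRUE)[[1]]
    stress <- strsplit(contrasts$stress_libs[ci], ",", fixed = TRUE)[[1]]
    for (m in rownames(em$tpm)) {
      r <- call_response(mean(em$tpm[m, mock]), mean(em$tpm[m, stress]))
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        mirna_id = m, contrast = contrasts$contrast[ci],
        log2fc = r$log2fc, call = r$call, stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, resp_rows)
  write_report_tsv(responses, file.path(out_dir, "responses.tsv"))
  stage_msg("express", t0)

  # annotate ------------------------------------------------------------
  domains <- data.frame()
  prot_path <- file.path(ind, "proteins.fa")
  if (file.exists(prot_path)) {
    proteins <- read_fasta(prot_path, "protein")
    domains <- annotate_proteins(proteins)
    write_report_tsv(domains, file.path(out_dir, "domains.tsv"))
  }
  stage_msg("annotate", t0)

  # evolve --------------------------------------------------------------
  write_report_tsv(data.frame(mirna_id = rownames(presence), presence,
                              check.names = FALSE),
                   file.path(out_dir, "presence.tsv"))
  events <- reconstruct_family_events(presence, tree)
  ev_df <- do.call(rbind, lapply(names(events), function(m) {
    e <- events[[m]]
    data.frame(mirna_id = m, origin = e$origin_label,
               origin_age = if (is.null(e$origin_age)) "" else
                 paste0(e$origin_age[1], "-", e$origin_age[2]),
               n_losses = e$n_losses,
               losses = paste(vapply(e$loss_clades, paste, character(1),
                                     collapse = "+"), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev_df)) ev_df <- data.frame()
  write_report_tsv(ev_df, file.path(out_dir, "events.tsv"))
  net <- network_and_overlaps(sites)
  write_report_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
  write_report_tsv(net$overlaps, file.path(out_dir, "overlaps.tsv"))
  stage_msg("evolve", t0)

  # summary -------------------------------------------------------------
  summary <- pipeline_summary(mirnas, sites, domains, deg, clusters,
                              responses, ev_df)
  write_report_tsv(summary, file.path(out_dir, "summary.tsv"))
  stage_msg("summary", t0)

  invisible(list(sites = sites, loci = all_loci, presence = presence,
                 precursors = precursors, degradome = deg,
                 clusters = clusters, expression = em,
                 responses = responses, domains = domains,
                 events = events, network = net, summary = summary))
}

load_genome_dir <- function(dir) {
  if (!dir.exists(dir)) stop("missing genome directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  gen <- lapply(files, read_fasta, alphabet = "dna")
  names(gen) <- sub("\\.fa(sta)?$", "", basename(files))
  gen
}

load_library_dir <- function(dir) {
  if (!dir.exists(dir)) stop("missing library directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  libs <- lapply(files, read_small_rna_library, dialect = "collapsed_fasta")
  names(libs) <- vapply(libs, `[[`, character(1), "name")
  libs
}

pipeline_summary <- function(mirnas, sites, domains, deg, clusters,
                             responses, ev_df) {
  rows <- lapply(mirnas$id, function(m) {
    s <- sites[sites$mirna_id == m, , drop = FALSE]
    tgt <- unique(s$transcript_id)
    nblrr <- if (nrow(domains) > 0) {
      cls <- domains$class[match(paste0(tgt, "_prot"), domains$protein_id)]
      mean(cls %in% c("N", "NL", "CNL"), na.rm = TRUE)
    } else NA_real_
    vcalls <- deg$calls[deg$calls$mirna_id == m &
                          deg$calls$p_value <= 0.05, , drop = FALSE]
    percat <- vapply(split(vcalls, vcalls$library), function(g) {
      tab <- table(g$category)
      paste(sprintf("%d(%s)", as.integer(tab), names(tab)), collapse = "; ")
    }, character(1))
    ph <- clusters[clusters$transcript_id %in% tgt, , drop = FALSE]
    rsp <- responses[responses$mirna_id == m, , drop = FALSE]
    data.frame(
      mirna_id = m, n_targets = length(tgt),
      nblrr_fraction = round(nblrr, 3),
      validated_targets = length(unique(vcalls$transcript_id)),
      cleavage_by_library = paste(names(percat), percat, sep = ":",
                                  collapse = " | "),
      phased_clusters = length(unique(paste(ph$transcript_id,
                                            ph$window_start))),
      response = paste(rsp$call, collapse = ","),
      origin = if (nrow(ev_df) && m %in% ev_df$mirna_id)
        ev_df$origin[ev_df$mirna_id == m] else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
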