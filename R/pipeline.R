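## Single-command pipeline: demultiplex -> trim -> assemble -> support
## filter -> re-map/flag -> homology screen -> precursor annotation ->
## physicochemical profiling, with per-stage counters and reports.

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: 20-nt primer windows
#' with at most 3 polymorphic positions, 0.8 clustering identity, Mott
#' trimming limit 0.05, 100-nt minimum read length, minimum contig
#' support 3, E-value cutoff 0.05, novelty identity bands 80/81-99/100
#' with a 70% coverage cutoff, 450-nt platform limit, 10-nt barcodes.
#' Unknown keys are rejected.
#'
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    window_len = 20L, max_polymorphic = 3L, identity_threshold = 0.8,
    trim_limit = 0.05, min_read_length = 100L, min_support = 3L,
    alpha = 0.05, id_similar_low = 81, id_below = 80, cover_novel = 70,
    platform_max = 450L, barcode_length = 10L, barcode_max_mismatch = 1L,
    min_overlap = 50L, min_overlap_identity = 0.95,
    polymorphism_floor = 0.2, flag_rate = 0.02,
    stringent_identity = 0.99, signal_len = 22L, strip_amidation = TRUE,
    min_orf_aa = 30L, forward_tail = "CAGGACCAGGGTACGGTG",
    reverse_tail = "CCTCTCTATGGGCAGTCGGTGAT", seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L)
    stop("unknown pipeline_config keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$trim_limit > 0, cfg$trim_limit < 1,
            cfg$min_read_length >= 1, cfg$min_support >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_overlap_identity > 0, cfg$min_overlap_identity <= 1,
            cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$cover_novel >= 0, cfg$cover_novel <= 100,
            cfg$platform_max > 0)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(
    path, simplifyVector = TRUE) else yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration
#'
#' The echoed file re-parses to an equal configuration.
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path (`.yaml` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  vals <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Run the full discovery pipeline on amplicon reads
#'
#' Stages: demultiplex (optional) -> quality trim -> greedy OLC assembly
#' -> read-support filter -> re-map and stringent re-assembly of
#' polymorphic contigs -> translated homology screen against the
#' known-AMP database -> precursor annotation -> physicochemical
#' profiling. Returns per-stage counters, a per-sample summary table
#' (raw reads, trimmed reads, contigs, AMPs on target) and a per-peptide
#' table (sequence, charge, H, MW, class, tier).
#'
#' @param reads A `qual_reads` object (or FASTQ path).
#' @param db Named character vector of known AMP precursor/mature
#'   proteins (or protein FASTA path) used for the screen and novelty
#'   tiering.
#' @param cfg A [pipeline_config()].
#' @param barcodes Named character vector of sample barcodes, or `NULL`
#'   when the library is a single unbarcoded sample.
#' @param out_dir Directory for per-stage TSV/FASTA outputs, or `NULL`
#'   to skip writing.
#' @return An `amp_pipeline_result`: list with `summary`, `peptides`,
#'   `annotation`, `contigs`, `hits`, `counters`, `config`.
#' @export
run_pipeline <- function(reads, db, cfg = pipeline_config(),
                         barcodes = NULL, out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_fastq(reads)
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- read_fasta(db)
  validate_config(cfg)
  counters <- list(raw_reads = length(reads))
  if (length(reads) == 0L) {
    warning("empty read set: producing an all-zero summary")
    return(structure(list(
      summary = data.frame(sample = character(), raw_reads = integer(),
                           trimmed_reads = integer(), contigs = integer(),
                           amps_on_target = integer()),
      peptides = NULL, annotation = NULL, contigs = NULL, hits = NULL,
      counters = counters, config = cfg), class = "amp_pipeline_result"))
  }
  samples <- if (is.null(barcodes)) list(sample1 = reads)
             else demultiplex(reads, barcodes, cfg$barcode_max_mismatch)
  samples <- samples[setdiff(names(samples), "undetermined")]
  tcfg <- trim_config(error_prob_limit = cfg$trim_limit,
                      min_length = cfg$min_read_length,
                      adapters = c(cfg$forward_tail,
                                   revcomp(cfg$reverse_tail)),
                      barcode_length = cfg$barcode_length,
                      barcode_max_mismatch = cfg$barcode_max_mismatch)
  summary_rows <- list(); all_ann <- list(); all_hits <- list()
  all_contigs <- list()
  for (s in names(samples)) {
    raw_n <- length(samples[[s]])
    tr <- trim_reads(samples[[s]], tcfg)
    counters[[paste0(s, "_trimmed")]] <- length(tr$reads)
    counters[[paste0(s, "_discarded")]] <- raw_n - length(tr$reads)
    asm <- assemble_olc(tr$reads, min_overlap = cfg$min_overlap,
                        min_overlap_identity = cfg$min_overlap_identity)
    kept <- filter_support(asm, cfg$min_support)
    rf <- remap_and_flag(kept, tr$reads,
                         polymorphism_floor = cfg$polymorphism_floor,
                         flag_rate = cfg$flag_rate,
                         stringent_identity = cfg$stringent_identity,
                         min_overlap = cfg$min_overlap)
    contigs <- rf$contigs
    names(contigs$consensus) <- paste0(s, "_", names(contigs$consensus))
    hits <- translated_search(contigs$consensus, db, alpha = cfg$alpha)
    pos <- contigs$consensus[names(contigs$consensus) %in% hits$query]
    ann <- if (length(pos) > 0L)
      annotate_contigs(pos, db = db, signal_len = cfg$signal_len,
                       strip_amidation = cfg$strip_amidation,
                       alpha = cfg$alpha, cover_novel = cfg$cover_novel,
                       min_orf_aa = cfg$min_orf_aa) else NULL
    ## "on target" = distinct known AMPs recovered at full identity
    ## when a database is available (truncation variants of the same
    ## target collapse onto one subject); otherwise all distinct
    ## annotated matures
    n_amp <- if (is.null(ann)) 0L
             else if (!all(is.na(ann$tier)))
               length(unique(ann$hit_subject[ann$tier ==
                                               "known_identical"]))
             else length(unique(ann$mature))
    summary_rows[[s]] <- data.frame(
      sample = s, raw_reads = raw_n, trimmed_reads = length(tr$reads),
      contigs = length(contigs$consensus), amps_on_target = n_amp,
      stringsAsFactors = FALSE)
    all_contigs[[s]] <- contigs
    if (nrow(hits) > 0L) all_hits[[s]] <- hits
    if (!is.null(ann)) all_ann[[s]] <- ann
  }
  annotation <- if (length(all_ann)) do.call(rbind, all_ann) else NULL
  peptides <- NULL
  if (!is.null(annotation)) {
    rownames(annotation) <- NULL
    peptides <- data.frame(
      id = annotation$contig,
      sequence = paste0(annotation$mature,
                        ifelse(annotation$amidated, "-NH2", "")),
      length = nchar(annotation$mature),
      charge = annotation$net_charge,
      H = round(annotation$mean_hydrophobicity, 3),
      MW = round(annotation$molecular_weight, 1),
      class = annotation$class, tier = annotation$tier,
      stringsAsFactors = FALSE)
  }
  res <- structure(list(
    summary = do.call(rbind, summary_rows),
    peptides = peptides, annotation = annotation,
    contigs = all_contigs,
    hits = if (length(all_hits)) do.call(rbind, all_hits) else NULL,
    counters = counters, config = cfg), class = "amp_pipeline_result")
  rownames(res$summary) <- NULL
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.amp_pipeline_result <- function(x, ...) {
  cat("amp_pipeline_result\n")
  print(x$summary)
  if (!is.null(x$peptides))
    cat(nrow(x$peptides), "annotated mature peptides\n")
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits summary.tsv, peptides.tsv, annotation.tsv, hits.tsv, contig
#' FASTAs, mature-peptide FASTA and the echoed config.
#'
#' @param res An `amp_pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) if (!is.null(df))
    write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$summary, "summary.tsv")
  wt(res$peptides, "peptides.tsv")
  wt(res$annotation, "annotation.tsv")
  if (!is.null(res$hits)) write_hits_tsv(res$hits,
                                         file.path(out_dir, "hits.tsv"))
  for (s in names(res$contigs)) {
    cc <- res$contigs[[s]]$consensus
    if (length(cc) > 0L)
      write_fasta(cc, file.path(out_dir, paste0(s, "_contigs.fasta")))
  }
  if (!is.null(res$annotation))
    write_mature_fasta(res$annotation,
                       file.path(out_dir, "mature_peptides.fasta"))
  write_config(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
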