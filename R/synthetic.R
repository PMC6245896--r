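## Seeded generator of ground-truthed AMP precursor gene families and
## Ion-Torrent-like amplicon reads, so every pipeline stage is testable
## without external downloads.

## run expr with a locally-seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## preferred codons for amino acids (one codon each; keeps back
## translation deterministic given RNG state)
AA_CODONS <- list(
  A = c("GCT", "GCA"), C = c("TGT", "TGC"), D = c("GAT", "GAC"),
  E = c("GAA", "GAG"), F = c("TTT", "TTC"), G = c("GGT", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC"), K = c("AAA", "AAG"),
  L = c("TTG", "CTT"), M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCA"), Q = c("CAA", "CAG"), R = c("CGT", "AGA"),
  S = c("TCT", "AGC"), T = c("ACT", "ACA"), V = c("GTT", "GTA"),
  W = "TGG", Y = c("TAT", "TAC"))

back_translate <- function(pep) {
  paste(vapply(seq_chars(pep), function(aa) {
    cods <- AA_CODONS[[aa]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

#' Family specification for the precursor generator
#'
#' The defaults emulate the architecture of anuran AMP precursor genes:
#' a highly conserved signal peptide (consensus encoding
#' MFTLKKSLLLLFFLGTINLSLC, the canonical ranid secretion signal, with
#' per-base mutations between loci), a negatively charged acidic
#' propeptide, a Lys-Arg processing site, a hypervariable cationic
#' mature region with optional rana-box and optional amidation signal, a
#' 3' UTR shorter than 200 nt and a poly-A tail.
#'
#' @param n_loci Number of loci (default 10).
#' @param signal_consensus Nucleotide consensus of the signal-peptide
#'   coding region, beginning with the start codon.
#' @param signal_mutation_rate Per-base substitution probability applied
#'   to the signal consensus per locus (default 0.03).
#' @param propeptide_length Propeptide length in residues (default 16).
#' @param propeptide_charge Target net formal charge of the propeptide
#'   (default -4; must be <= 0).
#' @param mature_length_range Mature peptide length range (default
#'   c(15, 30)).
#' @param mature_charge Target mature net charge (default +3).
#' @param ranabox_probability Probability a locus carries a rana-box
#'   (default 0.3).
#' @param amidation_probability Probability of a trailing G(K/R)
#'   amidation signal (default 0.4).
#' @param utr3_length_range 3' UTR length range, max < 200 (default
#'   c(50, 150)).
#' @param polyA_length Poly-A tail length (default 25).
#' @param seed RNG seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_loci = 10L,
                        signal_consensus = paste0(
                          "ATGTTCACCTTGAAGAAATCCCTTTTGCTTCTTTTCTTT",
                          "CTTGGAACTATTAACTTGTCTTTGTGT"),
                        signal_mutation_rate = 0.03,
                        propeptide_length = 16L,
                        propeptide_charge = -4L,
                        mature_length_range = c(15L, 30L),
                        mature_charge = 3L,
                        ranabox_probability = 0.3,
                        amidation_probability = 0.4,
                        utr3_length_range = c(50L, 150L),
                        polyA_length = 25L,
                        seed = 1L) {
  stopifnot(nchar(signal_consensus) %% 3 == 0,
            max(utr3_length_range) < 200L,
            signal_mutation_rate >= 0, signal_mutation_rate <= 1,
            ranabox_probability >= 0, ranabox_probability <= 1,
            amidation_probability >= 0, amidation_probability <= 1,
            propeptide_charge <= 0L)
  structure(as.list(environment()), class = "family_spec")
}

## acidic propeptide meeting the charge target: composition from
## {D,E,A,S,L,Q} with the number of D/E fixed by the target
random_propeptide <- function(len, charge) {
  n_acid <- 1L - charge             # (#D + #E) = 1 - target charge
  if (n_acid > len)
    stop("infeasible propeptide spec: length ", len,
         " cannot reach charge ", charge)
  acid <- sample(c("D", "E"), n_acid, replace = TRUE)
  rest <- sample(c("A", "S", "L", "Q"), len - n_acid, replace = TRUE)
  paste(sample(c(acid, rest)), collapse = "")
}

## cationic mature peptide: hydrophobic/neutral backbone with K/R placed
## to meet the charge target; optional rana-box; optional amidation tail
random_mature <- function(len_range, charge, ranabox, amidation) {
  len <- sample(len_range[1L]:len_range[2L], 1L)
  ranabox_here <- ranabox && len >= 12L
  ## N terminus contributes +1; the rana-box loop carries one K
  n_basic <- charge - 1L - if (ranabox_here) 1L else 0L
  n_basic <- max(0L, n_basic)
  reserved <- if (ranabox_here) 7L else 0L  # C K x x x C tail block
  if (n_basic + reserved > len)
    stop("infeasible mature spec: length ", len, " cannot host charge ",
         charge, if (ranabox_here) " plus a rana-box")
  body_len <- len - reserved
  repeat {
    backbone <- sample(c("G", "L", "A", "I", "V", "F", "S", "T"),
                       body_len, replace = TRUE)
    if (n_basic > 0L) {
      pos <- sample.int(body_len, n_basic)
      backbone[pos] <- sample(c("K", "R"), n_basic, replace = TRUE)
    }
    pep <- paste(backbone, collapse = "")
    ## a K-R dipeptide inside the mature region would offer a spurious
    ## downstream cleavage site; a G[KR]* suffix would mimic an
    ## amidation signal -- reject and redraw
    if (!grepl("KR", pep) &&
        (ranabox_here || !grepl("G[KR]*$", pep))) break
  }
  if (ranabox_here) {
    loop <- paste(sample(c("A", "I", "T", "S"), 3L, replace = TRUE),
                  collapse = "")
    ## loop is C + K + 3 neutral residues + C: gap 4, one basic inside
    pep <- paste0(pep, "C", "K", loop, "C")
  }
  amid_tail <- ""
  if (amidation)
    amid_tail <- paste0("G", sample(c("", "K", "R"), 1L))
  list(mature = pep, amid_tail = amid_tail)
}

#' Generate a ground-truthed precursor gene family
#'
#' Each locus is start codon + mutated signal + acidic propeptide +
#' KR-encoding `AAACGT` + cationic mature region (optional rana-box Cys
#' pair, optional trailing amidation signal) + stop + 3' UTR + poly-A,
#' deterministic under the spec seed.
#'
#' @param spec A [family_spec()].
#' @return List with `transcripts` (named character vector) and `truth`
#'   (data.frame manifest: locus, transcript, precursor protein, mature
#'   peptide, amidated flag, rana-box flag, propeptide charge).
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    loci <- paste0("locus", sprintf("%02d", seq_len(spec$n_loci)))
    transcripts <- character(spec$n_loci)
    truth <- vector("list", spec$n_loci)
    sig_chars <- seq_chars(spec$signal_consensus)
    for (i in seq_len(spec$n_loci)) {
      sig <- sig_chars
      mut <- runif(length(sig)) < spec$signal_mutation_rate
      mut[1:3] <- FALSE  # keep the start codon
      if (any(mut))
        sig[mut] <- vapply(which(mut), function(k)
          sample(setdiff(c("A", "C", "G", "T"), sig[k]), 1L), "")
      sig_nt <- paste(sig, collapse = "")
      ## avoid premature stops introduced by signal mutations
      sig_aa <- translate_seq(sig_nt)
      if (grepl("\\*", sig_aa)) { sig_nt <- spec$signal_consensus }
      pro <- random_propeptide(spec$propeptide_length,
                               spec$propeptide_charge)
      rb <- runif(1) < spec$ranabox_probability
      am <- runif(1) < spec$amidation_probability
      mt <- random_mature(spec$mature_length_range, spec$mature_charge,
                          rb, am)
      cds <- paste0(sig_nt, back_translate(pro), "AAACGT",
                    back_translate(paste0(mt$mature, mt$amid_tail)),
                    "TAA")
      utr_len <- sample(spec$utr3_length_range[1L]:
                          spec$utr3_length_range[2L], 1L)
      utr <- paste(sample(c("A", "C", "G", "T"), utr_len,
                          replace = TRUE), collapse = "")
      polyA <- strrep("A", spec$polyA_length)
      transcripts[i] <- paste0(cds, utr, polyA)
      truth[[i]] <- data.frame(
        locus = loci[i], transcript = transcripts[i],
        protein = translate_seq(cds),
        mature = mt$mature,
        amidated = nchar(mt$amid_tail) > 0L,
        ranabox = rb && nchar(mt$mature) >= 12L,
        propeptide = pro,
        propeptide_charge = net_charge(pro),
        stringsAsFactors = FALSE)
    }
    names(transcripts) <- loci
    list(transcripts = transcripts, truth = do.call(rbind, truth))
  })
}

#' Read simulation specification
#'
#' @param coverage Reads per locus (default 50).
#' @param read_length_mean,read_length_sd Normal read-length model,
#'   truncated to `[min_read_length, max_read_length]` and to the
#'   amplicon length (defaults 380, 40).
#' @param min_read_length Shortest simulated read (default 120).
#' @param max_read_length Platform limit (default 450; reads never
#'   exceed it).
#' @param substitution_rate Per-base substitution probability
#'   (default 0.005).
#' @param homopolymer_indel_rate Per-homopolymer-run (length >= 2)
#'   probability of a +-1-base length error (default 0.005).
#' @param barcode Sample barcode sequence (10 nt default).
#' @param forward_tail,reverse_tail Library adapters flanking the
#'   insert.
#' @param seed RNG seed.
#' @return A `read_sim_spec` list.
#' @export
read_sim_spec <- function(coverage = 50L, read_length_mean = 380,
                          read_length_sd = 40, min_read_length = 120L,
                          max_read_length = 450L,
                          substitution_rate = 0.005,
                          homopolymer_indel_rate = 0.005,
                          barcode = "TACGTAGCGT",
                          forward_tail = "CAGGACCAGGGTACGGTG",
                          reverse_tail = "CCTCTCTATGGGCAGTCGGTGAT",
                          seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 1,
            max_read_length <= 450L)
  structure(as.list(environment()), class = "read_sim_spec")
}

apply_substitutions <- function(chars, rate) {
  hit <- runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(which(hit), function(k)
      sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L), "")
  chars
}

apply_homopolymer_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  r <- rle(chars)
  runs <- which(r$lengths >= 2L)
  if (length(runs) == 0L) return(chars)
  hit <- runs[runif(length(runs)) < rate]
  if (length(hit) == 0L) return(chars)
  for (k in hit)
    r$lengths[k] <- max(1L, r$lengths[k] + sample(c(-1L, 1L), 1L))
  inverse.rle(r)
}

## decreasing-quality Phred model typical of flow-based platforms
sim_quals <- function(n) {
  q <- 34 - 10 * (seq_len(n) / 450) + rnorm(n, 0, 2)
  as.integer(pmax(2L, pmin(40L, round(q))))
}

#' Simulate amplicon reads from transcripts
#'
#' Amplicons follow the targeted 3'-RACE library layout: sample barcode,
#' forward tail, template from the forward-primer binding site through
#' the poly-A tail, then the reverse-complemented reverse tail. Reads
#' are amplicon prefixes with a truncated-normal length model (never
#' exceeding the platform limit), per-base substitutions and
#' homopolymer-run length errors at the specified rates, and a
#' decreasing Phred profile. Deterministic under the spec seed.
#' Templates without a primer binding site are omitted with a message.
#'
#' @param transcripts Named character vector (5'->3', poly-A tailed).
#' @param panel List of `degenerate_primer` objects (or one).
#' @param spec A [read_sim_spec()].
#' @param max_mismatches Primer-site mismatch allowance (default 2).
#' @return A `qual_reads` object; attribute `"amplicons"` holds the
#'   error-free amplicon per locus.
#' @export
simulate_reads <- function(transcripts, panel, spec = read_sim_spec(),
                           max_mismatches = 2L) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (inherits(panel, "degenerate_primer")) panel <- list(panel)
  preds <- predict_amplicons(transcripts, panel,
                             max_mismatches = max_mismatches,
                             platform_max = spec$max_read_length,
                             rev_tail = spec$reverse_tail)
  with_seed(spec$seed, {
    ids <- character(); seqs <- character(); quals <- list()
    amplicons <- character()
    for (tid in unique(preds$template_id)) {
      rows <- preds[preds$template_id == tid, , drop = FALSE]
      best <- rows[order(rows$mismatches, rows$forward_site)[1L], ,
                   drop = FALSE]
      insert <- substring(transcripts[[tid]], best$forward_site + 1L)
      amp <- paste0(spec$barcode, spec$forward_tail, insert,
                    revcomp(spec$reverse_tail))
      amplicons[tid] <- amp
      achars <- seq_chars(amp)
      for (r in seq_len(spec$coverage)) {
        len <- round(rnorm(1, spec$read_length_mean,
                           spec$read_length_sd))
        len <- max(spec$min_read_length,
                   min(len, spec$max_read_length, length(achars)))
        rd <- achars[seq_len(len)]
        rd <- apply_substitutions(rd, spec$substitution_rate)
        rd <- apply_homopolymer_indels(rd,
                                       spec$homopolymer_indel_rate)
        rd <- rd[seq_len(min(length(rd), spec$max_read_length))]
        ids <- c(ids, sprintf("%s_read%03d", tid, r))
        seqs <- c(seqs, paste(rd, collapse = ""))
        quals[[length(quals) + 1L]] <- sim_quals(length(rd))
      }
    }
    out <- qual_reads(ids, seqs, quals)
    attr(out, "amplicons") <- amplicons
    out
  })
}
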