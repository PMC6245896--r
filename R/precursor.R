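## Precursor annotation: split the precursor ORF into signal peptide,
## acidic propeptide and mature peptide at the Lys-Arg processing site,
## resolve C-terminal amidation, detect the rana-box, assign novelty
## tiers against a known-AMP database, and group peptides into classes.

#' Resolve a C-terminal amidation signal
#'
#' A precursor mature region ending in Gly followed by zero or more basic
#' residues (K/R) is enzymatically converted to a C-terminal amide on the
#' residue preceding the Gly. When `strip = TRUE` that suffix is removed
#' and the peptide flagged amidated; stripping is an explicit, flagged
#' transformation, never silent, because reported sequences sometimes
#' retain the signal. Idempotent: an already-amidated peptide is returned
#' unchanged.
#'
#' @param peptide Peptide string (or one-element list with `amidated`).
#' @param strip Apply the stripping rule (default TRUE)?
#' @param amidated Is the input already amidated (then a no-op)?
#' @return List with `peptide`, `amidated`, `stripped` (the removed
#'   suffix, `""` if none).
#' @examples
#' resolve_amidation("LVPFIGRTLGGLLARFGK")
#' @export
resolve_amidation <- function(peptide, strip = TRUE, amidated = FALSE) {
  p <- sub("\\*$", "", norm_pep(peptide))
  if (amidated || !strip)
    return(list(peptide = p, amidated = amidated, stripped = ""))
  m <- regmatches(p, regexpr("G[KR]*$", p))
  if (length(m) == 1L && nchar(p) - nchar(m) >= 1L) {
    list(peptide = substr(p, 1L, nchar(p) - nchar(m)), amidated = TRUE,
         stripped = m)
  } else {
    list(peptide = p, amidated = FALSE, stripped = "")
  }
}

#' Split a precursor protein at the Lys-Arg cleavage site
#'
#' The mature peptide is obtained by removing everything N-terminal to
#' the basic Lys-Arg propeptide cleavage site. Cleavage occurs at the
#' last `KR` dipeptide whose downstream segment has non-negative net
#' charge (anuran precursors can contain internal KR pairs; requiring a
#' cationic downstream segment prevents premature cleavage). The signal
#' peptide is taken as the first `signal_len` residues and the acidic
#' propeptide is the remainder up to the cleavage dipeptide.
#'
#' @param protein Precursor protein (should begin with Met; a trailing
#'   `*` is tolerated).
#' @param signal_len Signal peptide length when no external boundary is
#'   supplied (default 22, typical of anuran precursors).
#' @param site `"last_kr"` (default) or `"first_kr"`.
#' @param accept_kk_rr Also accept `KK`/`RR` dibasic sites?
#' @param strip_amidation Apply [resolve_amidation()] to the mature
#'   region? Stripping is opt-in (default `FALSE`): reported mature
#'   sequences sometimes retain the amidation signal, so the pipeline
#'   enables it explicitly.
#' @return A `precursor_annotation` list: `protein`, `signal`,
#'   `propeptide`, `mature`, `amidated`, `stripped`, `cleavage_site`
#'   (1-based index of the K of the dibasic motif, `NA` when absent),
#'   `no_cleavage_site` flag, `propeptide_charge_warning` flag.
#' @export
split_precursor <- function(protein, signal_len = 22L,
                            site = c("last_kr", "first_kr"),
                            accept_kk_rr = FALSE,
                            strip_amidation = FALSE) {
  site <- match.arg(site)
  p <- sub("\\*$", "", norm_pep(protein))
  res <- seq_chars(p)
  motifs <- if (accept_kk_rr) c("KR", "KK", "RR") else "KR"
  hits <- integer()
  if (length(res) >= 2L) {
    pairs <- paste0(res[-length(res)], res[-1L])
    hits <- which(pairs %in% motifs)
  }
  ## keep sites whose downstream segment is non-negatively charged
  ok <- hits[vapply(hits, function(i) {
    down <- substring(p, i + 2L)
    nchar(down) > 0L && net_charge(down) >= 0L
  }, TRUE)]
  if (length(ok) == 0L) ok <- integer()
  cut <- if (length(ok)) {
    if (site == "last_kr") max(ok) else min(ok)
  } else NA_integer_
  if (is.na(cut)) {
    ann <- list(protein = p, signal = substr(p, 1L, min(signal_len,
                                                        nchar(p))),
                propeptide = "", mature = "", amidated = FALSE,
                stripped = "", cleavage_site = NA_integer_,
                no_cleavage_site = TRUE,
                propeptide_charge_warning = FALSE)
    class(ann) <- "precursor_annotation"
    return(ann)
  }
  signal <- substr(p, 1L, min(signal_len, cut - 1L))
  propeptide <- if (cut - 1L > nchar(signal))
    substr(p, nchar(signal) + 1L, cut - 1L) else ""
  raw_mature <- substring(p, cut + 2L)
  am <- resolve_amidation(raw_mature, strip = strip_amidation)
  warn <- nchar(propeptide) > 0L && net_charge(propeptide) > 0L
  if (warn)
    warning("propeptide has positive net charge (expected acidic)")
  ann <- list(protein = p, signal = signal, propeptide = propeptide,
              mature = am$peptide, amidated = am$amidated,
              stripped = am$stripped, cleavage_site = cut,
              no_cleavage_site = FALSE,
              propeptide_charge_warning = warn)
  class(ann) <- "precursor_annotation"
  ann
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("precursor_annotation\n",
      " signal:     ", x$signal, "\n",
      " propeptide: ", x$propeptide, "\n",
      " mature:     ", x$mature,
      if (x$amidated) "-NH2" else "", "\n", sep = "")
  invisible(x)
}

#' Detect a rana-box motif
#'
#' The rana-box is a C-terminal disulfide loop of Ranidae AMPs: two Cys
#' residues separated by 3-5 loop residues, both within the C-terminal
#' 10 residues, with at least one basic residue (K/R) inside the loop.
#'
#' @param peptide Peptide string.
#' @return List with `found` (logical) and `loop_start`, `loop_end`
#'   (1-based Cys positions, `NA` when absent).
#' @examples
#' detect_ranabox("IVPILLGVVPQLVCAITKKC")$found  # TRUE
#' @export
detect_ranabox <- function(peptide) {
  p <- sub("\\*$", "", norm_pep(peptide))
  res <- seq_chars(p)
  n <- length(res)
  cys <- which(res == "C")
  cys <- cys[cys >= n - 9L]
  if (length(cys) >= 2L) {
    for (i in head(seq_along(cys), -1L)) for (j in (i + 1L):length(cys)) {
      gap <- cys[j] - cys[i] - 1L
      if (gap >= 3L && gap <= 5L) {
        loop <- res[(cys[i] + 1L):(cys[j] - 1L)]
        if (any(loop %in% c("K", "R")))
          return(list(found = TRUE, loop_start = cys[i],
                      loop_end = cys[j]))
      }
    }
  }
  list(found = FALSE, loop_start = NA_integer_, loop_end = NA_integer_)
}

#' Assign a novelty tier from database hits
#'
#' Tiers partition every peptide exactly once:
#' no significant hit -> `novel_no_hit`; best hit at 100% identity with
#' coverage below the cutoff -> `identical_low_cover`; 100% identity
#' otherwise -> `known_identical`; identity within the 81-99 band ->
#' `similar_81_99`; identity below 80 -> `below_80`. Identity is rounded
#' to the nearest integer band boundary (half away from zero), so values
#' in (80, 81) fall to the nearest band.
#'
#' @param hits data.frame of hits for one peptide (pre-filtered at
#'   `evalue < alpha`; may be empty).
#' @param alpha Significance cutoff applied defensively (default 0.05).
#' @param cover_novel Query-coverage cutoff (percent) under which a 100%
#'   identity hit still counts as novel (default 70).
#' @return List with `tier` (character) and `hit` (best hit row or
#'   `NULL`).
#' @export
assign_novelty <- function(hits, alpha = 0.05, cover_novel = 70) {
  if (!is.null(hits) && nrow(hits) > 0L)
    hits <- hits[hits$evalue < alpha, , drop = FALSE]
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(tier = "novel_no_hit", hit = NULL))
  ord <- order(hits$evalue, -hits$identity)
  best <- hits[ord[1L], , drop = FALSE]
  id <- round(best$identity)
  tier <- if (id >= 100) {
    if (best$coverage < cover_novel) "identical_low_cover"
    else "known_identical"
  } else if (id >= 81) {
    "similar_81_99"
  } else {
    "below_80"
  }
  list(tier = tier, hit = best)
}

## Mean alpha-helix propensity (Pace & Scholtz-style free energies would
## need inverting; this uses the classic Chou-Fasman P_alpha values,
## >1 = helix former), a crude stand-in for secondary-structure
## prediction used only as a classification feature.
HELIX_PROPENSITY <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)

#' Feature vector for peptide classification
#'
#' @param peptide Peptide string.
#' @param amidated C-terminal amide?
#' @return One-row data.frame: `length`, `net_charge`,
#'   `mean_hydrophobicity`, `cys_count`, `ranabox`, `amidated`,
#'   `helix_propensity`.
#' @export
peptide_features <- function(peptide, amidated = FALSE) {
  p <- sub("\\*$", "", norm_pep(peptide))
  res <- seq_chars(p)
  data.frame(
    length = nchar(p), net_charge = net_charge(p),
    mean_hydrophobicity = mean_hydrophobicity(p),
    cys_count = sum(res == "C"), ranabox = detect_ranabox(p)$found,
    amidated = amidated,
    helix_propensity = mean(HELIX_PROPENSITY[res]),
    stringsAsFactors = FALSE)
}

#' Default eight-class rule set
#'
#' An ordered list of (label, predicate) rules; the first matching rule
#' wins and class 8 is the fallback for peptides matching none. The
#' shipped rules are a feature-threshold reconstruction of a manual
#' grouping (rana-box loop, other disulfide peptides, short/long
#' cationic helicals, cationic hydrophilic, anionic, very short), fully
#' replaceable by the user.
#'
#' @return List of rules, each a list with `class` (integer), `label`
#'   and `test` (function of a feature row returning logical).
#' @export
default_class_rules <- function() {
  list(
    list(class = 1L, label = "rana_box_loop",
         test = function(f) f$ranabox),
    list(class = 2L, label = "disulfide_non_ranabox",
         test = function(f) f$cys_count >= 2L),
    list(class = 3L, label = "short_cationic_helical",
         test = function(f) f$net_charge >= 2L &&
           f$mean_hydrophobicity >= 1 && f$length <= 25L &&
           f$helix_propensity >= 1),
    list(class = 4L, label = "long_cationic_helical",
         test = function(f) f$net_charge >= 2L &&
           f$mean_hydrophobicity >= 1 && f$length > 25L),
    list(class = 5L, label = "cationic_hydrophilic",
         test = function(f) f$net_charge >= 2L &&
           f$mean_hydrophobicity < 1),
    list(class = 6L, label = "anionic_or_neutral",
         test = function(f) f$net_charge <= 0L),
    list(class = 7L, label = "very_short",
         test = function(f) f$length < 10L)
  )
}

#' Classify a mature peptide into one of eight classes
#'
#' First matching rule wins; peptides matching no rule fall to class 8
#' (`unclassified`). Classification is a total function: every valid
#' peptide receives exactly one class.
#'
#' @param peptide Peptide string (or a feature row from
#'   [peptide_features()]).
#' @param rules Ordered rule list (default [default_class_rules()]).
#' @param amidated C-terminal amide flag (when `peptide` is a string).
#' @return List with `class` (1-8), `label`, `features`.
#' @export
classify_peptide <- function(peptide, rules = default_class_rules(),
                             amidated = FALSE) {
  f <- if (is.data.frame(peptide)) peptide
       else peptide_features(peptide, amidated)
  for (r in rules) {
    if (!is.list(r) || !is.function(r$test) || is.null(r$class))
      stop("malformed classification rule")
    if (isTRUE(r$test(f)))
      return(list(class = as.integer(r$class), label = r$label,
                  features = f))
  }
  list(class = 8L, label = "unclassified", features = f)
}

#' Annotate AMP-positive contigs end to end
#'
#' For each contig: call the longest ORF (requiring Met), split the
#' precursor, compute features, class, physicochemical profile, and
#' novelty tier against the known-AMP database.
#'
#' @param contigs Named character vector of contig sequences.
#' @param db Named character vector of known mature AMP peptides (for
#'   novelty tiering). `NULL` skips tiering.
#' @param signal_len,site,accept_kk_rr,strip_amidation Passed to
#'   [split_precursor()].
#' @param alpha,cover_novel Passed to the search and [assign_novelty()].
#' @param rules Classification rules.
#' @param min_orf_aa Minimum ORF length in residues (default 30,
#'   enough for signal + propeptide + a short mature peptide).
#' @return data.frame, one row per contig with a called precursor:
#'   contig, ORF coordinates, signal, propeptide, mature, amidated,
#'   ranabox, class, tier, charge, H, MW and best-hit fields.
#' @export
annotate_contigs <- function(contigs, db = NULL, signal_len = 22L,
                             site = "last_kr", accept_kk_rr = FALSE,
                             strip_amidation = TRUE, alpha = 0.05,
                             cover_novel = 70,
                             rules = default_class_rules(),
                             min_orf_aa = 30L) {
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  rows <- list()
  for (cid in names(contigs)) {
    ## candidate ORFs, longest first (ties by frame order, then
    ## position); the precursor is the longest ORF that yields a valid
    ## cleavage call -- assembled contigs have arbitrary orientation and
    ## the reverse strand of a poly-A tail reads through as Phe runs, so
    ## the single longest ORF can be spurious
    orfs <- find_orfs(contigs[[cid]], require_start = TRUE,
                      min_aa = min_orf_aa)
    if (nrow(orfs) == 0L) next
    frame_rank <- match(orfs$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
    scan_pos <- ifelse(orfs$frame > 0L, orfs$nt_start, -orfs$nt_end)
    orfs <- orfs[order(-nchar(orfs$protein), frame_rank, scan_pos), ,
                 drop = FALSE]
    ann <- NULL; orf <- NULL
    for (k in seq_len(nrow(orfs))) {
      cand <- suppressWarnings(
        split_precursor(orfs$protein[k], signal_len = signal_len,
                        site = site, accept_kk_rr = accept_kk_rr,
                        strip_amidation = strip_amidation))
      if (cand$no_cleavage_site || nchar(cand$mature) == 0L) next
      ## candidates with the expected acidic propeptide win over
      ## cationic-propeptide calls regardless of ORF length
      if (!cand$propeptide_charge_warning) {
        ann <- cand; orf <- orfs[k, , drop = FALSE]; break
      }
      if (is.null(ann)) { ann <- cand; orf <- orfs[k, , drop = FALSE] }
    }
    if (is.null(ann)) next
    cls <- classify_peptide(ann$mature, rules, amidated = ann$amidated)
    tier <- NA_character_; hit <- NULL
    if (!is.null(db)) {
      hits <- protein_search(setNames(ann$mature, cid), db,
                             alpha = alpha, best_only = FALSE)
      nv <- assign_novelty(hits, alpha = alpha,
                           cover_novel = cover_novel)
      tier <- nv$tier; hit <- nv$hit
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cid, frame = orf$frame, nt_start = orf$nt_start,
      nt_end = orf$nt_end, signal = ann$signal,
      propeptide = ann$propeptide, mature = ann$mature,
      amidated = ann$amidated, ranabox = cls$features$ranabox,
      class = cls$class, class_label = cls$label, tier = tier,
      net_charge = cls$features$net_charge,
      mean_hydrophobicity = cls$features$mean_hydrophobicity,
      molecular_weight = molecular_weight(ann$mature, ann$amidated),
      hit_subject = if (is.null(hit)) NA_character_ else hit$subject,
      hit_identity = if (is.null(hit)) NA_real_ else hit$identity,
      hit_coverage = if (is.null(hit)) NA_real_ else hit$coverage,
      hit_evalue = if (is.null(hit)) NA_real_ else hit$evalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write mature peptides as FASTA with the -NH2 suffix convention
#'
#' @param annotation data.frame from [annotate_contigs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mature_fasta <- function(annotation, path) {
  seqs <- paste0(annotation$mature,
                 ifelse(annotation$amidated, "-NH2", ""))
  write_fasta(setNames(seqs, annotation$contig), path)
  invisible(path)
}
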