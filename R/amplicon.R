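## Raw amplicon reads to high-confidence contigs: modified-Mott quality
## trimming, barcode demultiplexing, adapter clipping, length filtering,
## greedy overlap-layout-consensus assembly, read-support filtering,
## re-mapping and stringent re-assembly of polymorphic contigs.

#' Trimming configuration
#'
#' @param error_prob_limit Mott trimming limit: per-base weight is
#'   `limit - 10^(-Q/10)` and the kept segment maximizes the running sum
#'   (default 0.05).
#' @param min_length Reads shorter than this after trimming are discarded
#'   (default 100).
#' @param adapters Character vector of adapter sequences to clip
#'   (semi-global match, at most `adapter_max_error` errors per aligned
#'   base).
#' @param adapter_max_error Maximum error fraction for an adapter match
#'   (default 0.1).
#' @param barcode_length Sample barcode length (default 10).
#' @param barcode_max_mismatch Barcode mismatch tolerance (default 1).
#' @return A `trim_config` list.
#' @export
trim_config <- function(error_prob_limit = 0.05, min_length = 100L,
                        adapters = character(), adapter_max_error = 0.1,
                        barcode_length = 10L, barcode_max_mismatch = 1L) {
  stopifnot(error_prob_limit > 0, error_prob_limit < 1, min_length >= 1)
  structure(list(error_prob_limit = error_prob_limit,
                 min_length = as.integer(min_length),
                 adapters = toupper(adapters),
                 adapter_max_error = adapter_max_error,
                 barcode_length = as.integer(barcode_length),
                 barcode_max_mismatch = as.integer(barcode_max_mismatch)),
            class = "trim_config")
}

## Modified-Mott segment selection: indices (start, end) of the segment
## maximizing sum(limit - perr); NULL when every segment is negative.
mott_segment <- function(quals, limit) {
  w <- limit - 10^(-quals / 10)
  cs <- cumsum(w)
  ## best segment (i, j] maximizes cs[j] - cs[i]; vectorized Kadane
  prev_min <- cummin(c(0, cs[-length(cs)]))
  gains <- cs - prev_min
  if (max(gains) <= 0) return(NULL)
  j <- which.max(gains)
  i <- which(c(0, cs[-length(cs)]) == prev_min[j])[1L]
  c(start = i, end = j)
}

## clip the best adapter occurrence and everything after it (adapters
## mark the transition into non-template sequence); leading/trailing Ns
## removed afterwards.
clip_adapters <- function(seq, quals, adapters, max_error) {
  for (ad in adapters) {
    if (nchar(seq) < 1L || nchar(ad) < 1L) next
    a <- cpp_fit_align(ad, seq)
    span <- a$c_end - a$c_start + 1L
    if (span <= 0) next
    if (a$edits <= floor(max_error * nchar(ad))) {
      mid <- (a$c_start + a$c_end) / 2
      if (mid <= nchar(seq) / 2) {
        ## 5' adapter: drop it and everything before it
        drop <- a$c_end
        seq <- substring(seq, drop + 1L)
        quals <- quals[-seq_len(drop)]
      } else {
        ## 3' adapter: drop it and everything after it
        keep <- a$c_start - 1L
        seq <- substr(seq, 1L, keep)
        quals <- quals[seq_len(keep)]
      }
    }
  }
  ## leading/trailing N
  n <- nchar(seq)
  if (n > 0L) {
    ch <- seq_chars(seq)
    keep <- which(ch != "N")
    if (length(keep) == 0L) return(list(seq = "", quals = integer()))
    lo <- min(keep); hi <- max(keep)
    seq <- substr(seq, lo, hi)
    quals <- quals[lo:hi]
  }
  list(seq = seq, quals = quals)
}

#' Quality-trim a single read (modified Mott)
#'
#' Keeps the contiguous segment maximizing the running sum of
#' `limit - 10^(-Q/10)`, clips adapter occurrences and leading/trailing
#' `N`, and discards the read when the final length falls below
#' `cfg$min_length`.
#'
#' @param seq Read bases.
#' @param quals Integer Phred vector, same length.
#' @param cfg A [trim_config()].
#' @return List `(seq, quals)` or `NULL` when discarded.
#' @export
trim_read <- function(seq, quals, cfg = trim_config()) {
  stopifnot(nchar(seq) == length(quals))
  seg <- mott_segment(quals, cfg$error_prob_limit)
  if (is.null(seg)) return(NULL)
  seq <- substr(seq, seg["start"], seg["end"])
  quals <- quals[seg["start"]:seg["end"]]
  cl <- clip_adapters(seq, quals, cfg$adapters, cfg$adapter_max_error)
  if (nchar(cl$seq) < cfg$min_length) return(NULL)
  cl
}

#' Trim a qual_reads set
#'
#' @param reads A `qual_reads` object.
#' @param cfg A [trim_config()].
#' @return List with `reads` (trimmed `qual_reads`) and `log`
#'   (data.frame of per-read outcomes: kept / discarded reason).
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  keep_id <- character(); keep_seq <- character(); keep_q <- list()
  outcome <- character(length(reads))
  for (i in seq_len(length(reads))) {
    tr <- trim_read(reads$seq[i], reads$qual[[i]], cfg)
    if (is.null(tr)) {
      outcome[i] <- "discarded_short_or_lowq"
    } else {
      outcome[i] <- "kept"
      keep_id <- c(keep_id, reads$id[i])
      keep_seq <- c(keep_seq, tr$seq)
      keep_q[[length(keep_q) + 1L]] <- tr$quals
    }
  }
  list(reads = qual_reads(keep_id, keep_seq, keep_q),
       log = data.frame(id = reads$id, outcome = outcome,
                        stringsAsFactors = FALSE))
}

#' Demultiplex reads by 5' barcode
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' within `max_mismatch` Hamming mismatches; unmatched reads go to the
#' `"undetermined"` bin. The matched barcode prefix is stripped from the
#' read. Barcodes must be of equal length with pairwise Hamming distance
#' greater than `2 * max_mismatch`.
#'
#' @param reads A `qual_reads` object.
#' @param barcodes Named character vector (sample -> barcode).
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return Named list of `qual_reads`, one per sample plus
#'   `undetermined`.
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 1L) {
  barcodes <- toupper(barcodes)
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("barcodes must share one length")
  if (is.null(names(barcodes))) stop("barcodes must be named by sample")
  if (length(barcodes) > 1L) {
    for (i in seq_along(barcodes)) for (j in seq_along(barcodes)) {
      if (i >= j) next
      d <- sum(seq_chars(barcodes[i]) != seq_chars(barcodes[j]))
      if (d <= 2L * max_mismatch)
        stop("barcode pair ", names(barcodes)[i], "/",
             names(barcodes)[j], " violates the distance requirement")
    }
  }
  bins <- setNames(vector("list", length(barcodes) + 1L),
                   c(names(barcodes), "undetermined"))
  idx <- setNames(vector("list", length(bins)), names(bins))
  bc_mat <- do.call(rbind, strsplit(barcodes, "", fixed = TRUE))
  for (i in seq_len(length(reads))) {
    if (nchar(reads$seq[i]) < bl) { sample <- "undetermined" }
    else {
      pre <- seq_chars(substr(reads$seq[i], 1L, bl))
      mm <- rowSums(bc_mat != matrix(pre, nrow(bc_mat), bl, byrow = TRUE))
      best <- which.min(mm)
      sample <- if (mm[best] <= max_mismatch) names(barcodes)[best]
                else "undetermined"
    }
    idx[[sample]] <- c(idx[[sample]], i)
  }
  for (s in names(bins)) {
    ii <- idx[[s]]
    if (is.null(ii)) { bins[[s]] <- qual_reads(character(), character(),
                                               list()); next }
    sub <- reads[ii]
    if (s != "undetermined") {
      sub <- qual_reads(sub$id, substring(sub$seq, bl + 1L),
                        lapply(sub$qual, function(q) q[-seq_len(bl)]))
    }
    bins[[s]] <- sub
  }
  bins
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of sequences/contigs with the best
#' suffix-prefix overlap of at least `min_overlap` nt at identity at
#' least `min_overlap_identity` (both orientations when
#' `both_orientations = TRUE`), building a per-column base-count profile;
#' the consensus is the per-column majority with ties resolved in favour
#' of the earlier-created contig's base. Terminates when no merge
#' qualifies.
#'
#' @param reads Character vector of (trimmed) read sequences, or a
#'   `qual_reads` object.
#' @param min_overlap Minimum overlap length (default 50).
#' @param min_overlap_identity Minimum overlap identity (default 0.95).
#' @param both_orientations Consider reverse-complement merges?
#' @return An `amp_contigs` object: list with `consensus` (named
#'   character), `support` (integer), `profile` (list of 5 x L count
#'   matrices, rows A,C,G,T,N), `assignment` (contig index per input
#'   read).
#' @export
assemble_olc <- function(reads, min_overlap = 50L,
                         min_overlap_identity = 0.95,
                         both_orientations = TRUE) {
  if (inherits(reads, "qual_reads")) reads <- reads$seq
  if (length(reads) == 0L)
    return(structure(list(consensus = character(), support = integer(),
                          profile = list(), assignment = integer()),
                     class = "amp_contigs"))
  reads <- norm_nuc(reads)
  res <- cpp_assemble_olc(reads, as.integer(min_overlap),
                          min_overlap_identity, both_orientations)
  names(res$consensus) <- paste0("contig", seq_along(res$consensus))
  structure(list(consensus = res$consensus, support = res$support,
                 profile = res$profile, assignment = res$assignment),
            class = "amp_contigs")
}

#' @export
print.amp_contigs <- function(x, ...) {
  cat(sprintf("amp_contigs: %d contigs (support %s)\n",
              length(x$consensus),
              paste(x$support, collapse = ",")))
  invisible(x)
}

#' Drop contigs with insufficient read support
#'
#' @param contigs An `amp_contigs` object.
#' @param min_reads Minimum supporting reads (default 3; contigs
#'   supported by fewer reads are discarded without further analysis).
#' @return Filtered `amp_contigs` (assignment entries for dropped contigs
#'   become `NA`).
#' @export
filter_support <- function(contigs, min_reads = 3L) {
  keep <- which(contigs$support >= min_reads)
  new_idx <- rep(NA_integer_, length(contigs$consensus))
  new_idx[keep] <- seq_along(keep)
  structure(list(consensus = contigs$consensus[keep],
                 support = contigs$support[keep],
                 profile = contigs$profile[keep],
                 assignment = new_idx[contigs$assignment]),
            class = "amp_contigs")
}

## semi-global re-mapping of reads onto contigs; returns per-contig
## allele count matrices (5 x L) and the per-read best contig.
map_reads <- function(reads, contigs) {
  if (inherits(reads, "qual_reads")) reads <- reads$seq
  counts <- lapply(contigs$consensus, function(cs)
    matrix(0L, 5L, nchar(cs),
           dimnames = list(c("A", "C", "G", "T", "N"), NULL)))
  best_contig <- rep(NA_integer_, length(reads))
  unmapped <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[i]
    best <- NULL; best_rate <- Inf; best_k <- NA_integer_
    for (k in seq_along(contigs$consensus)) {
      a <- cpp_fit_align(rd, contigs$consensus[[k]])
      rate <- a$edits / nchar(rd)
      if (rate < best_rate) { best_rate <- rate; best <- a; best_k <- k }
    }
    if (is.null(best) || best_rate > 0.2) { unmapped <- unmapped + 1L; next }
    best_contig[i] <- best_k
    cov <- seq_chars(best$cover)
    cols <- best$c_start:(best$c_start + length(cov) - 1L)
    keep <- cov != "-"
    rows <- match(cov[keep], c("A", "C", "G", "T"), nomatch = 5L)
    for (z in seq_along(rows))
      counts[[best_k]][rows[z], cols[keep][z]] <-
        counts[[best_k]][rows[z], cols[keep][z]] + 1L
  }
  list(counts = counts, best_contig = best_contig, unmapped = unmapped)
}

#' Re-map reads, measure polymorphism, re-assemble flagged contigs
#'
#' Each read is mapped semi-globally to its best contig; per-column
#' allele counts give the polymorphism rate (fraction of columns whose
#' minor-allele frequency is at least `polymorphism_floor`). Contigs at
#' or above `flag_rate` are re-assembled from their mapped reads with the
#' overlap identity raised to `stringent_identity`, and the variant
#' contigs replace the flagged contig.
#'
#' @param contigs An `amp_contigs` object (post support filtering).
#' @param reads Reads to re-map (`qual_reads` or character).
#' @param polymorphism_floor Minor-allele frequency making a column
#'   polymorphic (default 0.2).
#' @param flag_rate Polymorphism rate at which a contig is flagged
#'   (default 0.02).
#' @param stringent_identity Overlap identity for re-assembly
#'   (default 0.99).
#' @param min_overlap Minimum overlap for re-assembly (default 50).
#' @return List with `contigs` (an `amp_contigs`; flagged contigs
#'   replaced by their stringent variants), `polymorphism_rate` (per
#'   output contig), `flagged` (logical per output contig: came from a
#'   flagged parent), `unmapped` (count of reads mapping nowhere).
#' @export
remap_and_flag <- function(contigs, reads, polymorphism_floor = 0.2,
                           flag_rate = 0.02, stringent_identity = 0.99,
                           min_overlap = 50L) {
  if (inherits(reads, "qual_reads")) reads <- reads$seq
  if (length(contigs$consensus) == 0L)
    return(list(contigs = contigs, polymorphism_rate = numeric(),
                flagged = logical(), unmapped = length(reads)))
  mp <- map_reads(reads, contigs)
  poly_rate <- vapply(mp$counts, function(cm) {
    tot <- colSums(cm)
    covered <- tot > 0
    if (!any(covered)) return(0)
    minor <- tot[covered] - apply(cm[, covered, drop = FALSE], 2L, max)
    mean(minor / tot[covered] >= polymorphism_floor)
  }, 0)
  out_cons <- character(); out_sup <- integer(); out_prof <- list()
  out_rate <- numeric(); out_flag <- logical()
  for (k in seq_along(contigs$consensus)) {
    if (poly_rate[k] >= flag_rate) {
      sub <- reads[which(mp$best_contig == k)]
      re <- assemble_olc(sub, min_overlap = min_overlap,
                         min_overlap_identity = stringent_identity)
      for (v in seq_along(re$consensus)) {
        out_cons <- c(out_cons, re$consensus[[v]])
        out_sup <- c(out_sup, re$support[v])
        out_prof <- c(out_prof, re$profile[v])
        out_rate <- c(out_rate, NA_real_)
        out_flag <- c(out_flag, TRUE)
      }
    } else {
      out_cons <- c(out_cons, contigs$consensus[[k]])
      out_sup <- c(out_sup, contigs$support[k])
      out_prof <- c(out_prof, contigs$profile[k])
      out_rate <- c(out_rate, poly_rate[k])
      out_flag <- c(out_flag, FALSE)
    }
  }
  names(out_cons) <- paste0("contig", seq_along(out_cons))
  list(contigs = structure(list(consensus = out_cons, support = out_sup,
                                profile = out_prof,
                                assignment = rep(NA_integer_,
                                                 length(reads))),
                           class = "amp_contigs"),
       polymorphism_rate = out_rate, flagged = out_flag,
       unmapped = mp$unmapped)
}
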