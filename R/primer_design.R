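## Degenerate forward-primer design from alignments of signal-peptide
## (or, for Bombinatoridae-like precursors, propeptide) coding regions.

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -1);
#' identity = matches / alignment columns. Among optimal-score alignments
#' the one with the most matches (then fewest columns) defines the value,
#' so the result does not depend on traceback order.
#'
#' @param a,b Ungapped nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  cpp_nw_identity(norm_nuc(a), norm_nuc(b))$identity
}

#' Greedy longest-first identity clustering
#'
#' cd-hit-style greedy clustering: sequences are sorted by length
#' (descending, stable), and each joins the first existing cluster whose
#' representative it matches at `>= threshold` global identity, otherwise
#' founds a new cluster with itself as representative.
#'
#' @param seqs Named character vector of ungapped nucleotide sequences.
#' @param threshold Identity threshold in `(0, 1]` (default 0.8).
#' @return List of clusters; each a list with `representative` (name) and
#'   `members` (named character vector).
#' @export
cluster_by_identity <- function(seqs, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0L) return(list())
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- norm_nuc(seqs)
  ord <- order(-nchar(seqs))
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_seq <- clusters[[k]]$rep_seq
      if (global_identity(rep_seq, seqs[i]) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, seqs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = names(seqs)[i], rep_seq = unname(seqs[i]),
        members = seqs[i])
    }
  }
  lapply(clusters, function(cl)
    list(representative = cl$representative, members = cl$members))
}

#' Scan an alignment for conserved primer windows
#'
#' Slides a window of `window_len` columns across a gapped nucleotide
#' alignment and reports every gap-free window containing at most
#' `max_polymorphic` polymorphic columns. A column is polymorphic iff at
#' least two distinct bases each occur at frequency strictly greater than
#' `minor_freq_floor` (default 0: any second observed base counts).
#'
#' @param aln Named character vector: gapped sequences of equal length.
#' @param window_len Window length in columns (default 20).
#' @param max_polymorphic Maximum polymorphic columns allowed (default 3).
#' @param minor_freq_floor Frequency floor below which a minor base is
#'   ignored (default 0).
#' @return data.frame with columns `start` (0-based), `length`,
#'   `n_polymorphic`, `polymorphic_columns` (comma-separated 0-based
#'   indices), `consensus` (degenerate sequence), `degeneracy`.
#' @export
scan_windows <- function(aln, window_len = 20L, max_polymorphic = 3L,
                         minor_freq_floor = 0) {
  stopifnot(length(aln) >= 2L)
  aln <- norm_nuc(aln, allow_gap = TRUE)
  W <- unique(nchar(aln))
  if (length(W) != 1L) stop("alignment members must have equal length")
  empty <- data.frame(start = integer(), length = integer(),
                      n_polymorphic = integer(),
                      polymorphic_columns = character(),
                      consensus = character(), degeneracy = integer(),
                      stringsAsFactors = FALSE)
  if (W < window_len) return(empty)
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  col_info <- lapply(seq_len(W), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return(list(gap = TRUE))
    freq <- table(col) / length(col)
    obs <- names(freq)[freq > minor_freq_floor]
    if (length(obs) == 0L) obs <- names(freq)[which.max(freq)]
    list(gap = FALSE, bases = sort(obs), poly = length(obs) >= 2L)
  })
  gap_col <- vapply(col_info, `[[`, TRUE, "gap")
  poly_col <- vapply(col_info, function(ci)
    if (ci$gap) NA else ci$poly, TRUE)
  out <- list()
  for (s in seq_len(W - window_len + 1L)) {
    idx <- s:(s + window_len - 1L)
    if (any(gap_col[idx])) next
    npoly <- sum(poly_col[idx])
    if (npoly > max_polymorphic) next
    cons <- make_degenerate(lapply(col_info[idx], `[[`, "bases"))
    out[[length(out) + 1L]] <- data.frame(
      start = s - 1L, length = window_len, n_polymorphic = npoly,
      polymorphic_columns = paste(idx[poly_col[idx]] - 1L, collapse = ","),
      consensus = cons, degeneracy = degeneracy(cons),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Collapse per-column base sets to a degenerate consensus
#'
#' Each column maps to the minimal IUPAC code covering its observed
#' bases. A column containing `N` (or all four bases) becomes `N` with a
#' warning.
#'
#' @param columns List of character vectors, one set of observed bases
#'   per column (no gaps).
#' @return Degenerate nucleotide string.
#' @export
make_degenerate <- function(columns) {
  codes <- vapply(columns, function(bs) {
    bs <- unique(toupper(bs))
    if (any(bs == "-")) stop("gap character in consensus column")
    if (any(bs == "N") || length(setdiff(c("A", "C", "G", "T"), bs)) == 0L) {
      if (any(bs == "N"))
        warning("column contains N; consensus emits N")
      return("N")
    }
    expanded <- sort(unique(unlist(IUPAC_MAP[bs])))
    code <- IUPAC_REVERSE[[paste(expanded, collapse = "")]]
    if (is.null(code)) stop("cannot encode base set: ",
                            paste(bs, collapse = ","))
    code
  }, "")
  paste(codes, collapse = "")
}

#' Attach a 5' tail to a gene-specific degenerate primer part
#'
#' @param specific Degenerate gene-specific 3' part.
#' @param tail Fixed 5' tail sequence.
#' @param name Primer name.
#' @return A `degenerate_primer` object: list with `name`, `specific_part`,
#'   `tail`, `full_sequence` (tail followed by specific part) and
#'   `degeneracy`.
#' @examples
#' p <- attach_tail("ATGTTCACCTTGAAGRAATC", "CAGGACCAGGGTACGGTG", "TP1")
#' p$full_sequence
#' @export
attach_tail <- function(specific, tail, name = "primer") {
  stopifnot(nchar(specific) > 0L, nchar(tail) > 0L)
  specific <- norm_nuc(specific)
  tail <- norm_nuc(tail)
  structure(list(name = name, specific_part = specific, tail = tail,
                 full_sequence = paste0(tail, specific),
                 degeneracy = degeneracy(specific)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("degenerate_primer %s: %s + %s (degeneracy %d)\n",
              x$name, x$tail, x$specific_part, x$degeneracy))
  invisible(x)
}

#' Select the primer window from a set of conserved windows
#'
#' `signal_any` mode picks the window with the fewest polymorphic
#' columns, ties to the leftmost; `propeptide_3prime` mode picks the
#' window with the largest start coordinate among those within the
#' degeneracy budget (used when the amplicon must be kept short by
#' priming as close as possible to the 3' end of the propeptide-coding
#' region).
#'
#' @param windows data.frame from [scan_windows()].
#' @param mode `"signal_any"` or `"propeptide_3prime"`.
#' @param max_degeneracy Degeneracy budget for `propeptide_3prime`.
#' @return One-row data.frame (the chosen window).
#' @export
pick_primer_position <- function(windows, mode = c("signal_any",
                                                   "propeptide_3prime"),
                                 max_degeneracy = Inf) {
  mode <- match.arg(mode)
  if (is.null(windows) || nrow(windows) == 0L)
    stop("primer design failure: no conserved window available")
  if (mode == "signal_any") {
    ord <- order(windows$n_polymorphic, windows$start)
  } else {
    ok <- windows$degeneracy <= max_degeneracy
    if (!any(ok)) stop("primer design failure: no window within the ",
                       "degeneracy budget")
    windows <- windows[ok, , drop = FALSE]
    ord <- order(-windows$start)
  }
  windows[ord[1L], , drop = FALSE]
}

#' Design a degenerate forward primer from a region alignment
#'
#' Convenience wrapper: scan conserved windows, pick a window position,
#' and attach the 5' tail.
#'
#' @param aln Gapped nucleotide alignment (named character vector).
#' @param mode Window-positioning mode, see [pick_primer_position()].
#' @param tail 5' tail sequence.
#' @param name Primer name.
#' @inheritParams scan_windows
#' @param max_degeneracy Degeneracy budget in `propeptide_3prime` mode.
#' @return A `degenerate_primer` with an extra `window` element.
#' @export
design_primer <- function(aln, mode = "signal_any",
                          tail = "CAGGACCAGGGTACGGTG", name = "primer",
                          window_len = 20L, max_polymorphic = 3L,
                          minor_freq_floor = 0, max_degeneracy = Inf) {
  win <- scan_windows(aln, window_len, max_polymorphic, minor_freq_floor)
  sel <- pick_primer_position(win, mode, max_degeneracy)
  p <- attach_tail(sel$consensus, tail, name)
  p$window <- sel
  p
}

#' Predict amplicons for a primer panel against poly-A templates
#'
#' The forward binding site on each template is the best IUPAC-aware
#' ungapped match of the primer's gene-specific part (fewest mismatching
#' positions, ties to the leftmost site), accepted when mismatches do not
#' exceed `max_mismatches`. The predicted product length is the distance
#' from the binding-site start to the template 3' end plus both tail
#' lengths; products longer than `platform_max` are flagged as exceeding
#' the sequencing platform limit.
#'
#' @param templates Named character vector of transcripts oriented 5'->3'
#'   and ending in a poly-A tail.
#' @param panel List of `degenerate_primer` objects.
#' @param max_mismatches Maximum IUPAC-aware mismatches (default 2).
#' @param platform_max Platform read-length limit in nt (default 450).
#' @param rev_tail Reverse-primer tail sequence whose length is added to
#'   the product (default the trP1 adapter).
#' @return data.frame with one row per binding (template, primer) pair:
#'   `template_id`, `primer`, `forward_site` (0-based), `mismatches`,
#'   `product_length`, `exceeds_platform_limit`. Templates with no
#'   binding primer are omitted and reported via a message.
#' @export
predict_amplicons <- function(templates, panel, max_mismatches = 2L,
                              platform_max = 450L,
                              rev_tail = "CCTCTCTATGGGCAGTCGGTGAT") {
  if (inherits(panel, "degenerate_primer")) panel <- list(panel)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  mm_tab <- !iupac_match_matrix()
  rows <- list()
  for (tid in names(templates)) {
    tmpl <- norm_nuc(templates[[tid]])
    tvec <- seq_chars(tmpl)
    bound <- FALSE
    for (p in panel) {
      pvec <- seq_chars(p$specific_part)
      k <- length(pvec)
      L <- length(tvec)
      if (L < k) next
      n_off <- L - k + 1L
      mm <- vapply(seq_len(n_off), function(s) {
        sum(mm_tab[cbind(pvec, tvec[s:(s + k - 1L)])])
      }, 0)
      best <- which.min(mm)
      if (mm[best] > max_mismatches) next
      site <- best - 1L
      prod_len <- (L - site) + nchar(p$tail) + nchar(rev_tail)
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = tid, primer = p$name, forward_site = site,
        mismatches = mm[best], product_length = prod_len,
        exceeds_platform_limit = prod_len > platform_max,
        stringsAsFactors = FALSE)
      bound <- TRUE
    }
    if (!bound)
      message("predict_amplicons: no primer binds template '", tid,
              "' within ", max_mismatches, " mismatches; omitted")
  }
  if (length(rows) == 0L)
    return(data.frame(template_id = character(), primer = character(),
                      forward_site = integer(), mismatches = integer(),
                      product_length = integer(),
                      exceeds_platform_limit = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a primer panel to FASTA and TSV report
#'
#' @param panel List of `degenerate_primer` objects.
#' @param fasta_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report data.frame.
#' @export
write_primer_report <- function(panel, fasta_path = NULL, tsv_path = NULL) {
  if (inherits(panel, "degenerate_primer")) panel <- list(panel)
  rep <- do.call(rbind, lapply(panel, function(p) data.frame(
    name = p$name, specific_part = p$specific_part, tail = p$tail,
    full_sequence = p$full_sequence, degeneracy = p$degeneracy,
    window_start = if (!is.null(p$window)) p$window$start else NA_integer_,
    stringsAsFactors = FALSE)))
  if (!is.null(fasta_path))
    write_fasta(setNames(rep$full_sequence, rep$name), fasta_path)
  if (!is.null(tsv_path))
    write.table(rep, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
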