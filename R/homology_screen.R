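## AMP-likeness screens: a position-specific profile scan of translated
## sequences against a signal-peptide protein alignment (transparent
## stand-in for an HMM search) and a translated Smith-Waterman search
## against a custom known-AMP database (stand-in for BLASTx), both gated
## at significance 0.05.

## Gapped Karlin-Altschul constants published for BLOSUM62 with gap
## open 11 / extend 1 (the BLAST defaults); used when the matrix-derived
## ungapped lambda is not requested.
KA_GAPPED <- list(lambda = 0.267, K = 0.041)

#' Ungapped Karlin-Altschul lambda for a scoring matrix
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` by root finding, with
#' uniform background composition by default. The expected pairwise score
#' must be negative for a solution to exist.
#'
#' @param sm Substitution matrix (square, dimnames = residues).
#' @param p Background composition (named, defaults to uniform over the
#'   matrix alphabet restricted to the 20 standard residues).
#' @return Lambda (nats per score unit).
#' @export
karlin_lambda <- function(sm, p = NULL) {
  res <- intersect(rownames(sm), AA_LETTERS)
  sm <- sm[res, res]
  if (is.null(p)) p <- setNames(rep(1 / length(res), length(res)), res)
  p <- p[res] / sum(p[res])
  f <- function(lam) sum(outer(p, p) * exp(lam * sm)) - 1
  if (sum(outer(p, p) * sm) >= 0)
    stop("expected score must be negative for Karlin-Altschul statistics")
  uniroot(f, c(1e-6, 10), tol = 1e-9)$root
}

#' Build a position-specific profile from a protein alignment
#'
#' Columns with more than 50% gaps are dropped; per-column residue
#' frequencies receive an additive pseudocount spread over the background
#' composition, and log-odds (base 2) against that background are stored.
#'
#' @param aln Named character vector: gapped protein sequences of equal
#'   length (>= 2).
#' @param pseudocount Total pseudocount weight per column (default 1).
#' @param background Named composition vector (default uniform).
#' @param id Profile identifier.
#' @return An `amp_profile`: list with `probs` and `logodds` (20 x W
#'   matrices), `background`, `pseudocount`, `id`, `width`.
#' @export
build_profile <- function(aln, pseudocount = 1, background = NULL,
                          id = "profile") {
  if (length(aln) < 2L) stop("profile requires >= 2 aligned sequences")
  aln <- norm_pep(aln, allow_gap = TRUE)
  W <- unique(nchar(aln))
  if (length(W) != 1L) stop("alignment members must have equal length")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_LETTERS)
  background <- background[AA_LETTERS] / sum(background[AA_LETTERS])
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  keep <- colMeans(mat == "-") <= 0.5
  mat <- mat[, keep, drop = FALSE]
  probs <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA_LETTERS))
    p <- (as.numeric(cnt) + pseudocount * background) /
      (length(col) + pseudocount)
    p / sum(p)
  })
  rownames(probs) <- AA_LETTERS
  logodds <- log2(probs / background)
  structure(list(probs = probs, logodds = logodds,
                 background = background, pseudocount = pseudocount,
                 id = id, width = ncol(probs)),
            class = "amp_profile")
}

#' @export
print.amp_profile <- function(x, ...) {
  cat(sprintf("amp_profile '%s': %d columns, pseudocount %g\n",
              x$id, x$width, x$pseudocount))
  invisible(x)
}

## Best-window log-odds score of a peptide against a profile. When the
## peptide is shorter than the profile, the profile slides over the
## peptide instead (scoring a contiguous block of profile columns).
profile_best_score <- function(profile, residues) {
  lo <- profile$logodds
  W <- ncol(lo)
  n <- length(residues)
  idx <- match(residues, AA_LETTERS)
  if (anyNA(idx)) {
    keepable <- !is.na(idx)
    ## unknown residues (X) contribute the worst column score
    pen <- apply(lo, 2L, min)
  }
  if (n >= W) {
    scores <- vapply(0:(n - W), function(off) {
      cols <- seq_len(W)
      ii <- idx[off + cols]
      s <- ifelse(is.na(ii), apply(lo, 2L, min)[cols],
                  lo[cbind(ii, cols)])
      sum(s)
    }, 0)
  } else {
    scores <- vapply(0:(W - n), function(off) {
      cols <- off + seq_len(n)
      s <- ifelse(is.na(idx), apply(lo, 2L, min)[cols],
                  lo[cbind(idx, cols)])
      sum(s)
    }, 0)
  }
  max(scores)
}

#' Profile scan with empirical shuffle significance
#'
#' Scores each peptide's best window against the profile and estimates
#' significance as the fraction of `n_shuffles` residue-shuffled versions
#' scoring at least as high; peptides with significance below `alpha` are
#' reported.
#'
#' @param profile An `amp_profile`.
#' @param peptides Named character vector of peptides (six-frame
#'   translations are fine; internal `*` segments are scored as-is after
#'   stop removal, `X` scores as the worst column residue).
#' @param n_shuffles Number of shuffles (>= 20; default 100).
#' @param alpha Significance cutoff (default 0.05).
#' @return data.frame of retained hits: `query`, `subject` (profile id),
#'   `score` (bits), `pvalue`.
#' @export
profile_scan <- function(profile, peptides, n_shuffles = 100L,
                         alpha = 0.05) {
  stopifnot(inherits(profile, "amp_profile"))
  if (n_shuffles < 20L)
    stop("n_shuffles must be >= 20 for alpha = 0.05 resolution")
  if (is.null(names(peptides)))
    names(peptides) <- paste0("pep", seq_along(peptides))
  rows <- list()
  for (qid in names(peptides)) {
    res <- seq_chars(gsub("\\*", "", toupper(peptides[[qid]])))
    if (length(res) == 0L) next
    obs <- profile_best_score(profile, res)
    shuf <- vapply(seq_len(n_shuffles), function(k)
      profile_best_score(profile, sample(res)), 0)
    p <- mean(shuf >= obs)
    if (p < alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        query = qid, subject = profile$id, score = obs, pvalue = p,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## substitution matrix fetch (Biostrings ships BLOSUM/PAM matrices)
get_submat <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

## Smith-Waterman wrapper over the C++ kernel; sequences as residue
## strings, matrix rows/cols named by residues (plus '*' etc.).
sw_align <- function(query, subject, sm, gap_open = 11, gap_extend = 1) {
  alpha <- rownames(sm)
  qi <- match(seq_chars(query), alpha)
  si <- match(seq_chars(subject), alpha)
  if (anyNA(qi) || anyNA(si)) {
    qi[is.na(qi)] <- match("*", alpha)
    si[is.na(si)] <- match("*", alpha)
  }
  cpp_sw_affine(qi, si, sm, gap_open, gap_extend)
}

make_hit <- function(query, subject, a, m, n, lambda, K, qlen) {
  bits <- (lambda * a$score - log(K)) / log(2)
  evalue <- K * m * n * exp(-lambda * a$score)
  data.frame(
    query = query, subject = subject,
    identity = if (a$aln_len > 0) 100 * a$matches / a$aln_len else 0,
    aln_len = a$aln_len, mismatches = a$mismatches, gaps = a$gaps,
    q_start = a$q_start, q_end = a$q_end,
    s_start = a$s_start, s_end = a$s_end,
    evalue = evalue, bitscore = bits,
    coverage = if (!is.na(a$q_start)) 100 * (a$q_end - a$q_start + 1) / qlen
               else 0,
    stringsAsFactors = FALSE)
}

#' Protein-vs-protein local search against a peptide database
#'
#' Smith-Waterman with affine gaps against every database entry;
#' E-values via the Karlin-Altschul approximation
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the total database residue count.
#'
#' @param queries Named character vector of peptides.
#' @param db Named character vector of database peptides.
#' @param matrix Substitution matrix name (Biostrings) or matrix
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11, 1; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @param alpha E-value cutoff (default 0.05). `NULL` disables gating.
#' @param best_only Report only the best hit per query (lowest E-value,
#'   ties by higher identity then database order)?
#' @param lambda,K Karlin-Altschul parameters (defaults: published gapped
#'   BLOSUM62-11/1 constants).
#' @return data.frame of hits (12-column tabular report plus coverage).
#' @export
protein_search <- function(queries, db, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1, alpha = 0.05,
                           best_only = TRUE,
                           lambda = KA_GAPPED$lambda, K = KA_GAPPED$K) {
  stopifnot(length(db) > 0L)
  sm <- get_submat(matrix)
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  if (is.null(names(db))) names(db) <- paste0("db", seq_along(db))
  n_db <- sum(nchar(db))
  out <- list()
  for (qid in names(queries)) {
    q <- sub("\\*$", "", toupper(queries[[qid]]))
    if (nchar(q) == 0L) next
    hits <- lapply(names(db), function(sid)
      make_hit(qid, sid, sw_align(q, db[[sid]], sm, gap_open, gap_extend),
               m = nchar(q), n = n_db, lambda, K, qlen = nchar(q)))
    hits <- do.call(rbind, hits)
    if (!is.null(alpha)) hits <- hits[hits$evalue < alpha, , drop = FALSE]
    if (nrow(hits) == 0L) next
    if (best_only) {
      ord <- order(hits$evalue, -hits$identity)
      hits <- hits[ord[1L], , drop = FALSE]
    }
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(),
             identity = numeric(), aln_len = integer(),
             mismatches = integer(), gaps = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), evalue = numeric(), bitscore = numeric(),
             coverage = numeric(), stringsAsFactors = FALSE)
}

#' Translated search of nucleotide contigs against a peptide database
#'
#' Each contig is translated in all six frames; frame translations are
#' split at stop codons and every segment of at least `min_segment`
#' residues is searched with [protein_search()] machinery. The best hit
#' per contig (lowest E-value, ties by higher identity then database
#' order) is reported when it passes the E-value cutoff.
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @param db Named character vector of database peptides.
#' @inheritParams protein_search
#' @param min_segment Minimum translated segment length (default 5).
#' @return data.frame of best hits per contig, with `frame` column.
#' @export
translated_search <- function(contigs, db, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1, alpha = 0.05,
                              min_segment = 5L,
                              lambda = KA_GAPPED$lambda, K = KA_GAPPED$K) {
  stopifnot(length(db) > 0L)
  sm <- get_submat(matrix)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  if (is.null(names(db))) names(db) <- paste0("db", seq_along(db))
  n_db <- sum(nchar(db))
  out <- list()
  for (cid in names(contigs)) {
    if (nchar(contigs[[cid]]) < 3L) {
      message("translated_search: contig '", cid,
              "' shorter than one codon; skipped")
      next
    }
    frames <- translate_six_frames(contigs[[cid]])
    hits <- list()
    all_segs <- lapply(frames, function(f) {
      sg <- strsplit(f, "*", fixed = TRUE)[[1L]]
      sg[nchar(sg) >= min_segment]
    })
    ## E-values use the whole translated query as the effective search
    ## space (all frames, all segments), so the best-of-many selection
    ## across frames stays calibrated
    m_tot <- sum(nchar(unlist(all_segs)))
    for (fr in names(frames)) {
      for (seg in all_segs[[fr]]) {
        for (sid in names(db)) {
          a <- sw_align(seg, db[[sid]], sm, gap_open, gap_extend)
          h <- make_hit(cid, sid, a, m = m_tot, n = n_db,
                        lambda, K, qlen = nchar(seg))
          h$frame <- fr
          hits[[length(hits) + 1L]] <- h
        }
      }
    }
    if (length(hits) == 0L) next
    hits <- do.call(rbind, hits)
    ord <- order(hits$evalue, -hits$identity)
    best <- hits[ord[1L], , drop = FALSE]
    if (!is.null(alpha) && best$evalue >= alpha) next
    out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0L) {
    e <- empty_hits(); e$frame <- character(); return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write hits as a 12-column tab-separated report
#'
#' Columns: query, subject, identity, alignment length, mismatches,
#' gaps, q.start, q.end, s.start, s.end, E-value, bit score.
#'
#' @param hits data.frame from a search function.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("query", "subject", "identity", "aln_len", "mismatches",
            "gaps", "q_start", "q_end", "s_start", "s_end", "evalue",
            "bitscore")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
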