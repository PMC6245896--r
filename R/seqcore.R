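#' @useDynLib anuramp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames uniroot
#' @importFrom utils head tail write.table read.table
NULL

## IUPAC nucleotide ambiguity codes. Concrete bases expand to themselves;
## the 11 degenerate codes cover every non-empty subset of {A,C,G,T} of
## size >= 2 (plus N).
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## reverse lookup: sorted concatenation of a base set -> minimal code
IUPAC_REVERSE <- local({
  keys <- vapply(IUPAC_MAP, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_MAP), keys)
})

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Expand an IUPAC nucleotide symbol to its concrete bases
#'
#' @param code A single IUPAC nucleotide character (case-insensitive).
#' @return Character vector of concrete bases in `{A,C,G,T}`.
#' @examples
#' iupac_expand("R")  # A G
#' @export
iupac_expand <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  out <- IUPAC_MAP[[code]]
  if (is.null(out)) stop("unknown IUPAC symbol: '", code, "'")
  out
}

#' Test whether two IUPAC symbols can pair
#'
#' Two symbols match iff their concrete expansions intersect; the relation
#' is symmetric. Used for primer-template pairing.
#'
#' @param a,b Single IUPAC characters.
#' @return Logical scalar.
#' @export
iupac_match <- function(a, b) {
  length(intersect(iupac_expand(a), iupac_expand(b))) > 0L
}

## 15x15 logical match table, rows/cols in names(IUPAC_MAP) order;
## used for vectorised primer scans.
iupac_match_matrix <- function() {
  syms <- names(IUPAC_MAP)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(syms, syms))
  for (a in syms) for (b in syms)
    m[a, b] <- length(intersect(IUPAC_MAP[[a]], IUPAC_MAP[[b]])) > 0L
  m
}

#' Degeneracy of a (possibly degenerate) nucleotide sequence
#'
#' Product of the per-position IUPAC expansion sizes, i.e. the number of
#' concrete sequences a degenerate oligo encodes.
#'
#' @param seq A nucleotide string.
#' @return Integer >= 1.
#' @examples
#' degeneracy("ATGTTCACCWTGARKAAAYC")  # 16
#' @export
degeneracy <- function(seq) {
  chars <- seq_chars(seq)
  prod(vapply(chars, function(ch) length(iupac_expand(ch)), 1L))
}

## -- basic string helpers ----------------------------------------------

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Normalize and validate a nucleotide string
#'
#' Upper-cases the input and checks the alphabet (`A,C,G,T,N` plus the
#' IUPAC degenerate codes; `-` allowed when `allow_gap = TRUE`).
#'
#' @param x Character vector of sequences.
#' @param allow_gap Accept `-` (alignment gap)?
#' @return Normalized character vector.
#' @export
norm_nuc <- function(x, allow_gap = FALSE) {
  x <- toupper(x)
  ok <- paste0(c(names(IUPAC_MAP), if (allow_gap) "-"), collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), x)
  if (any(bad)) stop("invalid nucleotide characters in: ",
                     paste(head(x[bad], 3), collapse = ", "))
  x
}

#' Normalize and validate a peptide string
#'
#' @param x Character vector of peptide sequences (20 standard residues;
#'   `*` allowed only as a trailing stop, `-` when `allow_gap = TRUE`).
#' @param allow_gap Accept `-`?
#' @return Normalized character vector.
#' @export
norm_pep <- function(x, allow_gap = FALSE) {
  x <- toupper(x)
  body <- sub("\\*$", "", x)
  ok <- paste0(c(AA_LETTERS, if (allow_gap) "-"), collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), body)
  if (any(bad)) stop("invalid peptide characters in: ",
                     paste(head(x[bad], 3), collapse = ", "))
  x
}

#' Reverse complement (IUPAC-aware)
#'
#' An involution: `revcomp(revcomp(x)) == x` for every IUPAC string.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) paste(rev(seq_chars(s)), collapse = ""), "",
         USE.NAMES = FALSE)
}

## -- translation --------------------------------------------------------

codon_table <- function() {
  ## standard genetic code as a named vector keyed by concrete codon
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}
.CODON <- NULL
get_codon_table <- function() {
  if (is.null(.CODON)) utils::assignInMyNamespace(".CODON", codon_table())
  .CODON
}

translate_codon <- function(codon) {
  tab <- get_codon_table()
  aa <- tab[codon]
  if (!is.na(aa)) return(unname(aa))
  ## degenerate codon: translate to X unless all expansions agree
  sets <- lapply(seq_chars(codon), iupac_expand)
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(tab[apply(combos, 1L, paste, collapse = "")])
  if (length(aas) == 1L && !is.na(aas)) unname(aas) else "X"
}

#' Translate a nucleotide sequence in one frame
#'
#' Standard genetic code; trailing partial codons are dropped; stops are
#' rendered as `*`. Degenerate codons translate to `X` unless every
#' concrete expansion yields the same residue.
#'
#' @param seq Nucleotide string.
#' @param frame Integer in `c(1,2,3,-1,-2,-3)`; negative frames read the
#'   reverse complement.
#' @return Peptide string.
#' @export
translate_seq <- function(seq, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  s <- norm_nuc(seq)
  if (frame < 0L) s <- revcomp(s)
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  ncod <- n %/% 3L
  if (ncod <= 0L) return("")
  starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  if (all(codons %in% names(get_codon_table()))) {
    paste(get_codon_table()[codons], collapse = "")
  } else {
    paste(vapply(codons, translate_codon, ""), collapse = "")
  }
}

#' Translate a sequence in all six reading frames
#'
#' @param seq Nucleotide string of length >= 3.
#' @return Named character vector of 6 peptides, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
translate_six_frames <- function(seq) {
  stopifnot(nchar(seq) >= 3L)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  setNames(vapply(frames, function(f) translate_seq(seq, f), ""),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

## -- ORF finding --------------------------------------------------------

#' Enumerate open reading frames in all six frames
#'
#' An ORF runs from a start (ATG when `require_start = TRUE`, otherwise
#' from the frame start or the codon after the previous stop) to the next
#' in-frame stop, or to the end of the readable frame when no stop occurs
#' (incomplete ORF). Coordinates are 0-based half-open on the forward
#' strand; the protein excludes the stop.
#'
#' @param seq Nucleotide string, length >= 3.
#' @param require_start Must the ORF begin with Met?
#' @param min_aa Minimum protein length (residues) to report.
#' @return data.frame with columns `frame`, `nt_start`, `nt_end`,
#'   `protein`, `has_stop`.
#' @export
find_orfs <- function(seq, require_start = TRUE, min_aa = 1L) {
  s <- norm_nuc(seq)
  L <- nchar(s)
  res <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_seq(s, frame)
    if (nchar(pep) == 0L) next
    aa <- seq_chars(pep)
    off <- abs(frame) - 1L
    ## candidate ORF start codon indices (1-based in codon space)
    stops <- which(aa == "*")
    bounds <- c(0L, stops, length(aa) + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k] + 1L
      hi <- bounds[k + 1L] - 1L
      if (hi < lo) next
      seg <- aa[lo:hi]
      starts_in_seg <- if (require_start) which(seg == "M") else 1L
      if (length(starts_in_seg) == 0L) next
      st <- lo + starts_in_seg[1L] - 1L   # longest ORF in segment
      has_stop <- bounds[k + 1L] <= length(aa)
      prot <- paste(aa[st:hi], collapse = "")
      if (nchar(prot) < min_aa) next
      cs <- off + 3L * (st - 1L)              # codon-space nt start
      ce <- off + 3L * (hi + has_stop)        # nt end (incl stop codon)
      if (frame > 0L) {
        nt_start <- cs; nt_end <- ce
      } else {
        nt_start <- L - ce; nt_end <- L - cs
      }
      res[[length(res) + 1L]] <- data.frame(
        frame = frame, nt_start = nt_start, nt_end = nt_end,
        protein = prot, has_stop = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), protein = character(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Longest open reading frame over all six frames
#'
#' Ties are broken by frame order `+1,+2,+3,-1,-2,-3`, then by the
#' leftmost start within the frame's scanning direction.
#'
#' @inheritParams find_orfs
#' @return One-row data.frame as in [find_orfs()], or `NULL` when no ORF
#'   of at least `min_aa` residues exists.
#' @export
longest_orf <- function(seq, require_start = TRUE, min_aa = 1L) {
  orfs <- find_orfs(seq, require_start = require_start, min_aa = min_aa)
  if (nrow(orfs) == 0L) return(NULL)
  len <- nchar(orfs$protein)
  frame_rank <- match(orfs$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  scan_pos <- ifelse(orfs$frame > 0L, orfs$nt_start, -orfs$nt_end)
  ord <- order(-len, frame_rank, scan_pos)
  orfs[ord[1L], , drop = FALSE]
}

## -- FASTA / FASTQ I/O (Biostrings-backed) ------------------------------

#' Read a (possibly gapped) FASTA file
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read FASTQ (Sanger Phred+33) into a qual_reads object
#'
#' @param path File path.
#' @return An object of class `qual_reads`: list with `id` (character),
#'   `seq` (character) and `qual` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  ## the internal XStringSet coercion warns about dropped metadata
  ## columns; nothing user-visible is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- as(Biostrings::quality(x), "IntegerList")
  qual_reads(id = names(x), seq = unname(as.character(x)),
             qual = lapply(seq_along(qual), function(i) as.integer(qual[[i]])))
}

#' Construct a qual_reads object
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of bases over `{A,C,G,T,N}`.
#' @param qual List of integer Phred score vectors, one per read, each the
#'   same length as its read.
#' @return A `qual_reads` object.
#' @export
qual_reads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq) > 0) {
    stopifnot(all(nchar(seq) == lengths(qual)))
  }
  structure(list(id = as.character(id), seq = toupper(seq),
                 qual = lapply(qual, as.integer)),
            class = "qual_reads")
}

#' @export
length.qual_reads <- function(x) length(x$id)

#' @export
print.qual_reads <- function(x, ...) {
  cat("qual_reads with", length(x), "reads\n")
  invisible(x)
}

#' Subset a qual_reads object
#' @param x A `qual_reads` object.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.qual_reads` <- function(x, i, ...) {
  qual_reads(x$id[i], x$seq[i], x$qual[i])
}

#' Write a qual_reads object to FASTQ (Phred+33)
#'
#' @param reads A `qual_reads` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "qual_reads"))
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  q <- Biostrings::PhredQuality(methods::as(reads$qual, "IntegerList"))
  ## writeXStringSet warns that quality metadata columns are dropped
  ## from the object; the qualities are still written to the file
  withCallingHandlers(
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = q),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}
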