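## Physicochemical descriptors of mature peptides: net formal charge,
## mean per-residue hydrophobicity, and average molecular weight with an
## amidation correction.

#' Packaged hydrophobicity scales
#'
#' `ccs`: consensus hydrophobicity scale normalized to the interval
#' [-10, +10] (Phe most hydrophobic at +10.0, Arg least at -10.0), the
#' default for reporting mean peptide hydrophobicity. `kyte_doolittle`:
#' the classic KD scale, shipped as an alternative.
#'
#' @format A named list of two named numeric vectors (20 residues each).
#' @export
hydro_scales <- list(
  ccs = c(A = -1.1, C = -2.3, D = -8.3, E = -8.3, F = 10.0, G = -2.4,
          H = -3.8, I = 8.7, K = -9.9, L = 9.7, M = 4.6, N = -7.1,
          P = -0.2, Q = -6.0, R = -10.0, S = -4.3, T = -3.8, V = 4.1,
          W = 9.7, Y = 2.5),
  kyte_doolittle = c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                     G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                     M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                     S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
)

## Average (isotope-abundance-weighted) residue masses, Da.
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153
AMIDE_DELTA <- -0.9848  # OH -> NH2 at the C terminus

pep_counts <- function(peptide) {
  p <- sub("\\*$", "", norm_pep(peptide))
  if (nchar(p) == 0L) stop("empty peptide")
  table(factor(seq_chars(p), levels = AA_LETTERS))
}

#' Net formal charge of a peptide
#'
#' Counting convention: `(#Lys + #Arg) - (#Asp + #Glu) + 1` for the free
#' N-terminal amine; His, Cys and the C-terminus contribute nothing.
#' This is the convention under which the reported charges of anuran
#' mature peptides are reproduced exactly; a pH-7 Henderson-Hasselbalch
#' estimate is available via `convention = "hh_ph7"`.
#'
#' @param peptide Peptide string.
#' @param convention `"formal"` (default, integer) or `"hh_ph7"`.
#' @return Net charge (integer for `"formal"`).
#' @examples
#' net_charge("FLGALGNALSRVLGK")  # +3
#' @export
net_charge <- function(peptide, convention = c("formal", "hh_ph7")) {
  convention <- match.arg(convention)
  ct <- pep_counts(peptide)
  if (convention == "formal") {
    as.integer(ct[["K"]] + ct[["R"]] - ct[["D"]] - ct[["E"]] + 1L)
  } else {
    ph <- 7
    pos <- function(pka) 1 / (1 + 10^(ph - pka))
    neg <- function(pka) -1 / (1 + 10^(pka - ph))
    pos(9.0) +                                  # N terminus
      ct[["K"]] * pos(10.5) + ct[["R"]] * pos(12.5) +
      ct[["H"]] * pos(6.0) +
      ct[["D"]] * neg(3.9) + ct[["E"]] * neg(4.1) +
      ct[["C"]] * neg(8.3) + ct[["Y"]] * neg(10.1) +
      neg(3.1)                                  # C terminus
  }
}

#' Mean per-residue hydrophobicity
#'
#' Arithmetic mean of the scale values over the peptide's residues.
#'
#' @param peptide Peptide string.
#' @param scale Named numeric vector covering all residues present
#'   (default the packaged consensus scale, [hydro_scales]`$ccs`).
#' @return Mean hydrophobicity (scale-dependent units).
#' @export
mean_hydrophobicity <- function(peptide, scale = hydro_scales$ccs) {
  p <- sub("\\*$", "", norm_pep(peptide))
  res <- seq_chars(p)
  if (!all(res %in% names(scale)))
    stop("residues missing from hydrophobicity scale: ",
         paste(setdiff(res, names(scale)), collapse = ","))
  mean(scale[res])
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (18.015 Da); C-terminally
#' amidated peptides subtract 0.985 Da (OH -> NH2).
#'
#' @param peptide Peptide string.
#' @param amidated C-terminal amide?
#' @return Mass in Da.
#' @examples
#' molecular_weight("LVPFIGRTLGGLLARF", amidated = TRUE)  # 1729.1
#' @export
molecular_weight <- function(peptide, amidated = FALSE) {
  ct <- pep_counts(peptide)
  sum(AA_AVG_MASS[names(ct)] * as.integer(ct)) + WATER_MASS +
    if (amidated) AMIDE_DELTA else 0
}

#' Bundle the physicochemical descriptors of a peptide
#'
#' @param peptide Peptide string.
#' @param amidated C-terminal amide?
#' @param scale Hydrophobicity scale.
#' @return A `physchem_profile` (one-row data.frame): `length`,
#'   `net_charge`, `mean_hydrophobicity`, `molecular_weight`, `amidated`.
#' @export
profile_peptide <- function(peptide, amidated = FALSE,
                            scale = hydro_scales$ccs) {
  p <- sub("\\*$", "", norm_pep(peptide))
  out <- data.frame(
    sequence = p, length = nchar(p), net_charge = net_charge(p),
    mean_hydrophobicity = mean_hydrophobicity(p, scale),
    molecular_weight = molecular_weight(p, amidated),
    amidated = amidated, stringsAsFactors = FALSE)
  class(out) <- c("physchem_profile", class(out))
  out
}

#' Physicochemical table for a set of peptides
#'
#' Accepts the `-NH2` suffix convention on sequences (e.g. read from a
#' mature-peptide FASTA) to mark amidation.
#'
#' @param peptides Named character vector; a trailing `-NH2` marks an
#'   amidated peptide.
#' @param scale Hydrophobicity scale.
#' @return data.frame with one row per peptide: `id`, `sequence`,
#'   `length`, `net_charge` (`charge`), `mean_hydrophobicity` (`H`),
#'   `molecular_weight` (`MW`), `amidated`.
#' @export
physchem_table <- function(peptides, scale = hydro_scales$ccs) {
  if (is.null(names(peptides)))
    names(peptides) <- paste0("pep", seq_along(peptides))
  amid <- grepl("-NH2$", peptides)
  seqs <- sub("-NH2$", "", peptides)
  rows <- lapply(seq_along(seqs), function(i)
    cbind(id = names(peptides)[i],
          profile_peptide(seqs[[i]], amid[i], scale)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
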