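test_that("split_precursor cleaves at the last charge-valid KR site", {
  sig <- "MFTLKKSLLLLFFLGTINLSLC"
  prot <- paste0(sig, "AEEERDADEEGSE", "KR", "FLGALGNALSRVLGK")
  ann <- split_precursor(prot)
  expect_identical(ann$mature, "FLGALGNALSRVLGK")
  expect_identical(ann$signal, sig)
  expect_identical(ann$propeptide, "AEEERDADEEGSE")
  expect_false(ann$amidated)
  ## reconstruction invariant
  expect_identical(
    paste0(ann$signal, ann$propeptide, "KR", ann$mature, ann$stripped),
    prot)

  ## two KR sites; only the last precedes a cationic segment
  prot2 <- paste0(sig, "AEKREDDDEESE", "KR", "GLLKGLAKALGK")
  ann2 <- split_precursor(prot2)
  expect_identical(ann2$mature, "GLLKGLAKALGK")
  expect_identical(ann2$cleavage_site, nchar(sig) + 13L)

  ## no KR anywhere
  ann3 <- split_precursor(paste0(sig, "AEEDDSE", "GLLGALGK"))
  expect_true(ann3$no_cleavage_site)
  expect_identical(ann3$mature, "")

  ## cationic propeptide triggers a warning, not an error
  expect_warning(split_precursor(paste0(sig, "AKKKSLQ", "KR", "GLKGLAK")),
                 "propeptide")

  ## first_kr mode and KK/RR acceptance are available
  prot2b <- paste0(sig, "AE", "KR", "GKKG", "KR", "GLLKGLAKALGK")
  ann4 <- suppressWarnings(split_precursor(prot2b, site = "first_kr"))
  expect_identical(ann4$cleavage_site, nchar(sig) + 3L)
  ann4b <- suppressWarnings(split_precursor(prot2b, site = "last_kr"))
  expect_identical(ann4b$cleavage_site, nchar(sig) + 9L)
  ann5 <- split_precursor(paste0(sig, "AEEDDSE", "KK", "GLLKGALK"),
                          accept_kk_rr = TRUE)
  expect_identical(ann5$mature, "GLLKGALK")
})

test_that("resolve_amidation strips G+basic suffixes and is idempotent", {
  r1 <- resolve_amidation("LVPFIGRTLGGLLARFGK")
  expect_identical(r1$peptide, "LVPFIGRTLGGLLARF")
  expect_true(r1$amidated)
  expect_identical(r1$stripped, "GK")
  r2 <- resolve_amidation("LLGAALSALSSVIPSVISWFQKG")
  expect_identical(r2$peptide, "LLGAALSALSSVIPSVISWFQK")
  expect_true(r2$amidated)
  ## terminal G alone is an amidation signal under the opt-in rule
  r3 <- resolve_amidation("FLPIVTNLLLRFVG")
  expect_identical(r3$peptide, "FLPIVTNLLLRFV")
  expect_true(r3$amidated)
  ## opt-out returns the sequence unchanged
  r4 <- resolve_amidation("FLPIVTNLLLRFVG", strip = FALSE)
  expect_identical(r4$peptide, "FLPIVTNLLLRFVG")
  expect_false(r4$amidated)
  ## no signal
  r5 <- resolve_amidation("FLGALGNALSRVL")
  expect_false(r5$amidated)
  ## idempotent: re-resolving an amidated peptide is a no-op
  r6 <- resolve_amidation(r1$peptide, amidated = r1$amidated)
  expect_identical(r6$peptide, r1$peptide)
  expect_true(r6$amidated)
  set.seed(109)
  for (k in 1:25) {
    p <- random_pep(15)
    a <- resolve_amidation(p)
    b <- resolve_amidation(a$peptide, amidated = a$amidated)
    expect_identical(b$peptide, a$peptide)
    expect_identical(b$amidated, a$amidated)
  }
})

test_that("detect_ranabox applies the C-terminal loop rule", {
  rb <- detect_ranabox("IVPILLGVVPQLVCAITKKC")
  expect_true(rb$found)
  expect_identical(rb$loop_start, 14L)
  expect_identical(rb$loop_end, 20L)
  expect_true(detect_ranabox("IIPLLLGKVVCAITKKC")$found)
  expect_false(detect_ranabox("FLGALGNALSRVLGK")$found)       # no Cys
  expect_false(detect_ranabox("FLGALGNALSRVLGC")$found)       # single Cys
  ## Cys pair outside the C-terminal 10 residues does not count
  expect_false(detect_ranabox("CAKKACLLLLLLLLLLLLLL")$found)
  ## loop without a basic residue does not count
  expect_false(detect_ranabox("IVPILLGVVPQLVCAITSSC")$found)
  ## loop spacing outside 3-5 does not count
  expect_false(detect_ranabox("IVPILLGVVPQLLLCAKCLL")$found)
})

test_that("novelty tiers partition all inputs", {
  hit <- function(id, cov, e = 1e-10)
    data.frame(query = "q", subject = "s", identity = id, aln_len = 20L,
               mismatches = 0L, gaps = 0L, q_start = 1L, q_end = 20L,
               s_start = 1L, s_end = 20L, evalue = e, bitscore = 50,
               coverage = cov, stringsAsFactors = FALSE)
  expect_identical(assign_novelty(hit(100, 100))$tier, "known_identical")
  expect_identical(assign_novelty(hit(100, 60))$tier, "identical_low_cover")
  expect_identical(assign_novelty(hit(90, 100))$tier, "similar_81_99")
  expect_identical(assign_novelty(hit(75, 100))$tier, "below_80")
  expect_identical(assign_novelty(NULL)$tier, "novel_no_hit")
  expect_identical(assign_novelty(hit(100, 100, e = 0.2))$tier,
                   "novel_no_hit")
  ## band boundaries: identity rounds half away from zero
  expect_identical(assign_novelty(hit(80.6, 100))$tier, "similar_81_99")
  expect_identical(assign_novelty(hit(80.4, 100))$tier, "below_80")
  ## partition property over randomized hit lists
  tiers <- c("known_identical", "identical_low_cover", "similar_81_99",
             "below_80", "novel_no_hit")
  set.seed(113)
  for (k in 1:200) {
    n <- sample(0:4, 1)
    hits <- if (n == 0) NULL else do.call(rbind, lapply(seq_len(n),
      function(i) hit(runif(1, 0, 100), runif(1, 0, 100),
                      10^runif(1, -12, 0.5))))
    tier <- assign_novelty(hits)$tier
    expect_identical(sum(tier == tiers), 1L)
  }
})

test_that("classification is total and rule-ordered", {
  ## rana-box positive peptide gets the rana-box class
  cl <- classify_peptide("IVPILLGVVPQLVCAITKKC")
  expect_identical(cl$class, 1L)
  expect_identical(cl$label, "rana_box_loop")
  ## two Cys but no rana-box
  expect_identical(classify_peptide("CAKKACLLLLLLLLLLLLLL")$class, 2L)
  ## a peptide matching no rule falls to class 8: neutral charge (so not
  ## cationic or anionic rules), 10+ residues, no Cys, charge +1
  cl8 <- classify_peptide("GLLSGLSGLAGLK")
  expect_identical(cl8$class, 8L)
  expect_identical(cl8$label, "unclassified")
  ## malformed rules are rejected
  expect_error(classify_peptide("GLLK", rules = list(list(class = 1))),
               "malformed")
  ## total function: every peptide receives exactly one class
  set.seed(127)
  for (k in 1:500) {
    cls <- classify_peptide(random_pep(sample(5:40, 1)))$class
    expect_true(cls %in% 1:8)
  }
})

test_that("annotate_contigs produces consistent annotations", {
  sig <- "MFTLKKSLLLLFFLGTINLSLC"
  mat <- "FLGALGNALSRVLGK"
  prot <- paste0(sig, "AEEERDADEEGSE", "KR", mat)
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(aa)
    anuramp:::AA_CODONS[[aa]][1], ""), collapse = "")
  set.seed(131)
  contig <- paste0(cds, "TAA", random_dna(60), strrep("A", 20))
  db <- setNames(c(mat, "WWWWYYYYWWWWYYYY"), c("known1", "decoy"))
  ann <- annotate_contigs(setNames(contig, "c1"), db = db,
                          strip_amidation = FALSE)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$mature, mat)
  expect_identical(ann$signal, sig)
  expect_identical(ann$tier, "known_identical")
  expect_identical(ann$net_charge, 3L)
  ## reverse-complemented contig annotates identically
  ann_rc <- annotate_contigs(setNames(revcomp(contig), "c1rc"),
                             db = db, strip_amidation = FALSE)
  expect_identical(ann_rc$mature, mat)
})
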