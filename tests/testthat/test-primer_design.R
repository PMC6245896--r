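test_that("global_identity matches the base-R DP oracle", {
  set.seed(31)
  for (k in 1:40) {
    a <- random_dna(sample(20:40, 1))
    b <- random_dna(sample(20:40, 1))
    expect_equal(global_identity(a, b), oracle_nw_identity(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(global_identity("ACGTACGT", "ACGTACGT"), 1)
})

test_that("identity clustering follows the greedy longest-first rule", {
  s3 <- setNames(rep("ACGTACGTACGTACGTACGT", 3), paste0("s", 1:3))
  cl <- cluster_by_identity(s3, 0.8)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 3L)

  ## two sequences at 50% identity -> singletons at threshold 0.8
  a <- "ACGTACGTACGTACGTACGT"
  set.seed(5)
  repeat {
    b <- random_dna(20)
    if (abs(global_identity(a, b) - 0.5) < 0.11) break
  }
  cl2 <- cluster_by_identity(c(x = a, y = b), 0.8)
  expect_length(cl2, 2L)
  expect_true(all(lengths(lapply(cl2, `[[`, "members")) == 1L))

  expect_identical(cluster_by_identity(character(), 0.8), list())

  ## oracle comparison on 30 random 60-mers (some mutated copies so
  ## both cluster joins and new clusters occur)
  set.seed(33)
  base <- random_dna(60)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(60, k)
    ch[pos] <- vapply(pos, function(p)
      sample(setdiff(c("A","C","G","T"), ch[p]), 1), "")
    paste(ch, collapse = "")
  }
  seqs <- c(replicate(10, mut(base, sample(1:6, 1))),
            replicate(20, random_dna(60)))
  names(seqs) <- paste0("q", seq_along(seqs))
  got <- cluster_by_identity(seqs, 0.8)
  ora <- oracle_cluster(seqs, 0.8, oracle_nw_identity)
  got_idx <- lapply(got, function(cl) sort(match(names(cl$members),
                                                 names(seqs))))
  expect_identical(got_idx, ora)
  ## every member matches its representative at >= threshold
  for (cl in got)
    for (m in cl$members)
      expect_gte(global_identity(seqs[[cl$representative]], m), 0.8)
})

test_that("scan_windows finds conserved windows and their consensus", {
  ident <- setNames(rep("ACGTACGTACGTACGTACGTACGTA", 4), paste0("s", 1:4))
  w <- scan_windows(ident, window_len = 20, max_polymorphic = 3)
  expect_identical(nrow(w), 6L)          # 25 - 20 + 1 starts
  expect_true(all(w$n_polymorphic == 0L))
  expect_identical(w$consensus[1], substr(ident[[1]], 1, 20))

  ## polymorphic column every 5 positions -> >= 4 per 20-column window
  poly <- ident
  ch <- strsplit(poly[[1]], "")[[1]]
  for (j in seq(1, 25, by = 5))
    ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
  poly[1] <- paste(ch, collapse = "")
  w2 <- scan_windows(poly, window_len = 20, max_polymorphic = 3)
  expect_identical(nrow(w2), 0L)

  ## windows equal exhaustive enumeration on a 10-sequence fixture
  set.seed(41)
  base <- random_dna(60)
  fix <- vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(60, 6)
    ch[pos] <- vapply(pos, function(p)
      sample(setdiff(c("A","C","G","T"), ch[p]), 1), "")
    paste(ch, collapse = "")
  }, "")
  names(fix) <- paste0("m", 1:10)
  got <- scan_windows(fix, 20, 3)
  mat <- do.call(rbind, strsplit(fix, ""))
  poly_col <- vapply(1:60, function(j)
    length(unique(mat[, j])) >= 2, TRUE)
  exp_starts <- Filter(function(s) sum(poly_col[s:(s + 19)]) <= 3, 1:41) - 1
  expect_identical(got$start, as.integer(exp_starts))
  for (r in seq_len(nrow(got))) {
    cols <- (got$start[r] + 1):(got$start[r] + 20)
    for (ci in seq_along(cols))
      expect_setequal(iupac_expand(substr(got$consensus[r], ci, ci)),
                      unique(mat[, cols[ci]]))
  }
})

test_that("gapped columns exclude windows", {
  aln <- c(a = "ACGTACGTACGTACGTACGTAC",
           b = "ACGTACGTAC-TACGTACGTAC")
  w <- scan_windows(aln, window_len = 20)
  expect_identical(nrow(w), 0L)
})

test_that("make_degenerate emits minimal IUPAC codes", {
  expect_identical(make_degenerate(list("A")), "A")
  expect_identical(make_degenerate(list(c("A", "G"))), "R")
  expect_warning(out <- make_degenerate(list(c("A", "N"))), "N")
  expect_identical(out, "N")
  expect_identical(make_degenerate(list(c("A", "C", "G", "T"))), "N")
  ## property: expansion of the code equals the observed set
  set.seed(17)
  for (k in 1:50) {
    cols <- lapply(1:5, function(i)
      sample(c("A", "C", "G", "T"), sample(1:3, 1)))
    code <- make_degenerate(cols)
    for (i in 1:5)
      expect_setequal(iupac_expand(substr(code, i, i)),
                      unique(cols[[i]]))
  }
})

test_that("attach_tail reproduces the published primer strings", {
  tp1 <- attach_tail("ATGTTCACCTTGAAGRAATC", "CAGGACCAGGGTACGGTG", "TP1")
  expect_identical(tp1$full_sequence,
                   "CAGGACCAGGGTACGGTGATGTTCACCTTGAAGRAATC")
  expect_identical(tp1$degeneracy, 2)
  ## poly-dT reverse primer: the trP1 adapter already ends in T, so 19
  ## further T complete the printed 20-T stretch
  rev <- attach_tail(strrep("T", 19), "CCTCTCTATGGGCAGTCGGTGAT", "rev")
  expect_identical(rev$full_sequence,
                   "CCTCTCTATGGGCAGTCGGTGATTTTTTTTTTTTTTTTTTTT")
  expect_identical(attach_tail("ACGT", "GGCC")$degeneracy, 1)
})

test_that("pick_primer_position applies the stated ordering", {
  w1 <- data.frame(start = 5L, length = 20L, n_polymorphic = 1L,
                   polymorphic_columns = "7", consensus = "A",
                   degeneracy = 2L)
  expect_identical(pick_primer_position(w1, "signal_any")$start, 5L)
  w2 <- rbind(w1, data.frame(start = 11L, length = 20L,
                             n_polymorphic = 3L,
                             polymorphic_columns = "", consensus = "B",
                             degeneracy = 16L))
  expect_identical(pick_primer_position(w2, "propeptide_3prime")$start,
                   11L)
  expect_identical(
    pick_primer_position(w2, "propeptide_3prime", max_degeneracy = 4)$start,
    5L)
  expect_error(pick_primer_position(w1[0, ], "signal_any"), "failure")

  ## brute-force ordering oracle on 8 windows
  set.seed(19)
  w8 <- data.frame(start = sample(0:40, 8), length = 20L,
                   n_polymorphic = sample(0:3, 8, replace = TRUE),
                   polymorphic_columns = "", consensus = "x",
                   degeneracy = sample(c(1, 2, 4, 8), 8, replace = TRUE))
  sel <- pick_primer_position(w8, "signal_any")
  ora <- w8[order(w8$n_polymorphic, w8$start)[1], ]
  expect_identical(sel$start, ora$start)
  sel2 <- pick_primer_position(w8, "propeptide_3prime", max_degeneracy = 4)
  ok <- w8[w8$degeneracy <= 4, ]
  expect_identical(sel2$start, ok$start[which.max(ok$start)])
})

test_that("predict_amplicons finds binding sites and flags long products", {
  p <- attach_tail("ATGTTCACCTTGAAGAAATC", "CAGGACCAGGGTACGGTG", "TP1")
  ## no primer matches
  expect_message(
    pred0 <- predict_amplicons(c(t1 = strrep("GC", 100)), list(p)),
    "no primer binds")
  expect_identical(nrow(pred0), 0L)

  ## engineered template: primer site at 0, product 573 nt
  insert_len <- 573 - nchar(p$tail) - 23  # minus both tails
  set.seed(23)
  tmpl <- paste0(p$specific_part,
                 random_dna(insert_len - nchar(p$specific_part) - 20),
                 strrep("A", 20))
  pred <- predict_amplicons(c(bb = tmpl), list(p), platform_max = 450)
  expect_identical(pred$product_length, 573L)
  expect_true(pred$exceeds_platform_limit)
  expect_identical(pred$forward_site, 0L)

  ## predicted site/length equal a brute-force scan on small fixtures
  set.seed(29)
  for (k in 1:10) {
    site <- sample(0:30, 1)
    tmpl <- paste0(random_dna(site), "ATGTTCACCTTGAAGAAATC",
                   random_dna(60), strrep("A", 15))
    pred <- predict_amplicons(setNames(tmpl, "t"), list(p),
                              max_mismatches = 0)
    L <- nchar(tmpl); kk <- 20
    mm <- vapply(0:(L - kk), function(s) {
      tv <- substring(tmpl, s + 1, s + kk)
      sum(strsplit("ATGTTCACCTTGAAGAAATC", "")[[1]] !=
            strsplit(tv, "")[[1]])
    }, 0)
    expect_identical(pred$forward_site, (which.min(mm) - 1L))
    expect_identical(pred$product_length,
                     (L - pred$forward_site) + 18L + 23L)
  }
})

test_that("designed primers match back against alignment members", {
  set.seed(37)
  base <- random_dna(60)
  ## polymorphism confined to three fixed columns, as in a conserved
  ## signal-peptide alignment
  poly_cols <- c(12, 30, 47)
  fix <- vapply(1:8, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[poly_cols] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(fix) <- paste0("m", 1:8)
  pr <- design_primer(fix, "signal_any", name = "T1")
  win <- pr$window
  ## with minor_freq_floor = 0 every member matches the consensus with
  ## zero IUPAC mismatches
  for (m in fix) {
    frag <- substr(m, win$start + 1, win$start + 20)
    mm <- sum(!mapply(iupac_match, strsplit(pr$specific_part, "")[[1]],
                      strsplit(frag, "")[[1]]))
    expect_identical(mm, 0L)
  }
  ## degeneracy of the window consensus >= number of distinct observed
  ## 20-mers at that window
  obs <- unique(substr(fix, win$start + 1, win$start + 20))
  expect_gte(pr$degeneracy, length(obs))
})
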