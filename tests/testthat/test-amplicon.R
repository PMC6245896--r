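test_that("Mott trimming equals the brute-force segment oracle", {
  cfg <- trim_config(min_length = 1)
  set.seed(79)
  for (k in 1:200) {
    n <- sample(20:80, 1)
    quals <- sample(2:40, n, replace = TRUE)
    seq <- random_dna(n)
    got <- trim_read(seq, quals, cfg)
    ora <- oracle_mott(quals, 0.05)
    if (is.null(ora)) {
      expect_null(got)
    } else {
      expect_identical(got$seq, substr(seq, ora[1], ora[2]))
      expect_identical(got$quals, quals[ora[1]:ora[2]])
    }
  }
})

test_that("trimming respects the length floor and never lengthens reads", {
  cfg <- trim_config(min_length = 100)
  ## all-Q40, no adapter: unchanged
  s <- random_dna(150)
  got <- trim_read(s, rep(40L, 150), cfg)
  expect_identical(got$seq, s)
  ## an 80-nt high-quality read is below the floor
  expect_null(trim_read(random_dna(80), rep(40L, 80), cfg))
  ## a read whose high-quality segment is 80 nt is discarded too
  s2 <- paste0(random_dna(80), random_dna(60))
  expect_null(trim_read(s2, c(rep(40L, 80), rep(2L, 60)), cfg))
  set.seed(83)
  rq <- qual_reads(paste0("r", 1:30),
                   vapply(1:30, function(i) random_dna(140), ""),
                   lapply(1:30, function(i) sample(2:40, 140, TRUE)))
  tr <- trim_reads(rq, cfg)
  expect_identical(length(tr$reads) +
                     sum(tr$log$outcome != "kept"), 30L)
  expect_true(all(nchar(tr$reads$seq) >= 100))
  expect_true(all(nchar(tr$reads$seq) <= 140))
})

test_that("adapter occurrences are clipped", {
  ad <- "CAGGACCAGGGTACGGTG"
  cfg <- trim_config(min_length = 50, adapters = ad)
  core <- random_dna(120)
  ## 5' adapter: adapter and everything before it removed
  s <- paste0("ACGTAC", ad, core)
  got <- trim_read(s, rep(40L, nchar(s)), cfg)
  expect_identical(got$seq, core)
  ## 3' adapter: adapter and everything after it removed
  s2 <- paste0(core, ad, "ACGT")
  got2 <- trim_read(s2, rep(40L, nchar(s2)), cfg)
  expect_identical(got2$seq, core)
})

test_that("demultiplex assigns by prefix within tolerance", {
  bc <- c(s1 = "ACGTACGTAC", s2 = "TTTTGGGGCC")
  r <- qual_reads(
    c("a", "b", "c"),
    c(paste0("ACGTACGTAC", strrep("G", 20)),   # exact
      paste0("ACGTACGAAT", strrep("G", 20)),   # 2 mismatches
      paste0("TTTTGGGGCC", strrep("A", 20))),  # exact s2
    rep(list(rep(30L, 30)), 3))
  bins <- demultiplex(r, bc, max_mismatch = 1)
  expect_identical(bins$s1$id, "a")
  expect_identical(bins$s1$seq, strrep("G", 20))  # barcode stripped
  expect_identical(bins$undetermined$id, "b")
  expect_identical(bins$s2$id, "c")
  ## barcode table with insufficient distance is rejected
  expect_error(demultiplex(r, c(x = "ACGTACGTAC", y = "ACGTACGTAT"),
                           max_mismatch = 1), "distance")
  ## simulated reads with one injected mismatch: 100% accuracy
  set.seed(89)
  truth <- sample(names(bc), 40, replace = TRUE)
  seqs <- vapply(truth, function(s) {
    b <- strsplit(bc[[s]], "")[[1]]
    p <- sample(10, 1)
    b[p] <- sample(setdiff(c("A","C","G","T"), b[p]), 1)
    paste0(paste(b, collapse = ""), random_dna(30))
  }, "")
  rq <- qual_reads(paste0("r", 1:40), seqs,
                   rep(list(rep(30L, 40)), 40))
  bins2 <- demultiplex(rq, bc, max_mismatch = 1)
  for (s in names(bc))
    expect_setequal(bins2[[s]]$id, paste0("r", which(truth == s)))
})

test_that("greedy OLC reconstructs templates from error-free reads", {
  set.seed(97)
  ## single read -> one contig, support 1
  one <- assemble_olc("ACGTACGT", min_overlap = 4)
  expect_identical(unname(one$consensus), "ACGTACGT")
  expect_identical(one$support, 1L)
  expect_identical(length(assemble_olc(character())$consensus), 0L)

  ## reads tiling one 350-nt template
  tmpl <- random_dna(350)
  starts <- seq(1, 201, by = 25)
  reads <- substring(tmpl, starts, starts + 149)
  asm <- assemble_olc(reads, min_overlap = 50)
  expect_identical(unname(asm$consensus), tmpl)
  expect_identical(asm$support, length(reads))

  ## k = 3 disjoint templates, mixed orientations
  tmpls <- vapply(1:3, function(i) random_dna(300), "")
  reads3 <- unlist(lapply(tmpls, function(tx) {
    st <- seq(1, 151, by = 30)
    r <- substring(tx, st, st + 149)
    r[2] <- revcomp(r[2])
    r
  }))
  asm3 <- assemble_olc(sample(reads3), min_overlap = 50)
  expect_identical(length(asm3$consensus), 3L)
  got <- sort(vapply(asm3$consensus, function(x)
    min(x, revcomp(x)), ""))
  expect_identical(unname(got),
                   sort(vapply(tmpls, function(x)
                     min(x, revcomp(x)), "", USE.NAMES = FALSE)))
  ## read conservation: every read is in exactly one contig
  expect_identical(sum(asm3$support), length(reads3))
  expect_false(anyNA(asm3$assignment))
})

test_that("filter_support applies the boundary at 3 reads", {
  set.seed(101)
  tmpl <- random_dna(200)
  reads <- c(substring(tmpl, c(1, 21, 41), c(120, 140, 160)),
             random_dna(150), random_dna(150))
  asm <- assemble_olc(reads, min_overlap = 50)
  kept <- filter_support(asm, 3)
  expect_identical(kept$support, 3L)
  expect_identical(unname(kept$consensus), substr(tmpl, 1, 160))
  expect_identical(length(filter_support(asm, 4)$consensus), 0L)
  empty <- assemble_olc(character())
  expect_identical(length(filter_support(empty, 3)$consensus), 0L)
})

test_that("remap flags polymorphic contigs and re-assembly separates them", {
  set.seed(103)
  base <- random_dna(300)
  ch <- strsplit(base, "")[[1]]
  pos <- c(50, 100, 150, 200, 250)
  ch[pos] <- vapply(pos, function(p)
    sample(setdiff(c("A","C","G","T"), ch[p]), 1), "")
  hap2 <- paste(ch, collapse = "")
  st <- seq(1, 101, by = 20)
  reads <- c(substring(base, st, st + 199), substring(hap2, st, st + 199))
  ## permissive assembly collapses the two haplotypes
  asm <- assemble_olc(reads, min_overlap = 50,
                      min_overlap_identity = 0.90)
  expect_identical(length(asm$consensus), 1L)
  rf <- remap_and_flag(asm, reads, polymorphism_floor = 0.2,
                       flag_rate = 0.01, stringent_identity = 0.99)
  expect_true(any(rf$flagged))
  variants <- vapply(rf$contigs$consensus, function(x)
    min(x, revcomp(x)), "")
  expect_setequal(unname(variants),
                  vapply(c(base, hap2), function(x)
                    min(x, revcomp(x)), "", USE.NAMES = FALSE))

  ## error-free single-haplotype data: polymorphism rate 0
  asm1 <- assemble_olc(substring(base, st, st + 199), min_overlap = 50)
  rf1 <- remap_and_flag(asm1, substring(base, st, st + 199))
  expect_identical(unname(rf1$polymorphism_rate), 0)
  expect_false(any(rf1$flagged))
})

test_that("remap allele counts equal a brute-force recount", {
  set.seed(107)
  tmpl <- random_dna(150)
  st <- c(1, 26, 51)
  reads <- substring(tmpl, st, st + 99)
  asm <- assemble_olc(reads, min_overlap = 50)
  mp <- anuramp:::map_reads(reads, asm)
  counts <- mp$counts[[1]]
  ## brute force: reads are exact substrings at known offsets
  expected <- matrix(0L, 5, 150,
                     dimnames = list(c("A","C","G","T","N"), NULL))
  for (i in seq_along(reads)) {
    cols <- st[i]:(st[i] + 99)
    rows <- match(strsplit(reads[i], "")[[1]], c("A","C","G","T"))
    for (z in seq_along(cols))
      expected[rows[z], cols[z]] <- expected[rows[z], cols[z]] + 1L
  }
  expect_identical(counts, expected)
})
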