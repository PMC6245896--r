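## Independent oracles used by the test suite. These deliberately avoid
## the package's own code paths (C++ kernels, vectorized shortcuts) and
## implement the definitions directly in base R.

## global alignment maximizing (score, matches, -columns) with
## match +1 / mismatch -1 / gap -1; returns identity = matches / columns
oracle_nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1, m + 1); M <- matrix(0L, n + 1, m + 1)
  L <- matrix(0L, n + 1, m + 1)
  S[1, ] <- -(0:m); L[1, ] <- 0:m
  S[, 1] <- -(0:n); L[, 1] <- 0:n
  better <- function(s1, m1, l1, s2, m2, l2) {
    if (s1 != s2) return(s1 > s2)
    if (m1 != m2) return(m1 > m2)
    l1 < l2
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    eq <- A[i - 1] == B[j - 1]
    s <- S[i - 1, j - 1] + if (eq) 1L else -1L
    mm <- M[i - 1, j - 1] + as.integer(eq)
    ll <- L[i - 1, j - 1] + 1L
    if (better(S[i - 1, j] - 1L, M[i - 1, j], L[i - 1, j] + 1L, s, mm, ll)) {
      s <- S[i - 1, j] - 1L; mm <- M[i - 1, j]; ll <- L[i - 1, j] + 1L
    }
    if (better(S[i, j - 1] - 1L, M[i, j - 1], L[i, j - 1] + 1L, s, mm, ll)) {
      s <- S[i, j - 1] - 1L; mm <- M[i, j - 1]; ll <- L[i, j - 1] + 1L
    }
    S[i, j] <- s; M[i, j] <- mm; L[i, j] <- ll
  }
  M[n + 1, m + 1] / L[n + 1, m + 1]
}

## greedy longest-first clustering re-implemented from the stated rule,
## given a precomputed identity function
oracle_cluster <- function(seqs, threshold, identity_fun) {
  ord <- order(-nchar(seqs))
  reps <- integer(0)
  memb <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (identity_fun(seqs[[reps[k]]], seqs[[i]]) >= threshold) {
        memb[[k]] <- c(memb[[k]], i); placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); memb[[length(reps)]] <- i }
  }
  lapply(memb, sort)
}

## Smith-Waterman affine score by direct DP (score only);
## gap of length k costs open + k * extend
oracle_sw_score <- function(q, s, sm, open, extend) {
  Q <- strsplit(q, "")[[1]]; S <- strsplit(s, "")[[1]]
  n <- length(Q); m <- length(S)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
    F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + sm[Q[i - 1], S[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

## brute-force modified-Mott: maximize sum(limit - perr) over all
## contiguous segments
oracle_mott <- function(quals, limit) {
  w <- limit - 10^(-quals / 10)
  n <- length(w)
  best <- 0; seg <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    s <- sum(w[i:j])
    if (s > best) { best <- s; seg <- c(i, j) }
  }
  seg
}

## brute-force ORF enumeration: all six frames, start-to-stop
oracle_orfs <- function(seq, require_start = TRUE) {
  L <- nchar(seq)
  out <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    s <- if (frame > 0) seq else anuramp::revcomp(seq)
    off <- abs(frame) - 1
    ncod <- (nchar(s) - off) %/% 3
    if (ncod < 1) next
    starts <- off + 3 * (seq_len(ncod) - 1) + 1
    codons <- substring(s, starts, starts + 2)
    aa <- vapply(codons, function(cd)
      as.character(Biostrings::GENETIC_CODE[cd]), "")
    is_stop <- aa == "*"
    cand_starts <- if (require_start) which(aa == "M") else {
      c(1, which(is_stop) + 1)
    }
    cand_starts <- cand_starts[cand_starts <= ncod & !is_stop[cand_starts]]
    for (cs in cand_starts) {
      nxt <- which(is_stop & seq_len(ncod) > cs - 1)
      nxt <- nxt[nxt >= cs]
      ce <- if (length(nxt)) nxt[1] - 1 else ncod
      has_stop <- length(nxt) > 0
      prot <- paste(aa[cs:ce], collapse = "")
      c0 <- off + 3 * (cs - 1)
      c1 <- off + 3 * (ce + as.integer(has_stop))
      if (frame > 0) { nt0 <- c0; nt1 <- c1 }
      else { nt0 <- L - c1; nt1 <- L - c0 }
      out[[length(out) + 1]] <- data.frame(
        frame = frame, nt_start = nt0, nt_end = nt1, protein = prot,
        has_stop = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_pep <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")
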