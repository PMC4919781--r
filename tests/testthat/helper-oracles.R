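# Independent brute-force oracles used across the suite. These are
# deliberately naive (character loops, full DP matrices in plain R) and
# share no code with the package internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(comp_base[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# exhaustive triplet scan for NGG PAMs on both strands; returns 0-based
# leftmost sense coordinate of the PAM triplet
oracle_pam_scan <- function(seq, strands = c("+", "-")) {
  s <- toupper(seq)
  n <- nchar(s)
  pos <- integer(0); strand <- character(0)
  for (i in seq_len(max(n - 2L, 0L))) {
    trip <- substr(s, i, i + 2L)
    ch <- strsplit(trip, "")[[1]]
    if ("+" %in% strands && ch[1] != "N" && ch[2] == "G" && ch[3] == "G") {
      pos <- c(pos, i - 1L); strand <- c(strand, "+")
    }
    if ("-" %in% strands && ch[1] == "C" && ch[2] == "C" && ch[3] != "N") {
      pos <- c(pos, i - 1L); strand <- c(strand, "-")
    }
  }
  ord <- order(pos, strand)
  data.frame(pos = pos[ord], strand = strand[ord], stringsAsFactors = FALSE)
}

# exhaustive window scan: every position/strand whose adjacent triplet is
# NGG and whose Hamming distance to the spacer is <= max_mm
oracle_offtarget_scan <- function(genome_seq, spacer, max_mm) {
  s <- toupper(genome_seq)
  sp <- strsplit(toupper(spacer), "")[[1]]
  L <- length(sp)
  n <- nchar(s)
  out <- list()
  for (start in 0:(n - L)) {                      # 0-based window start
    win <- substr(s, start + 1L, start + L)
    # plus strand: PAM right of the window
    if (start + L + 3L <= n) {
      pam <- substr(s, start + L + 1L, start + L + 3L)
      pc <- strsplit(pam, "")[[1]]
      if (pc[1] != "N" && pc[2] == "G" && pc[3] == "G") {
        mm <- sum(strsplit(win, "")[[1]] != sp)
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(start = start, strand = "+",
                                                mm = mm)
        }
      }
    }
    # minus strand: PAM left of the window, site read as revcomp
    if (start >= 3L) {
      pam <- oracle_revcomp(substr(s, start - 2L, start))
      pc <- strsplit(pam, "")[[1]]
      if (pc[1] != "N" && pc[2] == "G" && pc[3] == "G") {
        site <- oracle_revcomp(win)
        mm <- sum(strsplit(site, "")[[1]] != sp)
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(start = start, strand = "-",
                                                mm = mm)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      mm = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# plain-R affine-gap global alignment, score only (gap of length k costs
# open + k * ext; N is neutral)
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               open = -8, ext = -1) {
  a <- strsplit(toupper(read), "")[[1]]
  b <- strsplit(toupper(ref), "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)
  IY <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) IY[1, j + 1] <- open + j * ext
  for (i in seq_len(n)) IX[i + 1, 1] <- open + i * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (a[i] == "N" || b[j] == "N") 0 else
        if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], IX[i, j], IY[i, j]) + sub
      IX[i + 1, j + 1] <- max(M[i, j + 1] + open + ext,
                              IX[i, j + 1] + ext,
                              IY[i, j + 1] + open + ext)
      IY[i + 1, j + 1] <- max(M[i + 1, j] + open + ext,
                              IY[i + 1, j] + ext,
                              IX[i + 1, j] + open + ext)
    }
  }
  max(M[n + 1, m + 1], IX[n + 1, m + 1], IY[n + 1, m + 1])
}

# a reference amplicon used by several indel tests: fixed, GC-balanced,
# no long homopolymers near the cut
make_test_amplicon <- function(len = 200, seed = 424242) {
  withr::with_seed(seed, rand_dna(len))
}
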