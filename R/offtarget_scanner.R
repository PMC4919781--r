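## Off-target site profiling. Candidate sites are compared to the guide
## by ungapped Hamming distance over two windows: the full spacer (m20)
## and the 17 PAM-proximal positions (m17). The PAM itself (NGG; its
## degenerate first base is printed lowercase in site tables) is never
## counted as a mismatch.

#' Hamming mismatch count between two equal-length DNA strings
#'
#' Case-insensitive, positionwise comparison. `N` is not allowed: the
#' comparison is meant for fully resolved spacer/site sequences.
#'
#' @param a,b DNA strings of equal length (A/C/G/T).
#' @return integer mismatch count.
#' @examples
#' hamming_mismatches("GTCCAGCTCGACCAGGA", "GTCCAGCTGGACCAGGA")  # 1
#' @export
hamming_mismatches <- function(a, b) {
  a <- as_dna_string(a, allow_n = FALSE, what = "a")
  b <- as_dna_string(b, allow_n = FALSE, what = "b")
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  sum(seq_chars(a) != seq_chars(b))
}

#' Mismatch profile over the full and PAM-proximal 17 nt windows
#'
#' Both sequences are PAM-excluded and aligned at their PAM-proximal
#' (3') ends. `m20` counts mismatches over all positions (the name
#' follows the full-length 20 nt spacer; for a 17 nt guide it equals
#' `m17`), `m17` over the 17 positions nearest the PAM.
#'
#' @param on_spacer on-target protospacer (length >= 17).
#' @param site_seq candidate site sequence, same length.
#' @return named integer vector `c(m20 = , m17 = )`.
#' @examples
#' windowed_mismatch_profile("GACGTAGCCTTCGGGCATGG", "TTTGTAGTCTTCAGGCATGG")
#' @export
windowed_mismatch_profile <- function(on_spacer, site_seq) {
  on_spacer <- as_dna_string(on_spacer, allow_n = FALSE, what = "on_spacer")
  site_seq <- as_dna_string(site_seq, allow_n = FALSE, what = "site_seq")
  L <- nchar(on_spacer)
  if (L < 17L) stop("spacer shorter than 17 nt", call. = FALSE)
  m_all <- hamming_mismatches(on_spacer, site_seq)
  m_prox <- hamming_mismatches(substr(on_spacer, L - 16L, L),
                               substr(site_seq, L - 16L, L))
  c(m20 = m_all, m17 = m_prox)
}

#' Scan a genome for off-target sites of a guide
#'
#' Enumerates every window on both strands whose adjacent trinucleotide
#' matches the PAM pattern and whose ungapped Hamming distance to the
#' guide's matched spacer is at most `max_mm`. Genomic `N` matches
#' nothing (a window containing `N` accrues mismatches at those
#' positions; a PAM containing `N` is not a PAM).
#'
#' @param genome named character vector of genome records (or a FASTA
#'   path, or a `DNAStringSet`).
#' @param guide one-row guide data.frame or spacer string; the matched
#'   (untagged, uppercase) portion is used for matching.
#' @param max_mm maximum mismatch count over the full spacer window. The
#'   default follows the extremes examined for each length: 5 for 20 nt
#'   guides, 4 for shorter ones.
#' @param include_nag also accept NAG PAMs (off by default; NGG is the
#'   canonical SpCas9 PAM).
#' @return data.frame with one row per hit: `guide_name`, `record`,
#'   `start`, `end` (0-based half-open protospacer span on the sense
#'   strand), `strand`, `site_seq` (PAM-excluded, guide-strand 5'->3'),
#'   `pam`, `m20`, `m17`; sorted by (record, start, strand).
#' @export
scan_genome <- function(genome, guide, max_mm = NULL, include_nag = FALSE) {
  if (is.character(genome) && length(genome) == 1L &&
      !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- toupper(as.character(genome))
    names(genome) <- nm
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("seq", seq_along(genome))
  }
  guide <- as_guide_row(guide)
  spacer <- matched_spacer(guide)
  L <- nchar(spacer)
  if (is.null(max_mm)) max_mm <- if (L >= 20L) 5L else 4L
  if (max_mm < 0L) stop("max_mm must be >= 0", call. = FALSE)
  sp_chars <- seq_chars(spacer)
  rc_chars <- seq_chars(revcomp(spacer))

  hits <- list()
  for (rec in names(genome)) {
    s <- as_dna_string(genome[[rec]], allow_n = TRUE, what = rec)
    ch <- seq_chars(s)
    n <- length(ch)
    if (n < L + 3L) next
    second <- if (include_nag) c("G", "A") else "G"

    # plus strand: protospacer [i, i+L), PAM [i+L, i+L+3)
    i <- seq_len(n - L - 2L)                 # 1-based protospacer start
    pam_ok <- ch[i + L] != "N" & ch[i + L + 1L] %in% second & ch[i + L + 2L] == "G"
    cand <- i[pam_ok]
    if (length(cand)) {
      mm <- integer(length(cand))
      mm17 <- integer(length(cand))
      for (k in seq_len(L)) {
        diff <- ch[cand + k - 1L] != sp_chars[k]
        mm <- mm + diff
        if (k > L - 17L) mm17 <- mm17 + diff
      }
      keep <- mm <= max_mm
      if (any(keep)) {
        cs <- cand[keep]
        hits[[length(hits) + 1L]] <- data.frame(
          guide_name = guide$name, record = rec,
          start = cs - 1L, end = cs - 1L + L, strand = "+",
          site_seq = substring(s, cs, cs + L - 1L),
          pam = substring(s, cs + L, cs + L + 2L),
          m20 = mm[keep], m17 = mm17[keep], stringsAsFactors = FALSE
        )
      }
    }

    # minus strand: sense-strand pattern is rc(PAM)=CCN followed by the
    # rc of the spacer; protospacer sense span [j, j+L) with PAM [j-3, j).
    j <- seq(4L, n - L + 1L)                 # 1-based protospacer start
    pam_ok <- ch[j - 3L] == "C" &
      ch[j - 2L] %in% (if (include_nag) c("C", "T") else "C") &
      ch[j - 1L] != "N"
    cand <- j[pam_ok]
    if (length(cand)) {
      mm <- integer(length(cand))
      mm17 <- integer(length(cand))
      # spacer position k (5'->3' on guide) sits at sense index j + L - k
      for (k in seq_len(L)) {
        diff <- ch[cand + L - k] != rc_chars[L - k + 1L]
        mm <- mm + diff
        if (k > L - 17L) mm17 <- mm17 + diff
      }
      keep <- mm <= max_mm
      if (any(keep)) {
        cs <- cand[keep]
        hits[[length(hits) + 1L]] <- data.frame(
          guide_name = guide$name, record = rec,
          start = cs - 1L, end = cs - 1L + L, strand = "-",
          site_seq = vapply(cs, function(x)
            revcomp(substr(s, x, x + L - 1L)), character(1)),
          pam = vapply(cs, function(x)
            revcomp(substr(s, x - 3L, x - 1L)), character(1)),
          m20 = mm[keep], m17 = mm17[keep], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(guide_name = character(0), record = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), site_seq = character(0),
                      pam = character(0), m20 = integer(0), m17 = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$record, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate off-target hits by mismatch category
#'
#' On-target hits (`m20 == 0`) are counted separately from candidate
#' off-target sites, which are partitioned by their PAM-proximal
#' mismatch count (and, secondarily, by the full-window count).
#'
#' @param hits data.frame of hits with `m17` and `m20` columns (from
#'   [scan_genome()] or a site-table fixture).
#' @return list with `n_on_target`, `n_candidates`, `m17_counts` and
#'   `m20_counts` (named integer vectors keyed by mismatch count).
#' @export
categorize_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(c("m17", "m20") %in% names(hits)))
  on <- hits$m20 == 0L
  cand <- hits[!on, , drop = FALSE]
  count_by <- function(x) {
    if (length(x) == 0L) return(integer(0))
    tab <- table(factor(x, levels = seq(0L, max(x))))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
  list(
    n_on_target = sum(on),
    n_candidates = nrow(cand),
    m17_counts = count_by(cand$m17),
    m20_counts = count_by(cand$m20)
  )
}

#' Write off-target hits as BED6
#'
#' name = `<guide>|<record>:<start>`, score = `m17`.
#'
#' @param hits hit data.frame from [scan_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$record, hits$start, hits$end,
                    paste0(hits$guide_name, "|", hits$record, ":", hits$start),
                    hits$m17, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
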