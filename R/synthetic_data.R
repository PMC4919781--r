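## Simulators for every input the pipeline consumes: edited Sanger-style
## clone reads, genomes with planted off-target sites at chosen
## mismatch counts, binomial FACS knockout counts, and noisy T7E1
## measurements. Every generator takes an explicit seed and records
## ground truth, so parameter recovery can be tested end to end. All
## randomness is isolated with withr::with_seed; no global RNG state is
## disturbed.

#' Indel spectrum for read simulation
#'
#' Defaults emulate the NHEJ outcome structure seen at reporter loci:
#' deletion-dominated (80%), with a geometric-like length distribution
#' of mean about 5 nt on support 1-30 nt. These are emulation
#' parameters, not measured values.
#'
#' @param p_deletion probability an edit is a deletion.
#' @param lengths integer support of event lengths.
#' @param length_probs probabilities over `lengths` (normalised).
#' @param complex_allele_rate probability an edited (deletion) allele
#'   additionally carries a short junction insertion.
#' @return list of class `indel_spectrum`.
#' @export
indel_spectrum <- function(p_deletion = 0.8, lengths = 1:30,
                           length_probs = 0.2 * 0.8^(lengths - 1),
                           complex_allele_rate = 0.05) {
  stopifnot(p_deletion >= 0, p_deletion <= 1,
            complex_allele_rate >= 0, complex_allele_rate <= 1,
            length(lengths) == length(length_probs), all(length_probs >= 0))
  structure(list(
    p_deletion = p_deletion,
    lengths = as.integer(lengths),
    length_probs = length_probs / sum(length_probs),
    complex_allele_rate = complex_allele_rate
  ), class = "indel_spectrum")
}

#' @keywords internal
#' @noRd
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate edited amplicon clone reads
#'
#' Each read is independently edited with probability `edit_rate`; an
#' edited read receives one event drawn from `spectrum`, placed at the
#' cut: insertions at the cut itself, deletions with their left edge at
#' most 10 nt 5' of the cut (so every event stays inside the default
#' calling window). Complex alleles add a 1-5 nt insertion at the
#' deletion junction. Reads are error-free otherwise, as Sanger clone
#' consensus sequences are.
#'
#' @param ref reference amplicon (length >= `cut_site` + 30, and
#'   `cut_site` >= 30, so the longest event fits).
#' @param cut_site 0-based cut coordinate.
#' @param n_reads number of clones.
#' @param edit_rate per-read editing probability.
#' @param spectrum an [indel_spectrum()].
#' @param seed integer seed (required; the only source of randomness).
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `clone_id`, `edited`, `kind` of "none", "deletion",
#'   "insertion" or "complex", `del_len`, `ins_len`, `event_pos`
#'   (0-based left edge), `net_length`).
#' @export
simulate_edited_reads <- function(ref, cut_site, n_reads, edit_rate,
                                  spectrum = indel_spectrum(), seed) {
  ref <- as_dna_string(ref, allow_n = FALSE, what = "ref")
  n <- nchar(ref)
  max_len <- max(spectrum$lengths)
  if (cut_site < max_len || cut_site + max_len > n) {
    stop("cut site too close to the reference edge for events up to ",
         max_len, " nt", call. = FALSE)
  }
  stopifnot(edit_rate >= 0, edit_rate <= 1, n_reads >= 1)
  withr::with_seed(seed, {
    rows <- vector("list", n_reads)
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      id <- sprintf("clone%04d", i)
      if (runif(1) >= edit_rate) {
        reads[i] <- ref
        rows[[i]] <- data.frame(clone_id = id, edited = FALSE, kind = "none",
                                del_len = 0L, ins_len = 0L,
                                event_pos = NA_integer_, net_length = 0L,
                                stringsAsFactors = FALSE)
        next
      }
      k <- sample(spectrum$lengths, 1L, prob = spectrum$length_probs)
      if (runif(1) < spectrum$p_deletion) {
        offset <- sample.int(min(k, 11L), 1L) - 1L      # 0..min(k-1, 10)
        left <- cut_site - offset                        # 0-based left edge
        ins <- ""
        kind <- "deletion"
        ins_len <- 0L
        if (runif(1) < spectrum$complex_allele_rate) {
          ins_len <- sample.int(5L, 1L)
          ins <- random_dna(ins_len)
          kind <- "complex"
        }
        reads[i] <- paste0(substr(ref, 1L, left), ins,
                           substr(ref, left + k + 1L, n))
        rows[[i]] <- data.frame(clone_id = id, edited = TRUE, kind = kind,
                                del_len = k, ins_len = ins_len,
                                event_pos = left, net_length = ins_len - k,
                                stringsAsFactors = FALSE)
      } else {
        ins <- random_dna(k)
        reads[i] <- paste0(substr(ref, 1L, cut_site), ins,
                           substr(ref, cut_site + 1L, n))
        rows[[i]] <- data.frame(clone_id = id, edited = TRUE,
                                kind = "insertion", del_len = 0L,
                                ins_len = k, event_pos = cut_site,
                                net_length = k, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    names(reads) <- truth$clone_id
    list(reads = reads, truth = truth)
  })
}

#' Plant off-target sites in a synthetic genome
#'
#' Builds a random background sequence and embeds, at non-overlapping
#' random positions and strands, NGG-adjacent sites derived from the
#' guide's matched spacer with exactly the requested number of
#' mismatches in the PAM-proximal 17 nt window. For spacers longer than
#' 17 nt, `distal_mm` additional mismatches can be placed in the
#' PAM-distal remainder so that m20 exceeds m17, as real site tables
#' show. The PAM is never mutated.
#'
#' @param guide one-row guide data.frame or spacer string.
#' @param plan named integer vector: `names` are m17 mismatch counts,
#'   values the number of sites to plant (e.g. `c("1" = 3, "2" = 9,
#'   "3" = 2, "4" = 5)`). Use `"0" = 1` to plant the exact on-target
#'   locus.
#' @param background_len background genome length (nt); must hold all
#'   sites without overlap.
#' @param seed integer seed.
#' @param distal_mm extra PAM-distal mismatches per site (0 keeps
#'   m20 = m17 for 20 nt guides).
#' @param gc background GC content.
#' @return list with `genome` (named character vector of one record,
#'   "chrSim") and `truth` (data.frame: `record`, `start`, `end`
#'   (0-based half-open protospacer span), `strand`, `site_id`, `m17`,
#'   `m20`).
#' @export
plant_offtarget_genome <- function(guide, plan, background_len = 20000L,
                                   seed, distal_mm = 0L, gc = 0.5) {
  guide <- as_guide_row(guide)
  spacer <- matched_spacer(guide)
  L <- nchar(spacer)
  window <- min(17L, L)
  m_levels <- as.integer(names(plan))
  if (any(is.na(m_levels)) || any(m_levels < 0L)) {
    stop("plan names must be nonnegative mismatch counts", call. = FALSE)
  }
  if (any(m_levels > window)) {
    stop("infeasible plan: more mismatches than window positions (",
         window, ")", call. = FALSE)
  }
  if (distal_mm > L - window) {
    stop("distal_mm exceeds the PAM-distal positions available",
         call. = FALSE)
  }
  n_sites <- sum(plan)
  footprint <- L + 3L
  block <- background_len %/% max(n_sites, 1L)
  if (block < footprint + 10L) {
    stop("background_len too small to hold ", n_sites,
         " non-overlapping sites", call. = FALSE)
  }
  withr::with_seed(seed, {
    genome <- seq_chars(random_dna(background_len, gc = gc))
    m_per_site <- rep(m_levels, times = plan)
    bases <- c("A", "C", "G", "T")
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      m <- m_per_site[i]
      site <- seq_chars(spacer)
      prox_idx <- seq(L - window + 1L, L)
      for (p in sample(prox_idx, m)) {
        site[p] <- sample(setdiff(bases, site[p]), 1L)
      }
      if (distal_mm > 0L && L > window) {
        for (p in sample(seq_len(L - window), distal_mm)) {
          site[p] <- sample(setdiff(bases, site[p]), 1L)
        }
      }
      pam <- c(sample(bases, 1L), "G", "G")
      strand <- sample(c("+", "-"), 1L)
      embedded <- c(site, pam)
      if (strand == "-") embedded <- seq_chars(revcomp(paste(embedded, collapse = "")))
      offset <- sample.int(block - footprint - 2L, 1L)
      e <- (i - 1L) * block + offset                    # 0-based embed start
      genome[(e + 1L):(e + footprint)] <- embedded
      start <- if (strand == "+") e else e + 3L
      rows[[i]] <- data.frame(
        record = "chrSim", start = start, end = start + L, strand = strand,
        site_id = sprintf("planted%02d_m%d", i, m),
        m17 = m, m20 = m + if (L > window) distal_mm else 0L,
        stringsAsFactors = FALSE
      )
    }
    truth <- if (n_sites) do.call(rbind, rows) else
      data.frame(record = character(0), start = integer(0), end = integer(0),
                 strand = character(0), site_id = character(0),
                 m17 = integer(0), m20 = integer(0))
    list(genome = c(chrSim = paste(genome, collapse = "")), truth = truth)
  })
}

#' Write a planted-site truth table as BED6
#'
#' @param truth truth data.frame from [plant_offtarget_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(truth$record, truth$start, truth$end, truth$site_id,
                    truth$m17, truth$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a FACS knockout readout
#'
#' GFP-negative cells are binomial with success probability
#' `true_ko + (1 - true_ko) * background_neg`: knocked-out cells are
#' negative, and unedited cells are negative at the reporter line's
#' background rate (default 0.5%, i.e. a 99.5% GFP-positive clone).
#'
#' @param true_ko true knockout proportion in `[0, 1]`.
#' @param n_cells number of cells analysed.
#' @param background_neg background GFP-negative proportion.
#' @param seed integer seed.
#' @param cell_line,guide_name,class,replicate labels for the record.
#' @return one-row data.frame with the count schema used by
#'   [summarize_ko_counts()] plus `ko_percent`, `true_ko` and
#'   `p_expected`.
#' @export
simulate_facs <- function(true_ko, n_cells, background_neg = 0.005, seed,
                          cell_line = "synthetic", guide_name = "sim",
                          class = "sim", replicate = 1L) {
  stopifnot(true_ko >= 0, true_ko <= 1,
            background_neg >= 0, background_neg <= 1)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  p <- true_ko + (1 - true_ko) * background_neg
  n_neg <- withr::with_seed(seed, rbinom(1L, n_cells, p))
  data.frame(cell_line = cell_line, guide = guide_name, class = class,
             replicate = as.integer(replicate), n_total = as.integer(n_cells),
             n_gfp_neg = n_neg, ko_percent = ko_efficiency(n_neg, n_cells),
             true_ko = true_ko, p_expected = p, stringsAsFactors = FALSE)
}

#' Simulate a T7E1 measurement from a true indel percentage
#'
#' Inverts the indel formula to the true fraction cleaved, adds Gaussian
#' measurement noise, truncates to `[0, 0.999999]` and converts back.
#'
#' @param true_indel_pct true indel percentage in `[0, 100)`.
#' @param noise_sd standard deviation of the noise on the fraction
#'   cleaved.
#' @param seed integer seed.
#' @param site_id label.
#' @param nd_threshold detection threshold (percent).
#' @return one-row data.frame with `site_id`, `f_c_true`, `f_c`,
#'   `indel_percent`, `detected`.
#' @export
simulate_t7e1 <- function(true_indel_pct, noise_sd = 0.02, seed,
                          site_id = "sim", nd_threshold = 2) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f_true <- invert_indel_percent(true_indel_pct)
  f <- withr::with_seed(seed, f_true + rnorm(1L, 0, noise_sd))
  f <- min(max(f, 0), 0.999999)
  p <- indel_percent(f)
  data.frame(site_id = site_id, f_c_true = f_true, f_c = f,
             indel_percent = p, detected = call_detection(p, nd_threshold),
             stringsAsFactors = FALSE)
}
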