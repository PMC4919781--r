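## Guide design under the truncated-sgRNA rules: SpCas9 protospacers are
## the spacer-length window immediately 5' of an NGG PAM. U6-driven
## transcription needs a 5' G, supplied either by requiring a matched
## genomic G (policy "require_matched_G") or by prepending a mismatched
## lowercase g (policy "prepend_g"). Effective guides need >= 17 matched
## nt, or >= 18 nt total when the 5' g is a mismatch.

GUIDE_COLUMNS <- c("name", "site_label", "strand", "start", "spacer",
                   "matched_len", "total_len", "pam",
                   "five_prime_tagged", "three_prime_pref", "effective_flag")

#' Find NGG PAM sites on one or both strands
#'
#' Scans a DNA sequence for SpCas9 PAM trinucleotides (NGG). A PAM on
#' the minus strand appears as CCN on the sense strand. Genomic `N`
#' never matches any PAM position, including the degenerate first base.
#'
#' @param seq a single DNA string (A/C/G/T/N, case-insensitive).
#' @param strands character vector, subset of `c("+", "-")`.
#' @return data.frame with columns `pos` (0-based sense-strand index of
#'   the leftmost base of the PAM trinucleotide) and `strand`.
#' @examples
#' find_pam_sites("GCCGTCCAGCTCGACCAGGATGG", strands = "+")
#' @export
find_pam_sites <- function(seq, strands = c("+", "-")) {
  s <- as_dna_string(seq, allow_n = TRUE, what = "seq")
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  ch <- seq_chars(s)
  n <- length(ch)
  pos <- integer(0)
  strand <- character(0)
  if (n >= 3L) {
    i <- seq_len(n - 2L)                      # 1-based leftmost index
    if ("+" %in% strands) {
      hit <- ch[i] != "N" & ch[i + 1L] == "G" & ch[i + 2L] == "G"
      pos <- c(pos, i[hit] - 1L)
      strand <- c(strand, rep("+", sum(hit)))
    }
    if ("-" %in% strands) {
      hit <- ch[i] == "C" & ch[i + 1L] == "C" & ch[i + 2L] != "N"
      pos <- c(pos, i[hit] - 1L)
      strand <- c(strand, rep("-", sum(hit)))
    }
  }
  ord <- order(pos, strand)
  data.frame(pos = pos[ord], strand = strand[ord], stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
new_guide <- function(name, site_label, strand, start, spacer, matched_len,
                      pam, five_prime_tagged) {
  total_len <- matched_len + as.integer(five_prime_tagged)
  last_base <- toupper(substr(spacer, nchar(spacer), nchar(spacer)))
  data.frame(
    name = name, site_label = as.integer(site_label), strand = strand,
    start = as.integer(start), spacer = spacer,
    matched_len = as.integer(matched_len), total_len = as.integer(total_len),
    pam = pam,
    five_prime_tagged = five_prime_tagged,
    three_prime_pref = last_base %in% c("G", "A"),
    effective_flag = !(matched_len < 17L ||
                         (five_prime_tagged && total_len < 18L)),
    stringsAsFactors = FALSE
  )
}

#' Design guide candidates for every designable PAM site
#'
#' For each NGG PAM with at least `spacer_len` nucleotides of 5' flank
#' (on the PAM's strand), emits one guide candidate. Under policy
#' `"require_matched_G"` only protospacers whose 5' base is G are kept;
#' under `"prepend_g"` protospacers starting with another base get a
#' mismatched lowercase `g` prepended (total length `spacer_len + 1`);
#' `"any"` emits all protospacers untagged. Candidates whose protospacer
#' window or PAM overlaps an `N` are skipped with a warning.
#'
#' The effectiveness flag encodes the minimum-length rules: a guide is
#' flagged ineffective when fewer than 17 nt are genome-matched, or when
#' it carries a mismatched 5' g and is shorter than 18 nt in total.
#'
#' @param seq target DNA string (sense strand).
#' @param spacer_len matched spacer length, 16-20.
#' @param policy `"require_matched_G"`, `"prepend_g"` or `"any"`.
#' @param strands strands to design on, subset of `c("+", "-")`.
#' @param name_prefix prefix for candidate names.
#' @param site_offset added to the 0-based start to form `site_label`
#'   (default 1, i.e. 1-based numbering).
#' @return data.frame of guide candidates (one row per kept PAM site)
#'   with columns name, site_label, strand, start, spacer, matched_len,
#'   total_len, pam, five_prime_tagged, three_prime_pref, effective_flag.
#' @examples
#' design_guides("GCCGTCCAGCTCGACCAGGATGG", 20, policy = "require_matched_G")
#' @export
design_guides <- function(seq, spacer_len,
                          policy = c("require_matched_G", "prepend_g", "any"),
                          strands = c("+", "-"),
                          name_prefix = "sg", site_offset = 1L) {
  s <- as_dna_string(seq, allow_n = TRUE, what = "seq")
  if (nchar(s) == 0L) stop("empty target sequence", call. = FALSE)
  if (!is.numeric(spacer_len) || length(spacer_len) != 1L ||
      spacer_len < 16L || spacer_len > 20L) {
    stop("spacer_len must be a single integer in [16, 20]", call. = FALSE)
  }
  spacer_len <- as.integer(spacer_len)
  policy <- match.arg(policy)

  pams <- find_pam_sites(s, strands = strands)
  rows <- vector("list", nrow(pams))
  n_skipped <- 0L
  for (k in seq_len(nrow(pams))) {
    p <- pams$pos[k]
    std <- pams$strand[k]
    if (std == "+") {
      if (p < spacer_len) next
      proto <- substr(s, p - spacer_len + 1L, p)          # [p-L, p) 0-based
      pam <- substr(s, p + 1L, p + 3L)
      start <- p - spacer_len
    } else {
      proto_start <- p + 3L                               # 0-based
      if (proto_start + spacer_len > nchar(s)) next
      sense_window <- substr(s, proto_start + 1L, proto_start + spacer_len)
      proto <- revcomp(sense_window)
      pam <- revcomp(substr(s, p + 1L, p + 3L))
      start <- proto_start
    }
    if (grepl("N", proto, fixed = TRUE) || grepl("N", pam, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    first <- substr(proto, 1L, 1L)
    tagged <- FALSE
    spacer <- proto
    if (policy == "require_matched_G") {
      if (first != "G") next
    } else if (policy == "prepend_g") {
      if (first != "G") {
        spacer <- paste0("g", proto)
        tagged <- TRUE
      }
    }
    label <- start + as.integer(site_offset)
    nm <- sprintf("%s_site%d_%dnt%s", name_prefix, label, spacer_len,
                  if (tagged) "g" else "")
    rows[[k]] <- new_guide(nm, label, std, start, spacer, spacer_len,
                           pam, tagged)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " candidate site(s) overlapping N were skipped",
            call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(
      name = character(0), site_label = integer(0), strand = character(0),
      start = integer(0), spacer = character(0), matched_len = integer(0),
      total_len = integer(0), pam = character(0),
      five_prime_tagged = logical(0), three_prime_pref = logical(0),
      effective_flag = logical(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncate a full-length guide to a shorter PAM-proximal spacer
#'
#' Returns the same guide shortened from its PAM-distal (5') end, i.e.
#' the spacer becomes the PAM-proximal `new_len` suffix. PAM, strand and
#' target site are unchanged; the effectiveness flag is recomputed.
#' Only untagged guides can be truncated.
#'
#' @param guide a one-row guide data.frame as returned by
#'   [design_guides()].
#' @param new_len target matched length, `16 <= new_len <= matched_len`.
#' @return a one-row guide data.frame.
#' @examples
#' g <- design_guides("GCCGTCCAGCTCGACCAGGATGG", 20,
#'                    policy = "require_matched_G", strands = "+")
#' truncate_guide(g, 17)$spacer  # "GTCCAGCTCGACCAGGA"
#' @export
truncate_guide <- function(guide, new_len) {
  guide <- as_guide_row(guide)
  if (isTRUE(guide$five_prime_tagged)) {
    stop("cannot truncate a g-tagged guide; design at the shorter length ",
         "with policy 'prepend_g' instead", call. = FALSE)
  }
  if (!is.numeric(new_len) || length(new_len) != 1L) {
    stop("new_len must be a single integer", call. = FALSE)
  }
  new_len <- as.integer(new_len)
  if (new_len < 16L) stop("new_len must be >= 16", call. = FALSE)
  if (new_len > guide$matched_len) {
    stop("new_len exceeds the guide's matched length", call. = FALSE)
  }
  old <- guide$matched_len
  spacer <- substr(guide$spacer, old - new_len + 1L, old)
  start <- if (guide$strand == "+") guide$start + (old - new_len) else guide$start
  label <- guide$site_label
  nm <- sub("_\\d+nt$", "", guide$name)
  new_guide(sprintf("%s_%dnt", nm, new_len), label, guide$strand, start,
            spacer, new_len, guide$pam, FALSE)
}

#' @keywords internal
#' @noRd
as_guide_row <- function(guide) {
  if (is.character(guide) && length(guide) == 1L) {
    # bare spacer string: build a minimal anonymous guide
    sp <- guide
    body <- toupper(sub("^g", "", sp))
    tagged <- grepl("^g", sp)
    body <- as_dna_string(body, allow_n = FALSE, what = "spacer")
    return(new_guide("guide", 1L, "+", 0L,
                     if (tagged) paste0("g", body) else body,
                     nchar(body), "NGG", tagged))
  }
  if (!is.data.frame(guide) || nrow(guide) != 1L) {
    stop("expected a single guide (one-row data.frame or spacer string)",
         call. = FALSE)
  }
  guide
}

#' Matched (genomic) portion of a spacer, uppercase
#'
#' Strips the mismatched 5' g tag if present.
#'
#' @param guide one-row guide data.frame or spacer string.
#' @return uppercase matched spacer string.
#' @export
matched_spacer <- function(guide) {
  guide <- as_guide_row(guide)
  sp <- guide$spacer
  if (isTRUE(guide$five_prime_tagged)) sp <- substr(sp, 2L, nchar(sp))
  toupper(sp)
}

#' Predicted SpCas9 cut site for a guide
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM. The value is the 0-based
#' sense-strand coordinate of the first base 3' of the cut (the cut
#' falls between `cut - 1` and `cut`).
#'
#' @param guide one-row guide data.frame.
#' @return integer 0-based coordinate.
#' @export
guide_cut_site <- function(guide) {
  guide <- as_guide_row(guide)
  if (guide$strand == "+") {
    guide$start + guide$matched_len - 3L
  } else {
    guide$start + 3L
  }
}

SGRNA_TEMPLATE_5P <- "TATATATCTTGTGGAAAGGACGAAACACCG"
SGRNA_TEMPLATE_3P <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAAT"
SGRNA_FWD_PRIMER <- "TATATATCTTGTGGAAAGGACGAA"
SGRNA_REV_PRIMER <- "ATTTTAACTTGCTATTTCTAGCTCTAA"

#' Build the Gibson-assembly synthesis template and primers for a guide
#'
#' The synthesis template places the spacer minus its leading G (the
#' template's trailing `...ACACCG` supplies that G) between two fixed
#' arms, ready for PCR with the standard forward/reverse primers and
#' Gibson assembly into a BbsI-cut U6 sgRNA backbone.
#'
#' @param guide one-row guide data.frame or spacer string beginning with
#'   G (or a mismatched lowercase g).
#' @return list with `template`, `insert`, `fwd_primer`, `rev_primer`.
#' @examples
#' build_cloning_oligos("GTCCAGCTCGACCAGGA")$insert  # 16 nt
#' @export
build_cloning_oligos <- function(guide) {
  guide <- as_guide_row(guide)
  sp <- guide$spacer
  if (!substr(sp, 1L, 1L) %in% c("G", "g")) {
    stop("spacer must begin with G (or a mismatched g); redesign with ",
         "policy 'prepend_g' to supply one", call. = FALSE)
  }
  insert <- toupper(substr(sp, 2L, nchar(sp)))
  if (nchar(insert) < 16L || nchar(insert) > 19L) {
    stop("insert length ", nchar(insert), " outside the synthesisable ",
         "range 16-19 nt", call. = FALSE)
  }
  list(
    template = paste0(SGRNA_TEMPLATE_5P, insert, SGRNA_TEMPLATE_3P),
    insert = insert,
    fwd_primer = SGRNA_FWD_PRIMER,
    rev_primer = SGRNA_REV_PRIMER
  )
}

#' Write designed guides to a TSV file
#'
#' @param guides guide data.frame from [design_guides()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(guides, path) {
  write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide TSV written by [write_guides_tsv()]
#'
#' @param path input path.
#' @return guide data.frame.
#' @export
read_guides_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
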