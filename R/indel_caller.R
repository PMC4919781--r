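## Indel calling from Sanger-style clone sequences. Each clone is
## globally aligned to the reference amplicon with an affine-gap
## Needleman-Wunsch aligner (leftmost co-optimal gap placement), indel
## events near the predicted cut site are extracted, and the clone's
## reading frame is classified from the net inserted-minus-deleted
## length. Scoring defaults (match +2, mismatch -4, gap open -8, gap
## extend -1) consolidate scattered differences into single gaps, which
## suits NHEJ alleles.

#' Globally align a clone read to a reference amplicon
#'
#' Optimal global alignment under affine gap scoring; a gap of length k
#' costs `gap_open + k * gap_extend`. Among co-optimal alignments, gaps
#' are placed at their leftmost reference position. `N` is
#' mismatch-neutral (scores 0, never counts as a match).
#'
#' @param read,ref non-empty DNA strings (A/C/G/T/N).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return an object of class `truncguide_alignment`: list with `score`,
#'   `ops` (one character per alignment column: M match, X mismatch,
#'   I insertion in the read, D deletion from the reference), `cigar`,
#'   `identity_fraction` (matches / alignment columns), `read`, `ref`.
#' @examples
#' align_to_reference("ACGTAC", "ACGTTAC")$cigar
#' @export
align_to_reference <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -8, gap_extend = -1) {
  read <- as_dna_string(read, allow_n = TRUE, what = "read")
  ref <- as_dna_string(ref, allow_n = TRUE, what = "ref")
  if (nchar(read) == 0L || nchar(ref) == 0L) {
    stop("read and ref must be non-empty", call. = FALSE)
  }
  res <- align_affine_cpp(read, ref, match, mismatch, gap_open, gap_extend)
  ops <- res$ops
  rl <- rle(seq_chars(ops))
  structure(list(
    score = res$score,
    ops = ops,
    cigar = paste0(rl$lengths, rl$values, collapse = ""),
    identity_fraction = sum(seq_chars(ops) == "M") / nchar(ops),
    read = read, ref = ref
  ), class = "truncguide_alignment")
}

#' @export
print.truncguide_alignment <- function(x, ...) {
  cat("Global alignment: score ", x$score, ", ", x$cigar,
      ", identity ", round(x$identity_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Extract indel events near the cut site from an alignment
#'
#' Walks the alignment and reports each insertion or deletion run whose
#' left edge lies within `window` nucleotides of `cut_site`. Events
#' outside the window (e.g. distal clone polymorphisms) are dropped.
#'
#' @param alignment a `truncguide_alignment` from [align_to_reference()].
#' @param cut_site 0-based reference coordinate of the predicted cut
#'   (see [guide_cut_site()]).
#' @param window maximum distance (nt) of an event's left edge from the
#'   cut site; default 20.
#' @return data.frame with columns `kind` ("insertion"/"deletion"),
#'   `length`, `ref_pos` (0-based left edge) and `offset_from_cut`.
#' @export
call_indels <- function(alignment, cut_site, window = 20L) {
  stopifnot(inherits(alignment, "truncguide_alignment"))
  if (window < 0L) stop("window must be >= 0", call. = FALSE)
  if (cut_site < 0L || cut_site > nchar(alignment$ref)) {
    stop("cut_site outside the reference", call. = FALSE)
  }
  ev <- alignment_events(alignment)
  keep <- abs(ev$ref_pos - cut_site) <= window
  ev <- ev[keep, , drop = FALSE]
  ev$offset_from_cut <- ev$ref_pos - as.integer(cut_site)
  rownames(ev) <- NULL
  ev
}

#' @keywords internal
#' @noRd
alignment_events <- function(alignment) {
  rl <- rle(seq_chars(alignment$ops))
  kind <- character(0); len <- integer(0); pos <- integer(0)
  ref_pos <- 0L
  for (k in seq_along(rl$values)) {
    v <- rl$values[k]; l <- rl$lengths[k]
    if (v %in% c("M", "X")) {
      ref_pos <- ref_pos + l
    } else if (v == "D") {
      kind <- c(kind, "deletion"); len <- c(len, l); pos <- c(pos, ref_pos)
      ref_pos <- ref_pos + l
    } else if (v == "I") {
      kind <- c(kind, "insertion"); len <- c(len, l); pos <- c(pos, ref_pos)
    }
  }
  data.frame(kind = kind, length = len, ref_pos = pos,
             stringsAsFactors = FALSE)
}

#' Classify the reading frame of a clone call
#'
#' A clone with no (windowed) events is `unedited`; an edited clone is
#' `in_frame` when its net indel length is a multiple of 3 and
#' `frameshift` otherwise. The classification depends only on the net
#' length modulo 3, never on event order.
#'
#' @param call a clone call from [call_clone()], or a numeric net indel
#'   length (insertions minus deletions), in which case `n_events` must
#'   be given.
#' @param n_events number of events (only when `call` is numeric).
#' @return one of `"unedited"`, `"in_frame"`, `"frameshift"`.
#' @export
classify_frame <- function(call, n_events = NULL) {
  if (is.list(call) && !is.null(call$events)) {
    net <- call$net_length
    n_events <- nrow(call$events)
  } else {
    net <- as.numeric(call)
    if (is.null(n_events)) {
      stop("n_events is required when passing a bare net length",
           call. = FALSE)
    }
  }
  if (n_events == 0L) return("unedited")
  if (net %% 3 == 0) "in_frame" else "frameshift"
}

#' Align one clone and call its indels and frame class
#'
#' @param read clone sequence.
#' @param ref reference amplicon.
#' @param cut_site 0-based cut coordinate.
#' @param window calling window around the cut (nt).
#' @param min_identity clones aligning below this identity fraction are
#'   flagged unalignable and excluded from cohort profiles.
#' @param clone_id label.
#' @param ... scoring parameters passed to [align_to_reference()].
#' @return list with `clone_id`, `events` (windowed, from
#'   [call_indels()]), `n_distal_events`, `net_length`, `frame_class`,
#'   `identity_fraction`, `unalignable`.
#' @export
call_clone <- function(read, ref, cut_site, window = 20L,
                       min_identity = 0.8, clone_id = "clone", ...) {
  aln <- align_to_reference(read, ref, ...)
  all_ev <- alignment_events(aln)
  ev <- call_indels(aln, cut_site, window)
  net <- sum(ev$length[ev$kind == "insertion"]) -
    sum(ev$length[ev$kind == "deletion"])
  list(
    clone_id = clone_id,
    events = ev,
    n_distal_events = nrow(all_ev) - nrow(ev),
    net_length = as.integer(net),
    frame_class = classify_frame(net, n_events = nrow(ev)),
    identity_fraction = aln$identity_fraction,
    unalignable = aln$identity_fraction < min_identity
  )
}

#' Call a set of clones against one reference
#'
#' @param reads named character vector (or FASTA path) of clone
#'   sequences.
#' @param ref reference amplicon.
#' @inheritParams call_clone
#' @param ... passed to [call_clone()].
#' @return list of clone calls.
#' @export
call_clones <- function(reads, ref, cut_site, window = 20L,
                        min_identity = 0.8, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fasta(reads)
  }
  if (is.null(names(reads))) names(reads) <- paste0("clone", seq_along(reads))
  lapply(names(reads), function(id) {
    call_clone(reads[[id]], ref, cut_site, window = window,
               min_identity = min_identity, clone_id = id, ...)
  })
}

#' Summarise a cohort of clone calls
#'
#' Aggregates windowed events across alignable clones: deletion vs
#' insertion fractions, event lengths binned as 1 bp / 2-8 bp / >= 9 bp
#' (the 9 bp boundary is assigned to the upper bin), median and mean
#' event length, and the frameshift fraction among edited clones. Both
#' the number of events and the number of edited clones are reported.
#'
#' @param calls list of clone calls from [call_clones()].
#' @return list with `n_clones`, `n_unalignable`, `n_edited`,
#'   `n_events`, `deletion_fraction`, `insertion_fraction`,
#'   `length_bin_counts` (named: "1bp", "2-8bp", ">=9bp"),
#'   `median_indel_length`, `mean_indel_length`, `frameshift_fraction`.
#' @export
summarize_cohort <- function(calls) {
  if (length(calls) == 0L) stop("empty cohort", call. = FALSE)
  unaln <- vapply(calls, function(x) isTRUE(x$unalignable), logical(1))
  kept <- calls[!unaln]
  events <- do.call(rbind, lapply(kept, `[[`, "events"))
  n_events <- if (is.null(events)) 0L else nrow(events)
  lens <- if (n_events) events$length else integer(0)
  bins <- c("1bp" = sum(lens == 1L),
            "2-8bp" = sum(lens >= 2L & lens <= 8L),
            ">=9bp" = sum(lens >= 9L))
  frames <- vapply(kept, `[[`, character(1), "frame_class")
  edited <- frames != "unedited"
  list(
    n_clones = length(kept),
    n_unalignable = sum(unaln),
    n_edited = sum(edited),
    n_events = n_events,
    deletion_fraction = if (n_events) mean(events$kind == "deletion") else NA_real_,
    insertion_fraction = if (n_events) mean(events$kind == "insertion") else NA_real_,
    length_bin_counts = bins,
    median_indel_length = if (n_events) median(lens) else NA_real_,
    mean_indel_length = if (n_events) mean(lens) else NA_real_,
    frameshift_fraction = if (any(edited)) mean(frames[edited] == "frameshift") else 0
  )
}
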