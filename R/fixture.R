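## Bundled site-table fixture: the published on-target/off-target site
## list for the four GFP-reporter guides (sites 42, 101, 261, 379),
## transcribed as plain sequences. Each row carries the full-length
## site with PAM, the PAM-proximal 17 nt site with PAM, and the
## measured indel percentage (or ND, not detected) for three cell lines
## under the 20 nt and 17 nt guides. The degenerate first PAM base is
## stored lowercase, as printed; all comparisons are case-insensitive.

#' Path to the bundled on/off-target site fixture
#' @return file path of `table1_sites.tsv`.
#' @export
table1_fixture_path <- function() {
  system.file("extdata", "table1_sites.tsv", package = "truncguide",
              mustWork = TRUE)
}

#' Read the bundled on/off-target site table
#'
#' @param path fixture path (defaults to the bundled table).
#' @return data.frame with columns `target_id`, `guide` (e.g. "sgGFP42"),
#'   `is_on_target`, `seq20_pam`, `seq17_pam`, `spacer20`, `spacer17`,
#'   `pam` (uppercase), and six measurement columns
#'   (`indel_<cellline>_<len>`, character: a percentage or "ND").
#' @export
read_site_table <- function(path = table1_fixture_path()) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "seq20_pam", "seq17_pam") %in% names(tab)))
  tab$guide <- sub("-(On|Off\\d+)$", "", tab$target_id)
  tab$is_on_target <- grepl("-On$", tab$target_id)
  strip_pam <- function(x) toupper(substr(x, 1L, nchar(x) - 3L))
  tab$spacer20 <- strip_pam(tab$seq20_pam)
  tab$spacer17 <- strip_pam(tab$seq17_pam)
  tab$pam <- toupper(substr(tab$seq20_pam, nchar(tab$seq20_pam) - 2L,
                            nchar(tab$seq20_pam)))
  tab
}

#' Mismatch profiles of every candidate site in a site table
#'
#' Compares each off-target row against its guide's on-target spacer
#' over the full 20 nt and PAM-proximal 17 nt windows.
#'
#' @param tab site table from [read_site_table()].
#' @return the candidate rows of `tab` with added integer columns `m20`
#'   and `m17`.
#' @export
site_table_profiles <- function(tab) {
  on <- tab[tab$is_on_target, , drop = FALSE]
  off <- tab[!tab$is_on_target, , drop = FALSE]
  prof <- t(vapply(seq_len(nrow(off)), function(i) {
    ref <- on$spacer20[match(off$guide[i], on$guide)]
    windowed_mismatch_profile(ref, off$spacer20[i])
  }, c(m20 = 0L, m17 = 0L)))
  off$m20 <- as.integer(prof[, "m20"])
  off$m17 <- as.integer(prof[, "m17"])
  off
}

#' Long-format measurements from a site table
#'
#' @param tab site table from [read_site_table()].
#' @return data.frame with `target_id`, `cell_line`, `guide_len`,
#'   `indel_percent` (NA where not detected) and `detected`.
#' @export
site_table_measurements <- function(tab) {
  meas_cols <- grep("^indel_", names(tab), value = TRUE)
  out <- do.call(rbind, lapply(meas_cols, function(cl) {
    parts <- strsplit(sub("^indel_", "", cl), "_")[[1L]]
    val <- tab[[cl]]
    data.frame(target_id = tab$target_id,
               cell_line = parts[1L],
               guide_len = parts[2L],
               indel_percent = suppressWarnings(as.numeric(val)),
               detected = val != "ND",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
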