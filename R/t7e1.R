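## T7 endonuclease I quantification. Reannealed heteroduplexes carrying
## an indel are cleaved; the fraction of cleaved gel signal f_c relates
## to the indel frequency through
##   % indel = 100 * (1 - sqrt(1 - f_c)),
## the probability that a random duplex pairs two alleles that differ.

#' Fraction cleaved from gel band intensities
#'
#' @param uncut intensity of the uncleaved band (arbitrary units).
#' @param cut numeric vector of cleavage-product band intensities.
#' @return proportion `sum(cut) / (uncut + sum(cut))` in `[0, 1]`; 1 is
#'   returned with a warning when `uncut` is 0, where the indel
#'   conversion is undefined.
#' @examples
#' fraction_cleaved(50, c(30, 20))  # 0.5
#' @export
fraction_cleaved <- function(uncut, cut) {
  if (any(c(uncut, cut) < 0)) stop("negative band intensity", call. = FALSE)
  tot <- uncut + sum(cut)
  if (tot <= 0) stop("all band intensities are zero", call. = FALSE)
  f <- sum(cut) / tot
  if (uncut == 0) {
    warning("uncut band is 0: fraction cleaved = 1, outside the domain of ",
            "the indel conversion", call. = FALSE)
  }
  f
}

#' Convert fraction cleaved to indel percentage
#'
#' `100 * (1 - sqrt(1 - f_c))`: strictly increasing and concave on
#' `[0, 1)` with derivative 50 at 0.
#'
#' @param f_c fraction cleaved, in `[0, 1)`.
#' @return indel percentage in `[0, 100)`.
#' @examples
#' indel_percent(0.19)  # 10
#' @export
indel_percent <- function(f_c) {
  if (any(f_c < 0 | f_c >= 1)) {
    stop("fraction cleaved must lie in [0, 1)", call. = FALSE)
  }
  100 * (1 - sqrt(1 - f_c))
}

#' Invert the indel-percentage formula
#'
#' Algebraic inverse used by the simulator:
#' `f_c = 1 - (1 - p/100)^2`.
#'
#' @param p indel percentage in `[0, 100)`.
#' @return fraction cleaved.
#' @examples
#' invert_indel_percent(10)  # 0.19
#' @export
invert_indel_percent <- function(p) {
  if (any(p < 0 | p >= 100)) {
    stop("indel percentage must lie in [0, 100)", call. = FALSE)
  }
  1 - (1 - p / 100)^2
}

#' Detection call for a measured indel percentage
#'
#' @param p indel percentage.
#' @param threshold detection threshold (percent); values at or above it
#'   are "detected", below it "ND" (not detected). The default 2 is a
#'   conservative floor well under typical positive T7E1 readouts.
#' @return "detected" or "ND".
#' @export
call_detection <- function(p, threshold = 2) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  ifelse(p >= threshold, "detected", "ND")
}

#' Quantify a table of T7E1 band intensities
#'
#' @param bands data.frame with columns `site_id`, `uncut`, and one or
#'   more `cut*` columns.
#' @param nd_threshold detection threshold passed to [call_detection()].
#' @return data.frame with `site_id`, `fraction_cleaved`,
#'   `indel_percent` and `detected` ("detected"/"ND").
#' @export
quantify_t7e1 <- function(bands, nd_threshold = 2) {
  stopifnot(is.data.frame(bands), all(c("site_id", "uncut") %in% names(bands)))
  cut_cols <- grep("^cut", names(bands), value = TRUE)
  if (length(cut_cols) == 0L) stop("no cut band columns", call. = FALSE)
  f <- vapply(seq_len(nrow(bands)), function(i) {
    cuts <- as.numeric(bands[i, cut_cols])
    fraction_cleaved(bands$uncut[i], cuts[!is.na(cuts)])
  }, numeric(1))
  p <- indel_percent(pmin(f, 1 - 1e-12))
  data.frame(site_id = bands$site_id, fraction_cleaved = f,
             indel_percent = p, detected = call_detection(p, nd_threshold),
             stringsAsFactors = FALSE)
}
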