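#' Expected interocular correlation from pixel-pair statistics
#'
#' Closed-form expectation of the Pearson correlation of a random-dot
#' stereogram, given its matched/unmatched pixel-pair statistics. With
#' black dots -1, white +1 and background 0:
#'
#' * mixed polarity: only matched dot pairs contribute to `<LR>`, so
#'   `r_mixed = m * d_m / d`;
#' * same polarity (all dots equal): unmatched double-dot pairs now also
#'   contribute, and the nonzero mean luminance enters, giving
#'   `r_same = (m*d_m + u*(2*d_u - 1) - d^2) / (d * (1 - d))`.
#'
#' @param stats a [pixel_pair_stats()] / [classify_pixel_pairs()] object,
#'   or a list with fields `d`, `m`, `u`, `d_m`, `d_u`.
#' @param polarity `"mixed"` or `"same"`.
#' @return the expected correlation (a scalar `<= 1`).
#' @export
expected_r <- function(stats, polarity = c("mixed", "same")) {
  polarity <- match.arg(polarity)
  d <- stats$d; m <- stats$m; u <- stats$u
  if (d <= 0 || d >= 1)
    stop("division-domain error: expected_r() requires 0 < d < 1")
  if (u == 0 || is.na(stats$d_u)) {
    # no unmatched pairs: fully correlated, r = 1 for both polarities
    if (polarity == "mixed") return(m * stats$d_m / d)
    return((m * stats$d_m - d^2) / (d * (1 - d)))
  }
  if (polarity == "mixed") {
    m * stats$d_m / d
  } else {
    (m * stats$d_m + u * (2 * stats$d_u - 1) - d^2) / (d * (1 - d))
  }
}

#' Conditional dot probability of unmatched pairs under free scatter
#'
#' When dots are scattered entirely at random (overlap allowed), the
#' probability that an unmatched left-eye dot pixel has any dot in the
#' right eye equals the overall coverage `d`, which fixes
#' `d_u = 1 / (2 - d)`.
#'
#' @param d dot coverage in `[0, 1)`.
#' @return a value in `[0.5, 1)`.
#' @export
du_overlap <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0 | d >= 1)) stop("du_overlap() requires 0 <= d < 1")
  1 / (2 - d)
}

#' Expected correlation under free scatter (both polarities)
#'
#' Substituting `d_u = 1/(2 - d)` into the general expressions collapses
#' mixed- and same-polarity expectations onto one value,
#' `1 - u / (d * (2 - d))`. Free scatter therefore yields no
#' mixed-polarity advantage.
#'
#' @param u unmatched-pair probability in `[0, 1]`.
#' @param d dot coverage in `(0, 1)`.
#' @export
r_overlap <- function(u, d) {
  stopifnot(is.numeric(u), is.numeric(d))
  if (any(d <= 0 | d >= 1)) stop("r_overlap() requires 0 < d < 1")
  if (any(u < 0 | u > 1)) stop("r_overlap() requires 0 <= u <= 1")
  1 - u / (d * (2 - d))
}

#' Expected correlation in the extreme no-overlap regime
#'
#' When overlap is forbidden and noise dots can only land on double
#' background, `d_u` attains its lower bound 0.5, and
#' `r_mixed = 1 - u/(2d)` while `r_same = 1 - u/(2d(1 - d))`. The
#' same-polarity value is strictly lower for any `u > 0`: this is the
#' stimulus-construction artefact that penalizes same-polarity patterns.
#'
#' @inheritParams r_overlap
#' @param polarity `"mixed"` or `"same"`.
#' @export
r_limit_no_overlap <- function(u, d, polarity = c("mixed", "same")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(u), is.numeric(d))
  if (any(d <= 0 | d >= 1)) stop("r_limit_no_overlap() requires 0 < d < 1")
  if (any(u < 0 | u > 1)) stop("r_limit_no_overlap() requires 0 <= u <= 1")
  if (polarity == "mixed") 1 - u / (2 * d) else 1 - u / (2 * d * (1 - d))
}
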