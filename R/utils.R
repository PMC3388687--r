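#' Round half away from zero
#'
#' Rounding convention used when converting log odds ratios to integer points:
#' 0.5 rounds to 1, -0.5 rounds to -1 (unlike [round()], which rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(0.49, 0.5, 1.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Snap a cut-point to a "convenient" value
#'
#' Replaces a numeric boundary with the nearest value having the fewest
#' significant digits, provided the relative change does not exceed `rel_tol`.
#' Ties between the two nearest candidates at a given resolution go to the
#' smaller magnitude. Used when rounding exact quintile boundaries for the
#' printed score table (e.g. 19.8 -> 20, 27.9 -> 28, 397 -> 400).
#'
#' @param b Numeric scalar boundary (finite).
#' @param rel_tol Maximum allowed relative displacement (default 0.05).
#' @return Snapped numeric scalar (equal to `b` if no coarser value qualifies).
#' @export
snap_convenient <- function(b, rel_tol = 0.05) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (b == 0) return(0)
  for (digits in 1:3) {
    scale <- 10^(floor(log10(abs(b))) - digits + 1)
    lo <- floor(b / scale) * scale
    hi <- ceiling(b / scale) * scale
    cand <- if (abs(b - lo) <= abs(hi - b)) lo else hi
    if (abs(cand - b) <= rel_tol * abs(b)) return(cand)
  }
  b
}

## internal: stable per-variable sub-stream seeds so that adding a variable to
## the generator does not perturb the draws of existing ones
stream_seed <- function(seed, stream) {
  offsets <- c(
    age = 1L, apache2 = 2L, sofa = 3L, days_hosp_to_icu = 4L, bmi = 5L,
    n_comorbid = 6L, il6 = 7L, crp = 8L, pct = 9L, oral_intake_pct = 10L,
    weight_loss_pct = 11L, mort28 = 12L, mv = 13L, icu = 14L,
    energy = 15L, adequacy = 16L, missing = 17L, noise = 18L, split = 19L
  )
  if (!stream %in% names(offsets)) {
    stop("unknown random sub-stream: ", stream)
  }
  (as.integer(seed) %% 65521L) * 32003L + offsets[[stream]]
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(seed, stream))
  expr
}

## internal: format an interval row label the way the printed table does
interval_label <- function(lower, upper, integer_valued = FALSE) {
  if (!is.finite(lower) && !is.finite(upper)) return("ALL")
  if (!is.finite(lower)) return(paste0("< ", format(upper)))
  if (!is.finite(upper)) return(paste0(format(lower), "+"))
  if (integer_valued && upper - 1 >= lower) {
    if (upper - 1 == lower) return(format(lower))
    return(paste0(format(lower), "-", format(upper - 1)))
  }
  paste0(format(lower), "-< ", format(upper))
}
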