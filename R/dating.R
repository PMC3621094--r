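#' LTR-pair divergence (uncorrected p-distance)
#'
#' The two LTRs of a provirus are identical at integration, so the
#' proportion of sites at which they differ clocks the age of the insertion.
#' The LTRs are globally aligned (match +1, mismatch -3, gap costs 5/2, the
#' same scoring used by the self-alignment repeat search); columns
#' containing a gap or an N are excluded and D is the fraction of the
#' retained columns that mismatch. No multiple-hit correction is applied
#' ("number of differences per site").
#'
#' @param ltr5,ltr3 the two LTR sequences.
#' @return list of class `divergence_result`: `D`, `aligned_sites`
#'   (retained columns), `differences`, `excluded` (gap/N columns). `D` is
#'   NA when no column is retained.
#' @export
ltr_divergence <- function(ltr5, ltr3) {
  stopifnot(nchar(ltr5) > 0, nchar(ltr3) > 0)
  al <- align_dna(ltr5, ltr3, type = "global")
  a <- seq_chars(al$a_aln); b <- seq_chars(al$b_aln)
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  n_keep <- sum(keep)
  diffs <- sum(a[keep] != b[keep])
  structure(list(
    D = if (n_keep == 0) NA_real_ else diffs / n_keep,
    aligned_sites = n_keep, differences = diffs,
    excluded = length(a) - n_keep), class = "divergence_result")
}

#' Default clade substitution rates
#'
#' Genomic substitution rates (substitutions/site/year) used to convert LTR
#' divergence into an integration age. These are configuration constants,
#' not estimates made by this package: Bayesian rate estimation is out of
#' scope, and the defaults are back-calculated from published
#' divergence/age pairs for a megabat and a microbat ERV so that
#' T = (D/R)/2 reproduces the published ages.
#'
#' @return named numeric vector (per clade).
#' @export
default_rates <- function() {
  c(megabat = 0.006 / (2 * 7.5e6),   # 4.0e-10 subs/site/year
    microbat = 0.008 / (2 * 4.2e6))  # 9.52e-10 subs/site/year
}

# half-up decimal rounding for report parity (R's round() is banker's)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Integration age from LTR divergence: T = (D/R)/2
#'
#' The division by two reflects that both LTRs accumulate substitutions
#' independently after integration, so their pairwise divergence grows at
#' twice the per-lineage rate.
#'
#' @param D LTR divergence (differences per site), or a
#'   `divergence_result`.
#' @param R substitution rate (substitutions/site/year), > 0.
#' @return list of class `age_estimate`: `T_myr` (rounded half-up to one
#'   decimal), `T_myr_raw`, `T_years`, `D`, `R`. When D is undefined the
#'   estimate is "ND" (`T_myr` = NA).
#' @export
estimate_age <- function(D, R) {
  stopifnot(R > 0)
  if (inherits(D, "divergence_result")) D <- D$D
  if (is.na(D)) {
    return(structure(list(T_myr = NA_real_, T_myr_raw = NA_real_,
                          T_years = NA_real_, D = NA_real_, R = R),
                     class = "age_estimate"))
  }
  stopifnot(D >= 0, D <= 1)
  t_years <- (D / R) / 2
  t_myr <- t_years / 1e6
  structure(list(T_myr = round_half_up(t_myr, 1L), T_myr_raw = t_myr,
                 T_years = t_years, D = D, R = R), class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  if (is.na(x$T_myr)) cat("<age_estimate> ND (divergence undefined)\n")
  else cat(sprintf("<age_estimate> D = %.4g, R = %.3g /site/yr -> T = %.1f Myr\n",
                   x$D, x$R, x$T_myr))
  invisible(x)
}
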