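#' Noise statistic psi of a sample's joint mismatch matrix
#'
#' psi is the variance-to-mean ratio of the X matrix cells in the
#' low-Phred band (row values 1 to 2/5 of the Phred range, all mismatch
#' columns).  A sample whose low-Phred counts are concentrated (high
#' psi) carries strong evidence about its own boundary fraction; a flat,
#' sparse band (low psi) means the sample should borrow strength from
#' the cohort.
#'
#' @param X integer matrix from [buildJointMatrices()].
#' @return psi (variance/mean over the band; 0 when the band mean is 0,
#'   in which case the cohort correction falls back entirely to the
#'   cohort mean, with a message).
#' @export
computePsi <- function(X) {
  p <- nrow(X) - 1L
  hi <- floor(2 / 5 * p)
  if (hi < 1L) return(0)
  cells <- X[1L + (1:hi), , drop = FALSE]   # row values 1..2p/5
  mu <- mean(cells)
  if (mu == 0) {
    message("empty low-Phred band: psi = 0, deferring to the cohort mean")
    return(0)
  }
  sigma <- mean((cells - mu)^2)
  sigma / mu
}

#' Cohort-weighted correction of boundary fractions
#'
#' Shrinks every sample's observed boundary fraction
#' theta_obs = F2a / (F2 + F4) towards the cohort mean theta_exp with
#' sample-specific weight psi: theta_cor = (theta_obs * psi +
#' theta_exp * w) / (psi + w).  High-psi samples keep their own
#' estimate; low-psi samples defer to the cohort.  The adjusted boundary
#' count is theta_cor * (F2 + F4).  With a single sample the correction
#' is disabled.  \code{strictDenominator = TRUE} divides by psi * w instead
#' of psi + w; that form is not a weighted average (equal-theta cohorts
#' are not a fixed point) and is provided for strict comparison only.
#'
#' @param cohort data.frame with columns \code{sample_id}, \code{F2},
#'   \code{F4}, \code{F2a} and \code{psi}.
#' @param w cohort weight (default 3).
#' @param strictDenominator use the non-normalised denominator psi * w.
#' @return the input with columns \code{theta_obs}, \code{theta_exp},
#'   \code{theta_cor} and \code{F2a_adjusted} added.
#' @export
correctTheta <- function(cohort, w = 3, strictDenominator = FALSE) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "F2", "F4", "F2a", "psi") %in%
                names(cohort)))
  if (!nrow(cohort)) stop("empty cohort")
  denom <- cohort$F2 + cohort$F4
  cohort$theta_obs <- ifelse(denom > 0, cohort$F2a / denom, 0)
  cohort$theta_exp <- mean(cohort$theta_obs)
  if (nrow(cohort) == 1L) {
    message("single-sample cohort: correction disabled")
    cohort$theta_cor <- cohort$theta_obs
  } else if (strictDenominator) {
    cohort$theta_cor <- (cohort$theta_obs * cohort$psi +
                           cohort$theta_exp * w) / (cohort$psi * w)
  } else {
    cohort$theta_cor <- (cohort$theta_obs * cohort$psi +
                           cohort$theta_exp * w) / (cohort$psi + w)
  }
  cohort$F2a_adjusted <- cohort$theta_cor * denom
  cohort
}
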