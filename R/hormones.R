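#' Simulate estradiol and progesterone across one menstrual or pill cycle
#'
#' Generates smooth hormone trajectories over the cycle-day axis. For a
#' naturally-cycling (NC) trajectory, estradiol rises to an ovulatory peak
#' near 0.46 x cycle length with a smaller mid-luteal bump, and progesterone
#' peaks near 0.75 x cycle length with low follicular values; the curves are
#' sums of Gaussian bumps over a positive baseline, parameterized so that the
#' cycle's dynamic range is roughly eight-fold for estradiol and roughly
#' eighty-fold for progesterone. Under hormonal-contraceptive (HC) use both
#' hormones are flat, low-level trajectories. Multiplicative log-normal
#' jitter emulates assay noise.
#'
#' Concentration units are arbitrary (pg/ml-like); all downstream modeling
#' scales hormone values within dataset, so only the shape and dynamic range
#' matter.
#'
#' @param cycle_length Cycle length in days, in `[21, 35]`.
#' @param hc_use Logical; `TRUE` for a hormonal-contraceptive (suppressed)
#'   trajectory.
#' @param sample_days Integer/numeric vector of days since menses onset at
#'   which to sample, each in `[0, cycle_length)`. Repeats are allowed.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param jitter_sd Standard deviation of the log-normal jitter (default
#'   0.04).
#' @return A data frame with columns `day`, `e2`, `p4` (class
#'   `"hormone_series"`), one row per element of `sample_days`.
#' @examples
#' h <- simulate_hormone_cycle(28, hc_use = FALSE, sample_days = 0:27, seed = 1)
#' max(h$e2) / min(h$e2)  # ~ 8
#' max(h$p4) / min(h$p4)  # ~ 80
#' @export
simulate_hormone_cycle <- function(cycle_length, hc_use = FALSE,
                                   sample_days = seq_len(cycle_length) - 1,
                                   seed = 1L, jitter_sd = 0.04) {
  if (!is.numeric(cycle_length) || length(cycle_length) != 1 ||
      cycle_length < 21 || cycle_length > 35) {
    stop("cycle_length must be a single value in [21, 35], got ", cycle_length)
  }
  bad <- sample_days < 0 | sample_days >= cycle_length
  if (any(bad)) {
    stop("sample day(s) outside [0, cycle_length): ",
         paste(unique(sample_days[bad]), collapse = ", "))
  }
  d <- as.numeric(sample_days)
  w <- cycle_length / 28  # widths/locations scale with cycle length

  if (isTRUE(hc_use)) {
    e2 <- rep(30, length(d))
    p4 <- rep(10, length(d))
  } else {
    bump <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))
    e2 <- 25 +
      160 * bump(d, 0.46 * cycle_length, 2.5 * w) +   # ovulatory surge
      60 * bump(d, 0.75 * cycle_length, 5.0 * w)      # mid-luteal bump
    p4 <- 1.5 +
      115 * bump(d, 0.75 * cycle_length, 4.5 * w)     # luteal peak
  }

  withr::with_seed(seed, {
    e2 <- e2 * exp(stats::rnorm(length(d), 0, jitter_sd))
    p4 <- p4 * exp(stats::rnorm(length(d), 0, jitter_sd))
  })

  structure(
    data.frame(day = d, e2 = e2, p4 = p4),
    class = c("hormone_series", "data.frame")
  )
}
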