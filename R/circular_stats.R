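# Circular descriptive statistics and a two-sample Watson U-squared test
# with a permutation null, used to compare heading and current-direction
# distributions between tracking periods.

#' Circular mean, SD and resultant length
#'
#' Mean direction from the atan2 of component sums; circular SD as
#' sqrt(-2 ln Rbar) (degrees); Rbar in [0, 1]. With Rbar = 0 (e.g. exact
#' antipodal cancellation) the mean is undefined and returned NA with
#' `defined = FALSE`.
#'
#' @param angles_rad angles in radians (any wrap).
#' @return list: `mean_deg` ([0, 360) or NA), `sd_deg`, `rbar`, `n`,
#'   `defined`.
#' @export
circ_mean_sd <- function(angles_rad) {
  angles_rad <- angles_rad[is.finite(angles_rad)]
  n <- length(angles_rad)
  if (n < 1) stop("need at least one angle")
  S <- mean(sin(angles_rad)); C <- mean(cos(angles_rad))
  rbar <- sqrt(S^2 + C^2)
  if (rbar < 1e-12)
    return(list(mean_deg = NA_real_, sd_deg = Inf, rbar = 0, n = n,
                defined = FALSE))
  list(mean_deg = wrap_deg(.rad2deg(atan2(S, C))),
       sd_deg = .rad2deg(sqrt(-2 * log(rbar))),
       rbar = rbar, n = n, defined = TRUE)
}

## Watson U^2 statistic for two circular samples (radians).
## Combined stable sort; d_k = difference of the two empirical CDFs at
## each ordered point; U2 = n*m/N^2 * (sum d^2 - (sum d)^2 / N).
.watson_stat <- function(labels_sorted, n, m) {
  N <- n + m
  d <- cumsum(labels_sorted) / n - cumsum(1 - labels_sorted) / m
  n * m / N^2 * (sum(d^2) - sum(d)^2 / N)
}

#' Two-sample Watson U-squared test with permutation p-value
#'
#' The U-squared statistic is rotation- and reflection-invariant and
#' measures the squared discrepancy between the two empirical circular
#' CDFs. Significance comes from `B` random label permutations with a
#' fixed seed: p = (b + 1) / (B + 1) with b the number of permuted
#' statistics >= the observed one. Ties in the combined sort are broken
#' stably by input order.
#'
#' @param x,y angles in radians.
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return object of class `watson_test`: `u2`, `p`, `n`, `m`, `B`,
#'   `seed`.
#' @export
watson_u2 <- function(x, y, B = 9999, seed = 1) {
  x <- x[is.finite(x)] %% (2 * pi)
  y <- y[is.finite(y)] %% (2 * pi)
  n <- length(x); m <- length(y)
  if (n < 4 || m < 4) stop("need n, m >= 4")
  if (B < 99) stop("need B >= 99 permutations")
  ang <- c(x, y)
  lab <- c(rep(1, n), rep(0, m))
  ord <- order(ang)  # stable: ties keep input order
  lab_s <- lab[ord]
  u2 <- .watson_stat(lab_s, n, m)
  if (length(unique(ang)) == 1) {
    out <- list(u2 = 0, p = 1, n = n, m = m, B = B, seed = seed)
    class(out) <- "watson_test"
    return(out)
  }
  set.seed(seed)
  N <- n + m
  b <- 0L
  for (i in seq_len(B)) {
    perm <- lab_s[sample.int(N)]
    if (.watson_stat(perm, n, m) >= u2 - 1e-12) b <- b + 1L
  }
  out <- list(u2 = u2, p = (b + 1) / (B + 1), n = n, m = m, B = B,
              seed = seed)
  class(out) <- "watson_test"
  out
}

#' @export
print.watson_test <- function(x, ...) {
  cat("Watson two-sample U2 =", signif(x$u2, 4),
      ", permutation p =", signif(x$p, 4),
      " (n =", x$n, ", m =", x$m, ", B =", x$B, ")\n")
  invisible(x)
}

#' Heading-versus-current test battery
#'
#' Runs the four period/heading contrasts on pooled daily values of
#' dispersive animals: headings period 1 vs period 2, headings vs current
#' directions within each period, and current directions period 1 vs
#' period 2. Daily values are pooled across animals within period (no
#' per-animal weighting); empty groups skip their contrast with a note.
#'
#' @param headings named list (one element per period) of heading vectors,
#'   degrees.
#' @param currents named list (same periods) of current-direction vectors,
#'   degrees.
#' @param B,seed permutation settings passed to [watson_u2()].
#' @return data.frame: `contrast`, `u2`, `p`, `n`, `m` (NA rows for
#'   skipped contrasts, with `note`).
#' @export
heading_current_contrast <- function(headings, currents, B = 9999,
                                     seed = 1) {
  periods <- names(headings)
  res <- list()
  add <- function(name, a, b, s) {
    if (length(a) < 4 || length(b) < 4) {
      res[[length(res) + 1]] <<- data.frame(
        contrast = name, u2 = NA, p = NA, n = length(a), m = length(b),
        note = "skipped: group too small")
      return()
    }
    w <- watson_u2(.deg2rad(a), .deg2rad(b), B = B, seed = s)
    res[[length(res) + 1]] <<- data.frame(
      contrast = name, u2 = w$u2, p = w$p, n = w$n, m = w$m, note = "")
  }
  if (length(periods) >= 2) {
    add(paste0("headings:", periods[1], "-vs-", periods[2]),
        headings[[1]], headings[[2]], seed)
    add(paste0("currents:", periods[1], "-vs-", periods[2]),
        currents[[1]], currents[[2]], seed + 1L)
  }
  for (k in seq_along(periods))
    add(paste0("headings-vs-currents:", periods[k]),
        headings[[k]], currents[[k]], seed + 1L + k)
  do.call(rbind, res)
}
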