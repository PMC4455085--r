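#' Laser-transmission W statistic (Tier II, CoDI)
#'
#' A 405-nm laser is passed through the tablet and the transmitted intensity
#' is read by a photoresistor twice: unfiltered (`I`) and through a red
#' filter (`I_filter`). The device statistic is
#' `W = (I - I_filter) / (I_filter / I)`, implemented exactly in that printed
#' form (algebraically `I * (I - I_filter) / I_filter`). `W` is zero when the
#' filter removes nothing, negative when the filtered reading exceeds the
#' open one, and scales homogeneously: `W(kI, kI_f) = k W(I, I_f)`.
#'
#' @param intensity_open Unfiltered reading(s), instrument units, `> 0`.
#' @param intensity_filtered Red-filtered reading(s), `> 0`.
#' @return Numeric W value(s).
#' @examples
#' compute_w(2, 1)      # 2
#' compute_w(1.5, 1.2)  # 0.375
#' @export
compute_w <- function(intensity_open, intensity_filtered) {
  if (any(!is.finite(intensity_open)) || any(!is.finite(intensity_filtered)))
    stopf("intensities must be finite")
  if (any(intensity_open <= 0) || any(intensity_filtered <= 0))
    stopf("intensities must be > 0")
  (intensity_open - intensity_filtered) / (intensity_filtered / intensity_open)
}

#' Authentic W reference range
#'
#' The inclusive `[min, max]` of W over a set of authentic tablets;
#' counterfeits are flagged as falling outside the range observed for
#' authentics.
#'
#' @param w W values of at least two authentic tablets.
#' @return An object of class `reference_range`: list with `lo`, `hi`, `n`.
#' @examples
#' codi_reference_range(c(1.30, 1.88, 3.25))
#' @export
codi_reference_range <- function(w) {
  if (!is.numeric(w) || length(w) < 2L) stopf("need at least 2 authentic W values")
  if (any(!is.finite(w))) stopf("W values must be finite")
  structure(list(lo = min(w), hi = max(w), n = length(w)),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("Authentic W range: [%.2f, %.2f] (n = %d)\n", x$lo, x$hi, x$n))
  invisible(x)
}

#' Tier II screen of W against the authentic range
#'
#' Pass iff `lo <= w <= hi` (endpoints inclusive). Vectorised over `w`.
#'
#' @param w W value(s) to screen.
#' @param ref A [codi_reference_range()] object, or a list with `lo` and
#'   `hi`.
#' @return Character vector in `{"pass", "fail"}`.
#' @examples
#' ref <- codi_reference_range(c(1.30, 3.25))
#' range_screen(c(0.30, 1.88), ref)  # "fail" "pass"
#' @export
range_screen <- function(w, ref) {
  if (is.null(ref$lo) || is.null(ref$hi) || ref$lo > ref$hi)
    stopf("`ref` must provide lo <= hi")
  ifelse(w >= ref$lo & w <= ref$hi, "pass", "fail")
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided Mann-Whitney test of two independent groups. The U statistic is
#' the number of pairs `(a, b)` with `a > b` plus half the tied pairs
#' (equivalently the mid-rank sum of group A minus `n_a(n_a+1)/2`). The exact
#' null distribution is computed over all `choose(n, n_a)` equally likely
#' assignments of the observed (mid-)ranks — evaluated by a
#' generating-function recursion rather than explicit enumeration, so ties
#' are handled exactly. The two-sided p doubles the smaller tail
#' (including the observed value), capped at 1. For larger samples a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_b Numeric observations, both non-empty.
#' @param mode `"auto"` (exact when `n_a + n_b <= 25`), `"exact"`, or
#'   `"normal"`.
#' @return A list with `U` (for group A), `p` (two-sided, in `(0, 1]`),
#'   `method`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided 0.1
#' @export
mann_whitney <- function(group_a, group_b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stopf("both groups must be non-empty")
  if (any(!is.finite(c(group_a, group_b)))) stopf("observations must be finite")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))           # mid-ranks for ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "auto") mode <- if (n <= 25) "exact" else "normal"
  if (mode == "exact") {
    p <- mw_exact_p(r, na, U)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      cc <- 0.5 * sign(U - mu)             # continuity correction toward the mean
      z <- (U - mu - cc) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
      if (p == 0) p <- .Machine$double.xmin
    }
    method <- "normal-approx"
  }
  list(U = U, p = p, method = method, n_a = na, n_b = nb)
}

# Exact two-sided p for the rank-sum of a size-na subset of the observed
# (mid-)ranks. Doubling the ranks makes every value an integer; f[k, s]
# counts subsets of size k-1 with doubled-rank-sum s-1, built one rank at a
# time (the coefficient array of prod_i (1 + z x^{2 r_i}) truncated at z^na).
#' @noRd
mw_exact_p <- function(r, na, U) {
  r2 <- as.integer(round(2 * r))
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  f <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    for (k in na:1) {
      src <- f[k, seq_len(smax + 1L - v)]
      nz <- which(src != 0)
      if (length(nz)) f[k + 1L, nz + v] <- f[k + 1L, nz + v] + src[nz]
    }
  }
  counts <- f[na + 1L, ]
  total <- sum(counts)
  s2 <- as.integer(round(2 * (U + na * (na + 1) / 2)))
  sums <- seq_along(counts) - 1L
  p_le <- sum(counts[sums <= s2]) / total
  p_ge <- sum(counts[sums >= s2]) / total
  min(1, 2 * min(p_le, p_ge))
}
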