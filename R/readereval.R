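#' Paired Wilcoxon signed-rank test
#'
#' Compares paired ordinal scores (e.g. DSA-only vs DSA-plus-color reader
#' confidence). Zero differences are discarded (the classical convention,
#' matching common SPSS defaults; `zero_method = "pratt"` keeps them in the
#' ranking but drops their ranks from the statistic). Ties among absolute
#' differences receive average ranks. The two-sided p-value is exact — by
#' enumeration of all `2^n` sign assignments — when the effective sample
#' size is at most `exact_max_n` and there are no ties; otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' When every difference is zero the test degenerates to `W = 0`,
#' `p = 1`, `n_effective = 0` (documented convention, no error).
#'
#' @param x,y paired numeric vectors (same length >= 1).
#' @param zero_method `"discard"` (default) or `"pratt"`.
#' @param exact_max_n largest tie-free `n_effective` for which the exact
#'   enumeration is used (default 12).
#' @return List with `statistic` (W, the sum of positive-difference ranks),
#'   `p_value` (two-sided), `n_effective` and `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 1, 2, 1, 3), c(2, 3, 4, 2, 5))  # exact p = 1/16
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("discard", "pratt"),
                                 exact_max_n = 12L) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y) || length(x) < 1L)
    stop("`x` and `y` must be paired vectors of equal length >= 1",
         call. = FALSE)
  d <- y - x
  nonzero <- d != 0
  n_eff <- sum(nonzero)
  if (n_eff == 0L)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate (all differences zero)"))
  if (zero_method == "discard") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    dd <- d[nonzero]
    r <- r_all[nonzero]
  }
  w <- sum(r[dd > 0])
  has_ties <- anyDuplicated(abs(dd)) > 0 ||
    (zero_method == "pratt" && n_eff < length(d))
  if (!has_ties && n_eff <= exact_max_n) {
    # full enumeration of sign assignments over the (integer) ranks
    ws <- vapply(0:(2^n_eff - 1), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, seq_len(n_eff) - 1L)) != 0L])
    }, numeric(1))
    p <- min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    # Var(W) = sum(r^2)/4; with average ranks this equals
    # n(n+1)(2n+1)/24 - sum(t^3 - t)/48 (the tie-corrected variance)
    sigma <- sqrt(sum(r^2) / 4)
    cc <- sign(w - mu) * 0.5
    z <- if (sigma > 0) (w - mu - cc) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, p_value = p, n_effective = as.integer(n_eff),
       method = method)
}

#' Count diagnostic reinforcement in paired reader scores
#'
#' For direction `"toward_bleeding"`, the *indeterminate* cases are those
#' the first reading did not call definite bleeding (`score_dsa < 5`);
#' among them, cases whose combined reading moved up
#' (`score_combined > score_dsa`) are *reinforced*, moves down are
#' *downgraded*, the rest *unchanged*. For `"toward_no_bleeding"` the
#' mirror definitions apply (`score_dsa > 1`, moves down reinforce). The
#' three outcome counts always partition the indeterminate set.
#'
#' @param table a [paired_scores()] table.
#' @param direction `"toward_bleeding"` or `"toward_no_bleeding"`.
#' @return List with `n_indeterminate`, `n_reinforced`, `n_downgraded`,
#'   `n_unchanged`.
#' @export
count_reinforced <- function(table, direction = c("toward_bleeding",
                                                  "toward_no_bleeding")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "paired_scores") || is.data.frame(table))
  if (nrow(table) == 0L) stop("score table is empty", call. = FALSE)
  a <- table$score_dsa; b <- table$score_combined
  if (direction == "toward_bleeding") {
    ind <- a < 5L
    reinf <- ind & (b > a)
    down <- ind & (b < a)
  } else {
    ind <- a > 1L
    reinf <- ind & (b < a)
    down <- ind & (b > a)
  }
  list(n_indeterminate = sum(ind), n_reinforced = sum(reinf),
       n_downgraded = sum(down), n_unchanged = sum(ind & !(reinf | down)))
}

#' Packaged clinical and ex-vivo score fixtures
#'
#' Three consensus-score tables shipped with the package:
#' \describe{
#'   \item{bleeding}{101 patients with clinically confirmed bleeding:
#'     46 scored 5 -> 5, 28 scored 4 -> 5, 20 scored 4 -> 4 and 7 scored
#'     3 -> 4 when the arrival-time color rendering was added.}
#'   \item{no_bleeding}{34 patients with confirmed absence of bleeding:
#'     21 scored 1 -> 1 and 13 scored 2 -> 1.}
#'   \item{ex_vivo}{22 scored bench-rig groups: 11 scored 5 -> 5,
#'     7 scored 4 -> 5, 2 scored 4 -> 3, 1 scored 3 -> 5 and 1 scored
#'     3 -> 4. (The remaining 5 of the 27 rig groups have no reported
#'     transitions and are excluded.)}
#' }
#'
#' @return Named list of three [paired_scores()] tables.
#' @export
clinical_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "dsacolor",
                                  mustWork = TRUE)
  list(bleeding = load_scores(path("bleeding_scores.csv")),
       no_bleeding = load_scores(path("no_bleeding_scores.csv")),
       ex_vivo = load_scores(path("ex_vivo_scores.csv")))
}
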