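#' Between-task regression of a regional metric
#'
#' Ordinary least-squares regression of one task's region-wise metric
#' vector (e.g. alpha power, mean burst duration) on the other's,
#' quantifying how similar the spatial distribution of PTR burst
#' characteristics is across tasks.
#'
#' @param a,b numeric vectors of one scalar per region, in matched region
#'   order (names are checked when present on both).
#' @return list with `r2`, `slope`, `intercept`, `n`.
#' @export
betweenTaskR2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("need matched metric vectors of length >= 3")
  }
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("region order differs between the two vectors")
  }
  if (stats::var(a) == 0) stop("predictor vector has zero variance")
  fit <- stats::lm(b ~ a)
  # simple OLS: R^2 is the squared Pearson correlation (avoids the
  # perfect-fit warning summary.lm emits on exact relationships)
  list(r2 = if (stats::var(b) == 0) 0 else stats::cor(a, b)^2,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(a))
}

#' Per-participant PTR-state probability contrast between conditions
#'
#' Mean PTR-state probability inside the PTR window, condition A minus
#' condition B (e.g. 2-back minus 1-back), one scalar per participant.
#' Participants missing either condition are dropped with a warning.
#'
#' @param evolutions named list (by participant) of lists with one
#'   [ProbabilityEvolution-class] per condition label; each evolution must
#'   contain the PTR-state row being contrasted as its single row, or a
#'   row index supplied via `row`.
#' @param conditions length-2 character, `(A, B)`.
#' @param ptrWindow `(start, end)` seconds after task cessation; defaults
#'   to the design window.
#' @param row row of each evolution to use (default 1).
#' @return named numeric vector of per-participant contrasts.
#' @export
ptrContrast <- function(evolutions, conditions, ptrWindow = NULL, row = 1L) {
  stopifnot(length(conditions) == 2L)
  out <- numeric(0)
  for (p in names(evolutions)) {
    ev <- evolutions[[p]]
    if (!all(conditions %in% names(ev))) {
      warning(sprintf("participant %s missing a condition; dropped", p))
      next
    }
    val <- vapply(conditions, function(cond) {
      e <- ev[[cond]]
      design <- e@design
      w <- if (is.null(ptrWindow)) design@ptrWindow else ptrWindow
      taskEnd <- design@instructionDur + design@taskDur
      a <- floor((taskEnd + w[1L]) * e@fs) + 1L
      b <- min(ceiling((taskEnd + w[2L]) * e@fs), ncol(e@evolution))
      mean(e@evolution[row, a:b])
    }, 0)
    out[p] <- val[1L] - val[2L]
  }
  out
}

#' Pearson correlation with behaviour, Bonferroni-corrected
#'
#' Correlates per-participant PTR-state probability contrasts with
#' reaction-time contrasts. Significance by two-sided Pearson test;
#' the Bonferroni factor defaults to 4, one test per anatomical
#' region/network examined (frontal, left parietal, left lateral visual,
#' dorsal attention network).
#'
#' @param ptr,rt numeric vectors, one value per participant.
#' @param m number of comparisons in the family (default 4).
#' @return list with `r`, `p_raw`, `p_bonferroni`, `n`.
#' @export
rtCorrelation <- function(ptr, rt, m = 4L) {
  if (length(ptr) != length(rt) || length(ptr) < 4L) {
    stop("need >= 4 paired participant values")
  }
  if (stats::var(ptr) == 0 || stats::var(rt) == 0) {
    stop("zero variance in one of the inputs")
  }
  ct <- stats::cor.test(ptr, rt, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_raw = ct$p.value,
       p_bonferroni = min(1, m * ct$p.value), n = length(ptr))
}
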