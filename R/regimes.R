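# vectorized three-way comparison against a baseline at relative tolerance
.classify_values <- function(F_values, baseline, epsilon) {
  up <- baseline * (1 + epsilon)
  dn <- baseline * (1 - epsilon)
  ifelse(F_values > up, "facilitation",
         ifelse(F_values < dn, "competition", "neutral"))
}

#' Classify one wildflower amount as facilitation, neutrality or competition
#'
#' Wherever pollinator visits to the crop exceed the no-wildflower baseline
#' F(c, 0) = N(c, 0), facilitation is occurring; wherever they fall below
#' it, the wildflowers compete with the crop. Comparison uses a relative
#' tolerance `epsilon` so that algebraically exact neutrality (the purely
#' linear family, where each plant attracts exactly the pollinators that
#' choose it) classifies as neutral despite floating point.
#'
#' @inheritParams attraction
#' @param c Crop amount (> 0).
#' @param w Wildflower amount (>= 0).
#' @param epsilon Relative neutrality tolerance (default 1e-9).
#' @return One of `"facilitation"`, `"neutral"`, `"competition"`.
#' @export
#' @examples
#' classify_point("hyperbolic", attraction_params(A = 10, a = 0.4, N_c = 10),
#'                c = 10, w = 1.2)  # facilitation
classify_point <- function(form, params, c, w, epsilon = 1e-9) {
  stopifnot(length(c) == 1L, length(w) == 1L, c > 0, w >= 0)
  Fw <- visit_rates(form, params, patch_state(c = c, w = w))$F_crop
  F0 <- visit_rates(form, params, patch_state(c = c, w = 0))$F_crop
  .classify_values(Fw, F0, epsilon)
}

#' Regime profile of the crop along a wildflower gradient
#'
#' Evaluates visit rates over an ascending grid of wildflower amounts,
#' labels every point relative to the no-wildflower baseline, and extracts
#' the maximal contiguous facilitation interval containing the smallest
#' facilitating amount. Interval edges live on the supplied grid; grid
#' density is the user's control over their resolution.
#'
#' @inheritParams classify_point
#' @param w_grid Ascending, non-empty grid of wildflower amounts.
#' @return An object of class `regime_profile`: a list with fields
#'   `w_grid`, `N`, `D`, `F_crop`, `baseline`, `labels`,
#'   `facilitation_interval` (length-2 numeric, or NULL when empty).
#' @export
regime_profile <- function(form, params, c, w_grid, epsilon = 1e-9) {
  if (length(w_grid) == 0L || is.unsorted(w_grid))
    stop("w_grid must be non-empty and ascending", call. = FALSE)
  stopifnot(c > 0)
  vr <- visit_rates(form, params,
                    patch_state(c = rep_len(c, length(w_grid)), w = w_grid))
  baseline <- visit_rates(form, params, patch_state(c = c, w = 0))$F_crop
  labels <- .classify_values(vr$F_crop, baseline, epsilon)
  fac <- labels == "facilitation"
  interval <- NULL
  if (any(fac)) {
    first <- which(fac)[1L]
    run_end <- first
    while (run_end < length(fac) && fac[run_end + 1L]) run_end <- run_end + 1L
    interval <- c(w_grid[first], w_grid[run_end])
  }
  structure(list(w_grid = w_grid, N = vr$N, D = vr$D, F_crop = vr$F_crop,
                 baseline = baseline, labels = labels,
                 facilitation_interval = interval),
            class = "regime_profile")
}

#' @export
print.regime_profile <- function(x, ...) {
  counts <- table(factor(x$labels,
                         levels = c("facilitation", "neutral", "competition")))
  cat("<regime_profile> ", length(x$w_grid), " points, baseline F(c,0) = ",
      format(x$baseline), "\n  ", paste(names(counts), counts, sep = ": ",
                                        collapse = ", "), "\n", sep = "")
  if (is.null(x$facilitation_interval)) {
    cat("  facilitation interval: empty\n")
  } else {
    cat("  facilitation interval: [", x$facilitation_interval[1], ", ",
        x$facilitation_interval[2], "]\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.regime_profile <- function(x, ...) {
  data.frame(w = x$w_grid, N = x$N, D = x$D, F_crop = x$F_crop,
             baseline = x$baseline, label = x$labels)
}

#' Scan for an interspecifically precipitated Allee effect
#'
#' An Allee effect here means a rising per-unit-amount visitation of the
#' wildflowers: V(w) = N(c, w) (1 - D(c, w)) / w = N(c, w) / (c + w), the
#' natural per-capita rate under input matching. A decelerating attraction
#' function alone (c = 0) never produces one, but the presence of the crop
#' can: near w = 0 the sign of V'(0) is the sign of (A/a) c - N_c for the
#' saturating family, so conspecific facilitation appears exactly when the
#' crop amount exceeds the facilitation threshold c0.
#'
#' @inheritParams classify_point
#' @param w_grid Ascending grid of strictly positive wildflower amounts.
#' @return A data.frame with one row per maximal interval of strictly
#'   increasing V (columns `w_start`, `w_end`); zero rows when none.
#' @export
allee_scan <- function(form, params, c, w_grid) {
  if (length(w_grid) < 2L || is.unsorted(w_grid) || any(w_grid <= 0))
    stop("w_grid must be ascending with all w > 0 and length >= 2",
         call. = FALSE)
  st <- patch_state(c = rep_len(c, length(w_grid)), w = w_grid)
  V <- attraction(form, params, st) / (c + w_grid)
  n <- length(V)
  dV <- numeric(n)
  dV[1] <- (V[2] - V[1]) / (w_grid[2] - w_grid[1])
  dV[n] <- (V[n] - V[n - 1]) / (w_grid[n] - w_grid[n - 1])
  if (n > 2)
    dV[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (w_grid[3:n] - w_grid[1:(n - 2)])
  # derivative-scale tolerance so exactly-flat V classifies as not increasing
  tol <- 1e-9 * max(abs(V)) / diff(range(w_grid))
  inc <- dV > tol
  runs <- rle(inc)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  data.frame(w_start = w_grid[starts[keep]], w_end = w_grid[ends[keep]])
}

#' Pairwise interaction signs at one patch state
#'
#' Classifies the effect of the wildflowers on the crop (visits to the
#' crop at (c, w) against the baseline w = 0) and, symmetrically, the
#' effect of the crop on the wildflowers (visits to the wildflowers at
#' (c, w) against the crop-absent baseline c = 0; parameters are left
#' untouched, so a scalar `N_c` persists in that baseline).
#'
#' Note an exact algebraic constraint: whenever the attraction function is
#' additive in the two species' contributions, N = h_c(c) + h_w(w) (all
#' linear and saturating families here), the two differences are exact
#' negatives of one another — \[h_w(w) c - h_c(c) w\] / (c + w) on the crop
#' side — so mutual facilitation at a single shared state requires a
#' non-additive family (e.g. the sigmoid Holling type III). Mutual benefit
#' under additive attraction instead shows up at each species' own
#' optimum; see [optimal_w_analytic()].
#'
#' @inheritParams classify_point
#' @param w Wildflower amount (> 0).
#' @return Named character vector `c(crop = ..., wild = ...)`.
#' @export
#' @examples
#' interaction_matrix("sigmoid", attraction_params(r = 0.02, y = 3),
#'                    c = 10, w = 10)  # both facilitated
interaction_matrix <- function(form, params, c, w, epsilon = 1e-9) {
  stopifnot(length(c) == 1L, length(w) == 1L, c > 0, w > 0)
  crop <- classify_point(form, params, c, w, epsilon)
  Fw <- visit_rates(form, params, patch_state(c = c, w = w))$F_wild
  F0 <- visit_rates(form, params, patch_state(c = 0, w = w))$F_wild
  wild <- .classify_values(Fw, F0, epsilon)
  c(crop = crop, wild = wild)
}
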