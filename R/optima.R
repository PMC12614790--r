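#' @keywords internal
new_optimum_result <- function(location, objective, method, at_boundary,
                               residual = NA_real_) {
  structure(list(location = location, objective = objective, method = method,
                 at_boundary = at_boundary, residual = residual),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat("<optimum_result> location =", format(x$location),
      " objective =", format(x$objective),
      " method =", x$method,
      " at_boundary =", x$at_boundary,
      " residual =", format(x$residual), "\n")
  invisible(x)
}

#' @export
as.data.frame.optimum_result <- function(x, ...) {
  data.frame(location = x$location, objective = x$objective,
             method = x$method, at_boundary = x$at_boundary,
             residual = x$residual)
}

# golden-section maximization of f on [lo, hi]; f assumed unimodal there
.golden_max <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 >= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

# grid scan to bracket the global maximum, then golden-section refinement.
# Ties (flat objectives) break toward the smallest x. Returns location,
# objective and a boundary flag for optima clamped to the domain edge.
.scan_and_refine <- function(f, lo, hi, n_grid = 1e4, tol = 1e-8,
                             warn_upper = TRUE, label = "x") {
  grid <- seq(lo, hi, length.out = n_grid + 1L)
  fv <- f(grid)
  m <- max(fv)
  tie <- abs(fv - m) <= 1e-12 * max(abs(m), 1)
  idx <- which(tie)[1L]
  n <- length(grid)
  if (idx == n) {
    if (warn_upper)
      warning("maximum of the objective lies at the upper search bound ",
              label, " = ", hi, "; enlarge the window", call. = FALSE)
    return(list(location = hi, objective = fv[n], at_boundary = TRUE))
  }
  if (idx == 1L) {
    # either a true boundary maximum / flat objective, or an interior peak
    # below the first grid step: refine the first cell to distinguish
    x <- .golden_max(f, grid[1L], grid[2L], tol)
    fx <- f(x)
    if (fx > fv[1L] * (1 + 1e-12) && fx > fv[1L] + 1e-15)
      return(list(location = x, objective = fx, at_boundary = FALSE))
    return(list(location = lo, objective = fv[1L], at_boundary = TRUE))
  }
  bl <- grid[max(idx - 1L, 1L)]
  bu <- grid[min(idx + 1L, n)]
  x <- .golden_max(f, bl, bu, tol)
  obj <- f(x)
  # golden refinement may land a hair below a boundary-grazing optimum
  if (obj < fv[idx]) { x <- grid[idx]; obj <- fv[idx] }
  at_b <- x <= lo + tol || x >= hi - tol
  list(location = x, objective = obj, at_boundary = at_b)
}

# central finite-difference derivative
.fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

#' Tangent (marginal-value) residual of the crop optimum
#'
#' At the wildflower amount w* that maximizes pollinator visits to the
#' crop, the slope of the attraction curve equals the slope of the tangent
#' drawn from -c on the amount axis: dN/dw = N(c, w) / (c + w). This
#' function returns the residual dN/dw - N/(c + w), which is zero at an
#' interior optimum, positive below it and negative beyond it.
#'
#' @inheritParams attraction
#' @param c Crop amount (c + w > 0).
#' @param w Wildflower amount(s).
#' @param derivative `"analytic"` uses the registered closed form
#'   (available for `hyperbolic`: dN/dw = A a / (a + w)^2); `"numeric"`
#'   falls back to a central finite difference (step `h`) for any family.
#' @param h Finite-difference step for `derivative = "numeric"`.
#' @return Numeric residual(s).
#' @export
#' @examples
#' tangent_residual(attraction_params(A = 10, a = 0.4, N_c = 10),
#'                  c = 10, w = 1.2)  # 0 at the optimum
tangent_residual <- function(params, c, w, form = "hyperbolic",
                             derivative = c("analytic", "numeric"),
                             h = 1e-6) {
  derivative <- match.arg(derivative)
  form <- .check_form(form)
  params <- .check_params(params, form)
  if (any(c + w <= 0)) stop("c + w must be positive", call. = FALSE)
  if (derivative == "analytic") {
    if (form != "hyperbolic")
      stop("no closed-form derivative registered for form '", form,
           "'; use derivative = \"numeric\"", call. = FALSE)
    dN <- params$A * params$a / (params$a + w)^2
  } else {
    dN <- vapply(w, function(wi) {
      .fd(function(x) attraction(form, params,
                                 patch_state(c = c, w = pmax(x, 0))), wi, h)
    }, numeric(1))
  }
  N <- attraction(form, params, patch_state(c = c, w = w))
  dN - N / (c + w)
}

#' Closed-form optimal wildflower amount w* (saturating attraction)
#'
#' For the saturating family N = A w / (a + w) + N_c the tangent condition
#' reduces to the quadratic w^2 (A + N_c) + w 2 a N_c + N_c a^2 - A a c = 0,
#' whose positive branch gives
#' w* = \[-2 a N_c + sqrt((2 a N_c)^2 - 4 (A + N_c)(N_c a^2 - a A c))\] /
#' \[2 (A + N_c)\]. When the branch is nonpositive (c at or below the
#' facilitation threshold c0 = N_c a / A) the crop does best with no
#' wildflowers at all and the result is clamped to w* = 0 with
#' `at_boundary = TRUE`.
#'
#' @param params An [attraction_params()] with `A`, `a` (and `N_c`) set;
#'   A + N_c must be positive.
#' @param c Crop amount (>= 0).
#' @return An `optimum_result` with `location` w*, `objective` F(c, w*),
#'   `method = "analytic"`, and the tangent residual at w*.
#' @seealso [facilitation_threshold()], [optimal_w_numeric()]
#' @export
#' @examples
#' optimal_w_analytic(attraction_params(A = 10, a = 0.4, N_c = 10), c = 10)
optimal_w_analytic <- function(params, c) {
  params <- .check_params(params, "hyperbolic")
  if (length(c) != 1L || !is.finite(c) || c < 0)
    stop("c must be a single nonnegative number", call. = FALSE)
  A <- params$A; a <- params$a; Nc <- params$N_c
  if (A + Nc <= 0) stop("A + N_c must be positive", call. = FALSE)
  disc <- (2 * a * Nc)^2 - 4 * (A + Nc) * (Nc * a^2 - a * A * c)
  w <- if (disc < 0) -Inf else (-2 * a * Nc + sqrt(disc)) / (2 * (A + Nc))
  if (!is.finite(w) || w <= 0) {
    obj <- if (c > 0) Nc else NA_real_  # F(c, 0) = N_c (all choice on crop)
    return(new_optimum_result(0, obj, "analytic", TRUE,
                              residual = NA_real_))
  }
  obj <- visit_rates("hyperbolic", params, patch_state(c = c, w = w))$F_crop
  res <- tangent_residual(params, c, w)
  new_optimum_result(w, obj, "analytic", FALSE, res)
}

#' Numerical optimal wildflower amount (brute-force oracle)
#'
#' Maximizes F_crop(c, w) over \[0, w_max\] by a dense grid scan (which
#' brackets the global maximum even for non-unimodal families such as the
#' sigmoid) followed by golden-section refinement. Flat objectives
#' (`linear_additive`) break ties toward w = 0, the conservative
#' recommendation. A warning is raised when the maximum sits at `w_max`
#' (search window too small).
#'
#' @inheritParams attraction
#' @param c Crop amount (> 0 so that F_crop is the crop's rate).
#' @param w_max Upper search bound (default 50).
#' @param tol Golden-section location tolerance (default 1e-8).
#' @param n_grid Number of grid cells in the bracketing scan (default 1e4).
#' @return An `optimum_result` with `method` `"golden_section"` (or
#'   `"grid"` for boundary/flat outcomes); `residual` is the central
#'   finite-difference derivative of F_crop at the reported location
#'   (interior optima only).
#' @export
optimal_w_numeric <- function(form, params, c, w_max = 50, tol = 1e-8,
                              n_grid = 1e4) {
  form <- .check_form(form)
  params <- .check_params(params, form)
  stopifnot(w_max > 0, tol > 0)
  f <- function(w) {
    st <- patch_state(c = rep_len(c, length(w)), w = w)
    attraction(form, params, st) * choice_fraction(st)
  }
  ans <- .scan_and_refine(f, 0, w_max, n_grid = n_grid, tol = tol,
                          label = "w_max")
  res <- if (ans$at_boundary) NA_real_ else .fd(f, ans$location)
  new_optimum_result(ans$location, ans$objective,
                     if (ans$at_boundary) "grid" else "golden_section",
                     ans$at_boundary, res)
}

#' Facilitation threshold c0
#'
#' The crop amount below which the optimal wildflower amount w* collapses
#' to zero for the saturating family: setting w* = 0 in the optimality
#' quadratic gives c0 = N_c a / A. For c > c0 a strictly positive amount
#' of the "competitor" increases pollinator visits to the crop.
#'
#' @param params An [attraction_params()] with `A > 0`, `a`, `N_c`.
#' @return The threshold amount c0.
#' @export
#' @examples
#' facilitation_threshold(attraction_params(A = 10, a = 0.4, N_c = 10))  # 0.4
facilitation_threshold <- function(params) {
  params <- .check_params(params, "hyperbolic")
  if (params$A <= 0)
    stop("facilitation threshold requires A > 0", call. = FALSE)
  params$N_c * params$a / params$A
}

#' Optimal wildflower amount along a crop gradient
#'
#' Evaluates the closed-form w* of [optimal_w_analytic()] on an ascending
#' grid of crop amounts. w*(c) is non-decreasing, zero up to the
#' facilitation threshold c0 and strictly increasing beyond it.
#'
#' @inheritParams optimal_w_analytic
#' @param c_grid Non-empty ascending vector of crop amounts.
#' @return A data.frame with columns `c`, `w_star`, `at_boundary`.
#' @export
w_star_curve <- function(params, c_grid) {
  if (length(c_grid) == 0L || is.unsorted(c_grid))
    stop("c_grid must be non-empty and ascending", call. = FALSE)
  rows <- lapply(c_grid, function(ci) {
    o <- optimal_w_analytic(params, ci)
    data.frame(c = ci, w_star = o$location, at_boundary = o$at_boundary)
  })
  do.call(rbind, rows)
}

#' Stationarity residual of the fixed-area crop optimum
#'
#' At the interior proportion p* maximizing the crop yield
#' f(p) = N_p D_p (1 - p), the product N_p D_p satisfies
#' d/dp (N_p D_p) = N_p D_p / (1 - p). This function returns
#' d/dp (N_p D_p) - N_p D_p / (1 - p), using the registered closed-form
#' derivative of the two-species saturating family (or a central finite
#' difference on request).
#'
#' @param config A [model_b_config()].
#' @param p Proportion(s) in the open interval (0, 1) at which to
#'   evaluate; defaults to `config$p`.
#' @param derivative `"analytic"` (closed form) or `"numeric"` (central
#'   finite difference, step `h`).
#' @param h Finite-difference step.
#' @return Numeric residual(s); zero at an interior p*.
#' @export
model_b_stationarity_residual <- function(config, p = config$p,
                                          derivative = c("analytic",
                                                         "numeric"),
                                          h = 1e-6) {
  stopifnot(inherits(config, "model_b_config"))
  derivative <- match.arg(derivative)
  if (any(p <= 0 | p >= 1))
    stop("stationarity residual is defined for 0 < p < 1", call. = FALSE)
  prm <- config$params; b <- config$b
  nd <- .model_b_ND(config, p)
  ND <- nd$N * nd$D
  if (derivative == "analytic") {
    dN <- prm$A_w * b * prm$a_w / (prm$a_w + b * p)^2 -
          prm$A_c * prm$a_c / (prm$a_c + 1 - p)^2
    dD <- -b / (1 + (b - 1) * p)^2
    dND <- dN * nd$D + nd$N * dD
  } else {
    g <- function(x) { v <- .model_b_ND(config, x); v$N * v$D }
    dND <- vapply(p, function(pi) .fd(g, pi, h), numeric(1))
  }
  dND - ND / (1 - p)
}

#' Numerical fixed-area crop optimum p*
#'
#' Maximizes the crop yield f(p) = N_p(p) D_p(p) (1 - p) over p in
#' \[0, 1\] by a dense grid scan plus golden-section refinement. The
#' endpoints are admissible; `at_boundary` flags p* in {0, 1}.
#'
#' @param config A [model_b_config()] (its `p` field is ignored).
#' @param tol Golden-section location tolerance (default 1e-8).
#' @param n_grid Number of grid cells in the scan (default 1e4).
#' @return An `optimum_result`; `residual` is the stationarity residual
#'   at p* (interior optima only).
#' @export
#' @examples
#' cfg <- model_b_config(b = 1, params = attraction_params(
#'   A_w = 1, A_c = 1, a_w = 0.4, a_c = 0.4))
#' optimal_p_numeric(cfg)  # p* = 0.0528, rounds to 0.05
optimal_p_numeric <- function(config, tol = 1e-8, n_grid = 1e4) {
  stopifnot(inherits(config, "model_b_config"), tol > 0)
  ans <- .scan_and_refine(function(p) model_b_yield(config, p), 0, 1,
                          n_grid = n_grid, tol = tol, warn_upper = FALSE,
                          label = "p")
  res <- if (ans$at_boundary) NA_real_ else
    model_b_stationarity_residual(config, ans$location)
  new_optimum_result(ans$location, ans$objective,
                     if (ans$at_boundary) "grid" else "golden_section",
                     ans$at_boundary, res)
}

#' Proportion maximizing total attraction in the fixed-area scenario
#'
#' Maximizes N_p(p) alone (ignoring choice and area) over p in \[0, 1\].
#' Under symmetric parameters (A_w = A_c, a_w = a_c, b = 1) the curve is
#' symmetric about p = 0.5 and the maximum sits exactly there: the patch
#' attracts the most pollinators with an equal mix of both species,
#' because each species' own attraction decelerates with its amount.
#'
#' @inheritParams optimal_p_numeric
#' @return An `optimum_result`; `residual` is the central
#'   finite-difference derivative of N_p at the location (interior only).
#' @export
argmax_attraction_p <- function(config, tol = 1e-8, n_grid = 1e4) {
  stopifnot(inherits(config, "model_b_config"), tol > 0)
  f <- function(p) .model_b_ND(config, p)$N
  ans <- .scan_and_refine(f, 0, 1, n_grid = n_grid, tol = tol,
                          warn_upper = FALSE, label = "p")
  res <- if (ans$at_boundary) NA_real_ else .fd(f, ans$location)
  new_optimum_result(ans$location, ans$objective,
                     if (ans$at_boundary) "grid" else "golden_section",
                     ans$at_boundary, res)
}
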