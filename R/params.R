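#' Attraction function families
#'
#' Names of the functional families available for the patch attraction
#' function N(c, w), the total number of pollinators drawn to a patch
#' containing amount `c` of the focal crop and amount `w` of wildflowers.
#'
#' @return Character vector of valid form names.
#' @seealso [attraction()] for the formula each name selects.
#' @export
#' @examples
#' attraction_forms()
attraction_forms <- function() {
  c("linear_additive", "linear_plus_local", "weighted_linear",
    "hyperbolic", "exponential_saturating", "power", "sigmoid",
    "dual_hyperbolic")
}

# fields each form actually reads (beyond defaults); used to check presence
.form_required <- list(
  linear_additive        = c("g"),
  linear_plus_local      = c("L", "g"),
  weighted_linear        = c("A", "g"),
  hyperbolic             = c("A", "a"),
  exponential_saturating = c("A", "a"),
  power                  = c("A", "a"),
  sigmoid                = c("r", "y"),
  dual_hyperbolic        = c("A_w", "A_c", "a_w", "a_c")
)

.check_form <- function(form) {
  if (!is.character(form) || length(form) != 1L || !form %in% attraction_forms())
    stop("unknown attraction form: ", deparse(form),
         "; valid forms: ", paste(attraction_forms(), collapse = ", "),
         call. = FALSE)
  form
}

.check_bound <- function(value, name, lower, strict) {
  if (is.na(value)) return(invisible(value))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("parameter '", name, "' must be a single finite number", call. = FALSE)
  ok <- if (strict) value > lower else value >= lower
  if (!ok)
    stop("parameter '", name, "' must be ", if (strict) "> " else ">= ",
         lower, " (got ", value, ")", call. = FALSE)
  invisible(value)
}

#' Parameters of the patch attraction function
#'
#' Bundles every constant used by any of the attraction families (see
#' [attraction_forms()]). All quantities are dimensionless: plant "amounts"
#' are abstract utilities to the pollinators (number of flowers, nectar
#' value, ...), and attraction is a number of pollinators. Fields that the
#' selected family does not read are ignored at evaluation time, but every
#' supplied field is validated against its bound here.
#'
#' @param A Long-range attractiveness scale of the wildflowers (>= 0).
#' @param a Deceleration / half-saturation constant (> 0). For the `power`
#'   family `a` is reused as the exponent and must satisfy 0 < a < 1.
#' @param N_c Pollinators attracted by the crop alone (>= 0); the baseline
#'   `N(c, 0)` of the single-species saturating families. Default 0.
#' @param L Local pollinator pool present regardless of planting (>= 0).
#' @param r Rate constant of the sigmoid (Holling type III) family (> 0).
#' @param y Exponent of the sigmoid family (> 0).
#' @param g Linear attraction constant (> 0).
#' @param A_w,A_c Per-species attractiveness scales of the two-species
#'   saturating family (>= 0).
#' @param a_w,a_c Per-species half-saturation constants (> 0).
#' @param amplitude Multiplicative amplitude of the sigmoid family (> 0,
#'   default 1, i.e. the family is used exactly as printed).
#' @return An object of class `attraction_params`.
#' @export
#' @examples
#' attraction_params(A = 10, a = 0.4, N_c = 10)
attraction_params <- function(A = NA_real_, a = NA_real_, N_c = 0,
                              L = NA_real_, r = NA_real_, y = NA_real_,
                              g = NA_real_, A_w = NA_real_, A_c = NA_real_,
                              a_w = NA_real_, a_c = NA_real_, amplitude = 1) {
  p <- list(A = as.numeric(A), a = as.numeric(a), N_c = as.numeric(N_c),
            L = as.numeric(L), r = as.numeric(r), y = as.numeric(y),
            g = as.numeric(g), A_w = as.numeric(A_w), A_c = as.numeric(A_c),
            a_w = as.numeric(a_w), a_c = as.numeric(a_c),
            amplitude = as.numeric(amplitude))
  .check_bound(p$A,   "A",   0, strict = FALSE)
  .check_bound(p$a,   "a",   0, strict = TRUE)
  .check_bound(p$N_c, "N_c", 0, strict = FALSE)
  .check_bound(p$L,   "L",   0, strict = FALSE)
  .check_bound(p$r,   "r",   0, strict = TRUE)
  .check_bound(p$y,   "y",   0, strict = TRUE)
  .check_bound(p$g,   "g",   0, strict = TRUE)
  .check_bound(p$A_w, "A_w", 0, strict = FALSE)
  .check_bound(p$A_c, "A_c", 0, strict = FALSE)
  .check_bound(p$a_w, "a_w", 0, strict = TRUE)
  .check_bound(p$a_c, "a_c", 0, strict = TRUE)
  .check_bound(p$amplitude, "amplitude", 0, strict = TRUE)
  structure(p, class = "attraction_params")
}

.check_params <- function(params, form) {
  if (!inherits(params, "attraction_params"))
    params <- do.call(attraction_params, as.list(params))
  need <- .form_required[[form]]
  missing <- need[vapply(need, function(f) is.na(params[[f]]), logical(1))]
  if (length(missing))
    stop("form '", form, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (form == "power" && (params$a <= 0 || params$a >= 1))
    stop("power form requires exponent 0 < a < 1 (got a = ", params$a, ")",
         call. = FALSE)
  params
}

#' @export
print.attraction_params <- function(x, ...) {
  set <- !vapply(x, is.na, logical(1))
  cat("<attraction_params> ",
      paste(names(x)[set], "=", format(unlist(x[set])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Patch state: amounts of crop and wildflowers
#'
#' The pair (c, w) of nonnegative dimensionless "amounts" (utilities to
#' the pollinators) of the focal crop and of the wildflowers. Vector
#' inputs are accepted (recycled to a common length) so whole sweeps can
#' be evaluated in one call.
#'
#' @param c Crop amount(s), >= 0.
#' @param w Wildflower amount(s), >= 0.
#' @return An object of class `patch_state` with fields `c` and `w`.
#' @export
#' @examples
#' patch_state(c = 10, w = 1.2)
patch_state <- function(c, w) {
  c <- as.numeric(c); w <- as.numeric(w)
  if (length(c) == 0L || length(w) == 0L)
    stop("c and w must be non-empty", call. = FALSE)
  n <- max(length(c), length(w))
  if (n %% length(c) != 0L || n %% length(w) != 0L)
    stop("c and w lengths are incompatible", call. = FALSE)
  c <- rep_len(c, n); w <- rep_len(w, n)
  if (anyNA(c) || anyNA(w) || any(!is.finite(c)) || any(!is.finite(w)))
    stop("c and w must be finite", call. = FALSE)
  if (any(c < 0) || any(w < 0))
    stop("amounts must be nonnegative: c >= 0 and w >= 0", call. = FALSE)
  structure(list(c = c, w = w), class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat("<patch_state> n =", length(x$c),
      if (length(x$c) == 1L) paste0("(c = ", x$c, ", w = ", x$w, ")"), "\n")
  invisible(x)
}

#' Fixed-total-area (Model B) configuration
#'
#' In the fixed-area scenario a proportion `p` of a patch of fixed total
#' area is devoted to wildflowers and `1 - p` to the crop. With the crop's
#' per-area value standardized to 1 and the wildflowers worth `b` per area,
#' the induced amounts are `c = 1 - p` and `w = b * p`. Attraction follows
#' the two-species saturating family (`dual_hyperbolic`).
#'
#' @param p Proportion of area in wildflowers, 0 <= p <= 1. Optimizers
#'   that search over p ignore this field; it defaults to 0.
#' @param b Relative per-area value of wildflowers to the pollinators (> 0).
#' @param total_area Pure scaling factor of the yield (> 0); it never moves
#'   an optimum.
#' @param params An [attraction_params()] carrying `A_w`, `A_c`, `a_w`, `a_c`.
#' @return An object of class `model_b_config`.
#' @export
#' @examples
#' model_b_config(p = 0.05, b = 1,
#'                params = attraction_params(A_w = 1, A_c = 1,
#'                                           a_w = 0.4, a_c = 0.4))
model_b_config <- function(p = 0, b = 1, total_area = 1,
                           params = attraction_params()) {
  p <- as.numeric(p)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("p must be a single number in [0, 1]", call. = FALSE)
  .check_bound(as.numeric(b), "b", 0, strict = TRUE)
  .check_bound(as.numeric(total_area), "total_area", 0, strict = TRUE)
  params <- .check_params(params, "dual_hyperbolic")
  structure(list(p = p, b = as.numeric(b), total_area = as.numeric(total_area),
                 params = params),
            class = "model_b_config")
}

#' @export
print.model_b_config <- function(x, ...) {
  cat("<model_b_config> p =", x$p, " b =", x$b, " total_area =", x$total_area,
      "\n  A_w =", x$params$A_w, " A_c =", x$params$A_c,
      " a_w =", x$params$a_w, " a_c =", x$params$a_c, "\n")
  invisible(x)
}
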