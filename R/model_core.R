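#' Choice fraction D under input matching
#'
#' Once in the patch, pollinators divide among the two plant species in
#' proportion to the species' amounts (input matching / ideal free
#' distribution), so the fraction landing on the crop is D = c / (c + w).
#'
#' @param state A [patch_state()]; vectors allowed.
#' @return Numeric vector of fractions in \[0, 1\]: 1 when w = 0, 0 when
#'   c = 0.
#' @export
#' @examples
#' choice_fraction(patch_state(c = 0.5, w = 1.5))  # 0.25
choice_fraction <- function(state) {
  if (!inherits(state, "patch_state")) stop("state must be a patch_state",
                                            call. = FALSE)
  tot <- state$c + state$w
  if (any(tot == 0))
    stop("degenerate patch: D is undefined at c = w = 0", call. = FALSE)
  state$c / tot
}

#' Patch attraction N(c, w)
#'
#' Total number of pollinators drawn to the patch, under one of the
#' functional families of [attraction_forms()]:
#' \describe{
#'   \item{linear_additive}{N = g (c + w): attraction proportional to the
#'     summed amounts.}
#'   \item{linear_plus_local}{N = L + g (c + w): a fixed local pool L on
#'     top of the linear draw.}
#'   \item{weighted_linear}{N = A g w + g c: wildflowers disproportionately
#'     attractive by the factor A.}
#'   \item{hyperbolic}{N = A w / (a + w) + N_c: saturating (Michaelis-Menten)
#'     in w on a crop baseline N_c.}
#'   \item{exponential_saturating}{N = A (1 - exp(-w / a)) + N_c.}
#'   \item{power}{N = A w^a + N_c with 0 < a < 1: decelerating but
#'     unbounded.}
#'   \item{sigmoid}{N = amplitude (r (c + w))^y / (1 + (r (c + w))^y): a
#'     Holling type III response to the joint amount.}
#'   \item{dual_hyperbolic}{N = A_w w / (a_w + w) + A_c c / (a_c + c):
#'     each species saturates independently.}
#' }
#'
#' @param form One name from [attraction_forms()].
#' @param params An [attraction_params()] supplying the fields the family
#'   reads.
#' @param state A [patch_state()]; vectors allowed.
#' @return Numeric vector of pollinator numbers, finite and >= 0.
#' @export
#' @examples
#' attraction("hyperbolic", attraction_params(A = 10, a = 0.4),
#'            patch_state(c = 1, w = 0.4))  # half-saturation: 5
attraction <- function(form, params, state) {
  form <- .check_form(form)
  params <- .check_params(params, form)
  if (!inherits(state, "patch_state")) stop("state must be a patch_state",
                                            call. = FALSE)
  c <- state$c; w <- state$w
  N <- switch(form,
    linear_additive        = params$g * (c + w),
    linear_plus_local      = params$L + params$g * (c + w),
    weighted_linear        = params$A * params$g * w + params$g * c,
    hyperbolic             = params$A * w / (params$a + w) + params$N_c,
    exponential_saturating = params$A * (1 - exp(-w / params$a)) + params$N_c,
    power                  = params$A * w^params$a + params$N_c,
    sigmoid                = {
      u <- (params$r * (c + w))^params$y
      params$amplitude * u / (1 + u)
    },
    dual_hyperbolic        = params$A_w * w / (params$a_w + w) +
                             params$A_c * c / (params$a_c + c)
  )
  stopifnot(all(is.finite(N)), all(N >= 0))
  N
}

#' Visit rates F = N D on each plant species
#'
#' Combines attraction to the patch with within-patch choice: the number of
#' pollinators on the crop is F_crop = N D and on the wildflowers
#' F_wild = N (1 - D), so F_crop + F_wild = N exactly (conservation).
#'
#' @inheritParams attraction
#' @return An object of class `visit_rates`: a list with numeric fields
#'   `N`, `D`, `F_crop`, `F_wild` (vectorized over the state).
#' @export
#' @examples
#' vr <- visit_rates("hyperbolic", attraction_params(A = 10, a = 0.4, N_c = 10),
#'                   patch_state(c = 10, w = 1.2))
#' vr$F_crop  # 15.625 > N_c = 10: facilitation
visit_rates <- function(form, params, state) {
  N <- attraction(form, params, state)
  D <- choice_fraction(state)
  structure(list(N = N, D = D, F_crop = N * D, F_wild = N * (1 - D)),
            class = "visit_rates")
}

#' @export
print.visit_rates <- function(x, ...) {
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.visit_rates <- function(x, ...) {
  data.frame(N = x$N, D = x$D, F_crop = x$F_crop, F_wild = x$F_wild)
}

#' Induced patch state of the fixed-area scenario
#'
#' Maps the wildflower proportion p to the amounts the pollinators see:
#' c = 1 - p (crop value standardized to 1 at p = 0) and w = b p.
#'
#' @param config A [model_b_config()].
#' @return A [patch_state()].
#' @export
#' @examples
#' model_b_state(model_b_config(p = 0.5, b = 3,
#'   params = attraction_params(A_w = 1, A_c = 1, a_w = 0.4, a_c = 0.4)))
model_b_state <- function(config) {
  stopifnot(inherits(config, "model_b_config"))
  patch_state(c = 1 - config$p, w = config$b * config$p)
}

# attraction and choice at proportion(s) p; internal, vectorized over p
.model_b_ND <- function(config, p = config$p) {
  prm <- config$params; b <- config$b
  c <- 1 - p; w <- b * p
  list(N = prm$A_w * w / (prm$a_w + w) + prm$A_c * c / (prm$a_c + c),
       D = ifelse(c + w == 0, 0, c / (c + w)))
}

#' Crop "yield" of the fixed-area scenario
#'
#' The quantity maximized for the crop: f(p) = N_p(p) D_p(p) (1 - p) times
#' the total area — pollinator visits to the crop weighted by the crop's
#' share of the area. "Yield" is a shorthand for pollination-limited,
#' area-linear output; no fruit production is modelled. f(1) = 0 (no crop
#' area, and no pollinator chooses a crop that is absent).
#'
#' @param config A [model_b_config()].
#' @param p Optional proportion(s) at which to evaluate, overriding
#'   `config$p`; vectors allowed.
#' @return Numeric vector of yield values, >= 0.
#' @export
#' @examples
#' cfg <- model_b_config(b = 1, params = attraction_params(A_w = 1, A_c = 1,
#'                                                         a_w = 0.4, a_c = 0.4))
#' model_b_yield(cfg, p = 0)  # 1/1.4 = 0.714...
model_b_yield <- function(config, p = config$p) {
  stopifnot(inherits(config, "model_b_config"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  nd <- .model_b_ND(config, p)
  nd$N * nd$D * (1 - p) * config$total_area
}

#' Wildflower-side "yield" of the fixed-area scenario
#'
#' The wildflower analogue of [model_b_yield()]:
#' N_p(p) (1 - D_p(p)) p times the total area.
#'
#' @inheritParams model_b_yield
#' @return Numeric vector of yield values, >= 0.
#' @export
model_b_wild_yield <- function(config, p = config$p) {
  stopifnot(inherits(config, "model_b_config"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  nd <- .model_b_ND(config, p)
  nd$N * (1 - nd$D) * p * config$total_area
}

#' Scaling constant for figure-comparable output
#'
#' Returns k = 1 / N(c_fixed, w_ref), the positive constant that rescales
#' the attraction curve to 1 at the reference amount w_ref. Used only to
#' make output tables comparable across functional families; a positive
#' rescaling never moves an argmax, so it is never applied in optimization.
#'
#' @inheritParams attraction
#' @param c_fixed Crop amount held constant.
#' @param w_ref Reference wildflower amount (default 50).
#' @return The scalar k with k * N(c_fixed, w_ref) = 1.
#' @export
normalize_attraction <- function(form, params, c_fixed, w_ref = 50) {
  N_ref <- attraction(form, params, patch_state(c = c_fixed, w = w_ref))
  if (N_ref == 0)
    stop("cannot normalize: N(c, w_ref) = 0", call. = FALSE)
  1 / N_ref
}
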