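# fixture parameter sets behind the named figure scenarios.
# Model A panels hold the crop at c = 10 with the reference constants
# a = 0.4, A = 10, L = 10, r = 0.02, y = 3, g = 1 (N_c = 10 where the
# family uses a crop baseline); the fixed-area panels use
# A_w = A_c = 1 (or A_w = 10), a_w = a_c = 0.4, b = 1.
.scenarios <- list(
  fig1  = list(variable = "w", form = "hyperbolic",
               params = list(A = 10, a = 0.4, N_c = 10), c = 10,
               normalize_at = NULL, tangent = TRUE),
  fig2a = list(variable = "w", form = "linear_additive",
               params = list(g = 1), c = 10, normalize_at = 50),
  fig2b = list(variable = "w", form = "linear_plus_local",
               params = list(L = 10, g = 1), c = 10, normalize_at = 50),
  fig2c = list(variable = "w", form = "weighted_linear",
               params = list(A = 10, g = 1), c = 10, normalize_at = 50),
  fig2d = list(variable = "w", form = "power",
               params = list(A = 10, a = 0.4, N_c = 10), c = 10,
               normalize_at = 50),
  fig2e = list(variable = "w", form = "hyperbolic",
               params = list(A = 10, a = 0.4, N_c = 10), c = 10,
               normalize_at = 50),
  fig2f = list(variable = "w", form = "sigmoid",
               params = list(r = 0.02, y = 3), c = 10, normalize_at = 50),
  fig3a = list(variable = "p",
               model_b = list(A_w = 1, A_c = 1, a_w = 0.4, a_c = 0.4,
                              b = 1, total_area = 1)),
  fig3b = list(variable = "p",
               model_b = list(A_w = 10, A_c = 1, a_w = 0.4, a_c = 0.4,
                              b = 1, total_area = 1))
)

#' Specify a parameter sweep
#'
#' A sweep evaluates the model along a grid of one swept quantity (the
#' wildflower amount `w` in the independent-amount scenario, or the area
#' proportion `p` in the fixed-area scenario) with everything else held
#' fixed. Named scenarios load the reference parameter sets behind the
#' illustrative figures; `"custom"` takes everything from the arguments.
#' Attraction curves of `w`-sweeps can be rescaled to 1 at a reference
#' amount (`normalize_at`, default 50 for the comparison panels) purely
#' for cross-family comparability.
#'
#' @param scenario One of `"fig1"`, `"fig2a"` ... `"fig2f"`, `"fig3a"`,
#'   `"fig3b"`, `"custom"`.
#' @param variable Swept quantity, `"w"` or `"p"` (custom sweeps).
#' @param grid Ascending grid of swept values; defaults to 501 points on
#'   \[0, 50\] for `w` and 101 points on \[0, 1\] for `p`.
#' @param form,params,c Attraction family, [attraction_params()] and fixed
#'   crop amount for `w`-sweeps; scenario fixtures override them.
#' @param model_b A [model_b_config()] for `p`-sweeps.
#' @param normalize_at Optional reference amount at which N is scaled to 1
#'   (`NULL` disables).
#' @return An object of class `sweep_spec` for [run_sweep()].
#' @export
#' @examples
#' run_sweep(sweep_spec("fig3a", grid = seq(0, 1, by = 0.05)))
sweep_spec <- function(scenario = "custom", variable = NULL, grid = NULL,
                       form = NULL, params = NULL, c = NULL,
                       model_b = NULL, normalize_at = NULL) {
  known <- c(names(.scenarios), "custom")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% known)
    stop("unknown scenario: ", deparse(scenario), "; valid: ",
         paste(known, collapse = ", "), call. = FALSE)
  tangent <- FALSE
  if (scenario != "custom") {
    fx <- .scenarios[[scenario]]
    variable <- fx$variable
    if (variable == "w") {
      form <- fx$form
      params <- do.call(attraction_params, fx$params)
      c <- fx$c
      if (is.null(normalize_at)) normalize_at <- fx$normalize_at
      tangent <- isTRUE(fx$tangent)
    } else {
      mb <- fx$model_b
      model_b <- model_b_config(b = mb$b, total_area = mb$total_area,
                                params = attraction_params(
                                  A_w = mb$A_w, A_c = mb$A_c,
                                  a_w = mb$a_w, a_c = mb$a_c))
    }
  }
  if (is.null(variable) || !variable %in% c("w", "p"))
    stop("variable must be \"w\" or \"p\"", call. = FALSE)
  if (is.null(grid))
    grid <- if (variable == "w") seq(0, 50, length.out = 501) else
      seq(0, 1, length.out = 101)
  if (is.unsorted(grid) || length(grid) == 0L)
    stop("grid must be non-empty and ascending", call. = FALSE)
  if (variable == "w") {
    if (is.null(form) || is.null(params) || is.null(c))
      stop("w-sweeps need form, params and c", call. = FALSE)
    params <- .check_params(params, .check_form(form))
  } else {
    if (!inherits(model_b, "model_b_config"))
      stop("p-sweeps need a model_b_config", call. = FALSE)
  }
  structure(list(scenario = scenario, variable = variable, grid = grid,
                 form = form, params = params, c = c, model_b = model_b,
                 normalize_at = normalize_at, tangent = tangent),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates attraction, choice and visit rates (and, for fixed-area
#' sweeps, both species' area-weighted yields) along the sweep grid. The
#' output is a plain data.frame, one row per grid value; identical specs
#' give byte-identical CSV (the model is fully deterministic).
#'
#' @param spec A [sweep_spec()].
#' @return A data.frame with columns `w` (or `p`), `N`, `D`, `F_crop`,
#'   `F_wild`; `p`-sweeps add `f_crop_yield` and `f_wild_yield`;
#'   the tangent-construction scenario (`fig1`) adds `tangent_residual`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (spec$variable == "w") {
    w <- spec$grid
    # D undefined at c = w = 0; c is positive in every scenario
    st <- patch_state(c = rep_len(spec$c, length(w)), w = w)
    vr <- visit_rates(spec$form, spec$params, st)
    k <- if (is.null(spec$normalize_at)) 1 else
      normalize_attraction(spec$form, spec$params, spec$c,
                           spec$normalize_at)
    out <- data.frame(w = w, N = k * vr$N, D = vr$D,
                      F_crop = k * vr$F_crop, F_wild = k * vr$F_wild)
    if (spec$tangent)
      out$tangent_residual <- tangent_residual(spec$params, spec$c, w,
                                               form = spec$form)
    out
  } else {
    p <- spec$grid
    nd <- .model_b_ND(spec$model_b, p)
    data.frame(p = p, N = nd$N, D = nd$D,
               F_crop = nd$N * nd$D, F_wild = nd$N * (1 - nd$D),
               f_crop_yield = model_b_yield(spec$model_b, p),
               f_wild_yield = model_b_wild_yield(spec$model_b, p))
  }
}

# CSV dialect: comma-separated, '.' decimal, header, no row names, LF
.write_csv <- function(df, file = stdout()) {
  utils::write.table(df, file, sep = ",", eol = "\n", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
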