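.config_keys <- c("form", "A", "a", "N_c", "L", "r", "y", "g",
                  "A_w", "A_c", "a_w", "a_c", "b", "total_area",
                  "c", "w", "p", "amplitude")

.param_keys <- c("A", "a", "N_c", "L", "r", "y", "g",
                 "A_w", "A_c", "a_w", "a_c", "amplitude")

#' Load and validate a model configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) file of scalar keys and
#' returns a validated bundle. Recognized keys are the attraction
#' parameters, the functional `form`, the patch amounts `c` and `w`, and
#' the fixed-area keys `p`, `b`, `total_area`. Unknown keys are rejected
#' with an error naming them — never silently ignored — and every type
#' invariant (bounds, 0 <= p <= 1, ...) is enforced at load time.
#'
#' @param path Path to a JSON or YAML file.
#' @return A list of class `ac_config` with components `form` (or NULL),
#'   `params` ([attraction_params()]), `state` ([patch_state()] when `c`
#'   and `w` are both present), `model_b` ([model_b_config()] when any
#'   fixed-area key is present), and `raw` (the scalar key-value list).
#' @seealso [write_config()] for the exact round-trip inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml (got .", ext, ")",
         call. = FALSE))
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop("config must be a mapping of named scalar keys", call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(.config_keys, collapse = ", "), call. = FALSE)
  bad <- names(raw)[!vapply(raw, function(v)
    length(v) == 1L && (is.numeric(v) || is.character(v)), logical(1))]
  if (length(bad))
    stop("config key(s) must be scalar: ", paste(bad, collapse = ", "),
         call. = FALSE)
  form <- raw$form
  if (!is.null(form)) .check_form(form)
  params <- do.call(attraction_params, raw[intersect(names(raw), .param_keys)])
  if (!is.null(form)) .check_params(params, form)
  state <- NULL
  if (!is.null(raw$c) && !is.null(raw$w))
    state <- patch_state(c = raw$c, w = raw$w)
  model_b <- NULL
  if (any(c("p", "b", "total_area") %in% names(raw))) {
    mb_args <- raw[intersect(names(raw), c("p", "b", "total_area"))]
    mb_args$params <- params
    model_b <- do.call(model_b_config, mb_args)
  }
  structure(list(form = form, params = params, state = state,
                 model_b = model_b, raw = raw),
            class = "ac_config")
}

#' Write a model configuration
#'
#' Serializes a configuration (an `ac_config` from [load_config()], or a
#' plain named list of recognized scalar keys) back to JSON or YAML, by
#' file extension. `load_config(write_config(x, path))` reproduces `x`.
#'
#' @param x An `ac_config` or named list of recognized keys.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  raw <- if (inherits(x, "ac_config")) x$raw else x
  if (!is.list(raw) || is.null(names(raw)))
    stop("x must be an ac_config or a named list", call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(raw, path),
    stop("path must end in .json, .yaml or .yml", call. = FALSE))
  invisible(path)
}
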