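#' Measurement model specifications
#'
#' Constructors for the five estimable model variants:
#'
#' * `mixture2p()` — two-parameter mixture (target von Mises + uniform
#'   guessing); estimates `kappa` (log link) and `thetat` (mixing weight).
#' * `mixture3p()` — three-parameter mixture adding swap errors to
#'   non-target items; additionally estimates `thetant`.
#' * `imm()` — interference measurement model; versions `"abc"` (context
#'   activation `c`, general activation `a`, background noise `b = 1`),
#'   `"bsc"` (no `a`, but a generalization gradient with slope `s` over
#'   context distances), and `"full"` (both `a` and `s`).
#'
#' Fixed constants common to all variants: the target and guessing
#' distributions are centred at 0 (the data are response errors), the
#' guessing von Mises has `log(kappa) = -100` (numerically uniform), the
#' guessing mixing weight is the softmax reference fixed at 0, and the IMM
#' background noise is `b = 1` (the activation scale).
#'
#' @param resp_error Name of the response-error column (radians, relative
#'   to the target).
#' @param nt_features Character vector of non-target feature columns
#'   (radians relative to target), or a single regular expression if
#'   `regex = TRUE`.
#' @param set_size Name of the set-size column.
#' @param nt_distances Character vector of context-distance columns
#'   (required for IMM versions `"bsc"` and `"full"`), or a regex.
#' @param version IMM version: `"full"` (default), `"bsc"`, or `"abc"`.
#' @param regex Interpret `nt_features` / `nt_distances` as regular
#'   expressions to be matched against the data's column names at
#'   validation time.
#' @return An object of class `wmm_model`: a list with elements `name`,
#'   `parameters` (named list of link functions), `fixed` (named constants),
#'   and `vars` (column roles).
#' @examples
#' mixture2p(resp_error = "response_error")
#' mixture3p("response_error", nt_features = paste0("col_lure", 1:5),
#'           set_size = "setsize")
#' imm("resp_err", nt_features = "nt.*_loc", set_size = "n_items",
#'     nt_distances = "nt.*_dist", version = "full", regex = TRUE)
#' @export
mixture2p <- function(resp_error = "response_error") {
  new_wmm_model("mixture2p", resp_error = resp_error)
}

#' @rdname mixture2p
#' @export
mixture3p <- function(resp_error = "response_error", nt_features, set_size,
                      regex = FALSE) {
  if (missing(nt_features) || missing(set_size)) {
    stop("mixture3p requires `nt_features` and `set_size` columns")
  }
  new_wmm_model("mixture3p", resp_error = resp_error,
                nt_features = nt_features, set_size = set_size, regex = regex)
}

#' @rdname mixture2p
#' @export
imm <- function(resp_error = "response_error", nt_features, set_size,
                nt_distances = NULL, version = c("full", "bsc", "abc"),
                regex = FALSE) {
  version <- match.arg(version)
  if (missing(nt_features) || missing(set_size)) {
    stop("imm requires `nt_features` and `set_size` columns")
  }
  if (version %in% c("bsc", "full") && is.null(nt_distances)) {
    stop("IMM version '", version,
         "' requires `nt_distances` (context distances of non-targets)")
  }
  new_wmm_model(paste0("imm_", version), resp_error = resp_error,
                nt_features = nt_features, set_size = set_size,
                nt_distances = nt_distances, regex = regex)
}

# parameter sets and link functions per model variant
model_parameter_table <- list(
  mixture2p = list(kappa = "log", thetat = "identity"),
  mixture3p = list(kappa = "log", thetat = "identity", thetant = "identity"),
  imm_abc   = list(kappa = "log", c = "log", a = "log"),
  imm_bsc   = list(kappa = "log", c = "log", s = "log"),
  imm_full  = list(kappa = "log", c = "log", a = "log", s = "log")
)

new_wmm_model <- function(name, resp_error, nt_features = NULL,
                          set_size = NULL, nt_distances = NULL, regex = FALSE) {
  if (!name %in% names(model_parameter_table)) {
    stop("unknown model: ", name)
  }
  structure(list(
    name = name,
    parameters = model_parameter_table[[name]],
    fixed = c(mu_target = 0, mu_uniform = 0, log_kappa_uniform = -100,
              theta_guess = 0, b = 1),
    vars = list(resp_error = resp_error, nt_features = nt_features,
                set_size = set_size, nt_distances = nt_distances,
                regex = regex)
  ), class = "wmm_model")
}

#' @export
print.wmm_model <- function(x, ...) {
  cat("<wmm_model>", x$name, "\n")
  cat("  parameters:",
      paste(sprintf("%s (%s)", names(x$parameters), unlist(x$parameters)),
            collapse = ", "), "\n")
  cat("  fixed: mu = 0, log kappa_uniform = -100, theta_guess = 0",
      if (startsWith(x$name, "imm")) ", b = 1" else "", "\n", sep = "")
  cat("  response:", x$vars$resp_error, "\n")
  if (!is.null(x$vars$set_size)) cat("  set size:", x$vars$set_size, "\n")
  invisible(x)
}

#' Mixture component layout for a trial
#'
#' Returns the ordered component roles of the response mixture at a given
#' set size `n`: the target, `n - 1` non-target (swap) components, and the
#' guessing component. The two-parameter mixture never has non-target
#' components; at set size 1 all models reduce to (target, guess).
#'
#' @param model A `wmm_model`.
#' @param set_size Integer `>= 1`.
#' @return Character vector of component roles, e.g.
#'   `c("target", "nontarget_1", ..., "guess")`.
#' @examples
#' component_layout(mixture2p(), 6)
#' component_layout(mixture3p("e", "nt1", "n"), 4)
#' @export
component_layout <- function(model, set_size) {
  stopifnot(inherits(model, "wmm_model"))
  set_size <- as.integer(set_size)
  if (is.na(set_size) || set_size < 1) stop("`set_size` must be >= 1")
  m <- if (model$name == "mixture2p") 0L else set_size - 1L
  c("target", if (m > 0) paste0("nontarget_", seq_len(m)), "guess")
}

resolve_model_columns <- function(model, data) {
  v <- model$vars
  resolve <- function(x) {
    if (is.null(x)) return(NULL)
    if (isTRUE(v$regex) && length(x) == 1L) {
      hits <- grep(x, names(data), value = TRUE)
      if (length(hits) == 0L) stop("no columns match pattern '", x, "'")
      return(hits)
    }
    x
  }
  list(resp_error = v$resp_error,
       nt_features = resolve(v$nt_features),
       set_size = v$set_size,
       nt_distances = resolve(v$nt_distances))
}
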