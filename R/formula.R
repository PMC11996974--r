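#' Per-parameter model formulas
#'
#' `wmf()` collects one linear-model formula per estimable model parameter,
#' e.g. `wmf(kappa ~ 0 + setsize + (0 + setsize || subID), thetat ~ ...)`.
#' The left-hand side names the parameter to be predicted; the right-hand
#' side may contain fixed-effect terms and random-effect terms in
#' parentheses:
#'
#' * `(terms | group)` — random effects with estimated correlations,
#' * `(terms || group)` — uncorrelated random effects,
#' * `gr(group, by = stratum)` in the group slot — stratified grouping:
#'   separate random-effect standard deviations per level of `stratum`
#'   (e.g. different between-subject variability per age group).
#'
#' `0 +` suppresses the intercept (cell-means coding of a factor); `0` and
#' `1` markers are mutually exclusive within one part.
#'
#' @param ... Formulas, one per parameter.
#' @return A `wmm_formula` object: a list of parsed per-parameter formulas.
#' @examples
#' wmf(kappa ~ 0 + setsize + (0 + setsize || subID),
#'     thetat ~ 0 + setsize + (0 + setsize || subID))
#' @export
wmf <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1]]) && !inherits(fs[[1]], "formula")) {
    fs <- fs[[1]]
  }
  parsed <- lapply(fs, parse_parameter_formula)
  names(parsed) <- vapply(parsed, `[[`, character(1), "parameter")
  if (anyDuplicated(names(parsed))) {
    stop("duplicate formula for parameter(s): ",
         paste(unique(names(parsed)[duplicated(names(parsed))]), collapse = ", "))
  }
  structure(parsed, class = "wmm_formula")
}

#' @export
print.wmm_formula <- function(x, ...) {
  cat("<wmm_formula>\n")
  for (pf in x) {
    rand <- vapply(pf$random, function(r) {
      bar <- if (r$correlated) "|" else "||"
      grp <- if (is.null(r$by)) r$group else sprintf("gr(%s, by = %s)", r$group, r$by)
      sprintf("(%s %s %s)", deparse_rhs(r$terms, r$intercept), bar, grp)
    }, character(1))
    cat(" ", pf$parameter, "~",
        paste(c(deparse_rhs(pf$fixed_terms, pf$intercept), rand), collapse = " + "),
        "\n")
  }
  invisible(x)
}

deparse_rhs <- function(terms, intercept) {
  if (length(terms) == 0L) return(if (intercept) "1" else "0")
  paste(c(if (!intercept) "0", vapply(terms, function(t) paste(deparse(t), collapse = ""), character(1))),
        collapse = " + ")
}

# split a call into its top-level `+` terms
split_plus <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("+")) && length(e) == 3L) {
    c(split_plus(e[[2]]), split_plus(e[[3]]))
  } else {
    list(e)
  }
}

is_bar_call <- function(e) {
  is.call(e) && (identical(e[[1]], as.name("|")) || identical(e[[1]], as.name("||")))
}

# classify a term list into intercept flag + non-marker terms
scan_intercept <- function(terms, context) {
  markers <- vapply(terms, function(t) is.numeric(t) && t %in% c(0, 1), logical(1))
  vals <- unlist(terms[markers])
  if (length(vals) > 1L) {
    stop("conflicting intercept markers ('0'/'1') in ", context,
         ": specify at most one of `0 +` or `1 +`")
  }
  list(intercept = !(length(vals) == 1L && vals == 0), terms = terms[!markers])
}

parse_group_expr <- function(e) {
  if (is.name(e)) return(list(group = as.character(e), by = NULL))
  if (is.call(e) && identical(e[[1]], as.name("gr"))) {
    args <- as.list(e)[-1]
    nm <- names(args)
    if (is.null(nm)) nm <- rep("", length(args))
    grp <- if (any(nm == "")) args[[which(nm == "")[1]]] else args[["group"]]
    by <- if ("by" %in% nm) args[["by"]] else NULL
    if (is.null(grp) || !is.name(grp)) stop("gr() needs a grouping variable")
    if (!is.null(by) && !is.name(by)) stop("gr(by = ) must name a factor")
    return(list(group = as.character(grp),
                by = if (is.null(by)) NULL else as.character(by)))
  }
  stop("malformed grouping term: ", paste(deparse(e), collapse = ""))
}

parse_parameter_formula <- function(f) {
  if (!inherits(f, "formula") || length(f) != 3L) {
    stop("each formula must have the form `parameter ~ predictors`")
  }
  lhs <- f[[2]]
  if (!is.name(lhs)) stop("left-hand side must be a single parameter name")
  terms <- split_plus(f[[3]])

  # peel parentheses; a parenthesised bar call is a random-effect term
  random <- list()
  fixed <- list()
  for (t in terms) {
    inner <- t
    while (is.call(inner) && identical(inner[[1]], as.name("(")) && length(inner) == 2L) {
      inner <- inner[[2]]
    }
    if (is_bar_call(inner)) {
      correlated <- identical(inner[[1]], as.name("|"))
      lhs_terms <- scan_intercept(split_plus(inner[[2]]),
                                  "random-effect term")
      grp <- parse_group_expr(inner[[3]])
      random[[length(random) + 1L]] <- list(
        terms = lhs_terms$terms, intercept = lhs_terms$intercept,
        group = grp$group, by = grp$by, correlated = correlated)
    } else if (is_bar_call(t)) {
      stop("random-effect terms must be parenthesised: (terms | group)")
    } else {
      fixed[[length(fixed) + 1L]] <- t
    }
  }
  fx <- scan_intercept(fixed, sprintf("fixed part of '%s'", as.character(lhs)))
  list(parameter = as.character(lhs),
       fixed_terms = fx$terms, intercept = fx$intercept,
       random = random)
}

check_formula_parameters <- function(formula, model) {
  est <- names(model$parameters)
  given <- names(formula)
  unknown <- setdiff(given, est)
  if (length(unknown)) {
    stop("formula given for parameter(s) not in model '", model$name, "': ",
         paste(unknown, collapse = ", "),
         " (estimable: ", paste(est, collapse = ", "), ")")
  }
  # parameters without a formula get an intercept-only default
  missing <- setdiff(est, given)
  for (p in missing) {
    formula[[p]] <- list(parameter = p, fixed_terms = list(),
                         intercept = TRUE, random = list())
  }
  structure(formula[est], class = "wmm_formula")
}
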