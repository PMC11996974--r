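#' Contrast schemes for factor predictors
#'
#' `succ_diff_contrast(k)` builds the successive-difference (forward
#' difference) coding for a `k`-level factor: with an intercept, the
#' intercept is the mean of level 1 and coefficient `j` is
#' `mean(level j+1) - mean(level j)`. The design row for level `i` has 1s
#' in the first `i - 1` difference columns, so non-negative coefficients
#' (enforced with an `lb = 0` prior) imply a monotonically non-decreasing
#' pattern across levels.
#'
#' `contrast_scheme()` returns the contrast matrix for one of the named
#' schemes: `"treatment"` (dummy coding, the default for factors),
#' `"successive_difference"`, or `"cell_means"` (identity coding, intended
#' for `0 +` formulas).
#'
#' @param k Number of factor levels, `>= 1`.
#' @param name Scheme name.
#' @return A `k x (k - 1)` contrast matrix (`k x k` identity for
#'   `"cell_means"`).
#' @examples
#' succ_diff_contrast(4)
#' @export
succ_diff_contrast <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("`k` must be >= 1")
  m <- matrix(0, k, max(k - 1L, 0L))
  if (k > 1L) {
    # row i: 1s in columns 1..(i-1)
    for (j in seq_len(k - 1L)) m[(j + 1L):k, j] <- 1
    colnames(m) <- paste0("d", 2:k)
  }
  rownames(m) <- seq_len(k)
  m
}

#' @rdname succ_diff_contrast
#' @export
contrast_scheme <- function(name = c("treatment", "successive_difference", "cell_means"), k) {
  name <- match.arg(name)
  switch(name,
    treatment = stats::contr.treatment(k),
    successive_difference = succ_diff_contrast(k),
    cell_means = diag(k)
  )
}

terms_to_formula <- function(terms, intercept) {
  rhs <- if (length(terms) == 0L) {
    if (intercept) quote(1) else quote(0)
  } else {
    e <- terms[[1]]
    if (length(terms) > 1L) {
      for (t in terms[-1]) e <- call("+", e, t)
    }
    if (!intercept) e <- call("+", quote(0), e)
    e
  }
  stats::as.formula(call("~", rhs))
}

# contrasts: named list factor -> scheme name or contrast matrix
contrasts_arg_for <- function(data, f, contrasts) {
  vars <- all.vars(f)
  out <- list()
  for (v in vars) {
    if (!v %in% names(data)) next
    if (is.factor(data[[v]]) && v %in% names(contrasts)) {
      sch <- contrasts[[v]]
      k <- nlevels(data[[v]])
      m <- if (is.character(sch)) contrast_scheme(sch, k) else sch
      if (is.matrix(m) && ncol(m) == k) {
        # identity / cell-means coding only makes sense without an intercept;
        # model.matrix handles that via the 0 + marker in the formula
        rownames(m) <- levels(data[[v]])
      }
      out[[v]] <- m
    }
  }
  if (length(out)) out else NULL
}

model_matrix_part <- function(terms, intercept, data, contrasts, context) {
  f <- terms_to_formula(terms, intercept)
  vars <- all.vars(f)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("unknown column(s) in ", context, ": ",
         paste(missing_vars, collapse = ", "))
  }
  X <- stats::model.matrix(f, data = data,
                           contrasts.arg = contrasts_arg_for(data, f, contrasts))
  if (nrow(X) != nrow(data)) {
    stop("missing values in predictor columns of ", context,
         " are not allowed")
  }
  colnames(X) <- clean_coef_names(colnames(X))
  X
}

clean_coef_names <- function(x) {
  x <- sub("^\\(Intercept\\)$", "Intercept", x)
  gsub("[^A-Za-z0-9_.:]", "", x)
}

#' Build design matrices for every model parameter
#'
#' Realises a [wmf()] formula set against a trial table: one fixed-effect
#' design matrix per parameter plus random-effect blocks (group index maps,
#' per-group coefficient structure, correlation flags, and stratified
#' standard-deviation indexing for `gr(group, by = stratum)` terms).
#' Construction is deterministic given `(formula, data, contrasts)`.
#'
#' @param formula A `wmm_formula`.
#' @param data A data frame with one row per trial.
#' @param contrasts Named list mapping factor columns to a contrast scheme
#'   name (see [contrast_scheme()]) or matrix. Factors not listed use
#'   treatment (dummy) coding.
#' @param model Optional `wmm_model`; when given, formula parameters are
#'   checked against the model's estimable parameters and intercept-only
#'   formulas are filled in for parameters without one.
#' @return A `wmm_design` object: per parameter, `X` (fixed design),
#'   `coef_names`, and `random` blocks each with `Z`, `group_index`,
#'   `sd_index` (term x group-level -> SD parameter), and names.
#' @export
build_design <- function(formula, data, contrasts = list(), model = NULL) {
  stopifnot(inherits(formula, "wmm_formula"), is.data.frame(data))
  if (!is.null(model)) formula <- check_formula_parameters(formula, model)
  design <- lapply(formula, function(pf) {
    par <- pf$parameter
    X <- model_matrix_part(pf$fixed_terms, pf$intercept, data, contrasts,
                           sprintf("fixed part of '%s'", par))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
      stop("rank-deficient fixed design for '", par, "': aliased column(s) ",
           paste(aliased, collapse = ", "))
    }
    coef_names <- paste0("b_", par, "_", colnames(X))
    random <- lapply(seq_along(pf$random), function(i) {
      r <- pf$random[[i]]
      Z <- model_matrix_part(r$terms, r$intercept, data, contrasts,
                             sprintf("random part %d of '%s'", i, par))
      if (!r$group %in% names(data)) {
        stop("unknown grouping variable '", r$group, "' for '", par, "'")
      }
      g <- factor(data[[r$group]])
      gi <- as.integer(g)
      n_g <- nlevels(g)
      if (!is.null(r$by)) {
        if (!r$by %in% names(data)) {
          stop("unknown stratification variable '", r$by, "'")
        }
        by_f <- factor(data[[r$by]])
        # each group level must fall in exactly one stratum
        tab <- table(g, by_f) > 0
        if (any(rowSums(tab) != 1L)) {
          stop("grouping variable '", r$group,
               "' is not nested in stratification factor '", r$by, "'")
      }
        stratum_of_group <- apply(tab, 1, which)
        strata_levels <- levels(by_f)
      } else {
        stratum_of_group <- rep(1L, n_g)
        strata_levels <- NULL
      }
      q <- ncol(Z)
      term_names <- colnames(Z)
      sd_names <- if (is.null(strata_levels)) {
        paste0("sd_", r$group, "_", par, "_", term_names)
      } else {
        as.vector(outer(term_names, strata_levels, function(t, s) {
          paste0("sd_", r$group, ".", clean_coef_names(s), "_", par, "_", t)
        }))
      }
      cor_names <- character(0)
      if (r$correlated && q > 1L) {
        pairs <- which(lower.tri(matrix(0, q, q)), arr.ind = TRUE)
        cor_names <- paste0("cor_", r$group, "_", par, "_",
                            term_names[pairs[, 2]], "_", term_names[pairs[, 1]])
      }
      list(Z = Z, group = r$group, group_levels = levels(g),
           group_index = gi, n_groups = n_g, q = q,
           term_names = term_names, correlated = r$correlated && q > 1L,
           stratum_of_group = stratum_of_group,
           n_strata = max(stratum_of_group), strata_levels = strata_levels,
           sd_names = sd_names, cor_names = cor_names,
           z_names = as.vector(outer(term_names, levels(g), function(t, g2) {
             paste0("r_", r$group, "_", par, "[", g2, ",", t, "]")
           })))
    })
    list(parameter = par, X = X, coef_names = coef_names, random = random)
  })
  structure(list(parameters = design, n = nrow(data)), class = "wmm_design")
}
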