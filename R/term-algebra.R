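#' Model terms and hierarchical term sets
#'
#' A term is a non-empty set of variable labels; its order is the number of
#' labels. Order-1 terms are main effects; higher orders are interactions.
#' Polynomial labels (age2, age3, cal2, cal3) may only appear as main
#' effects: interactions involve the linear component of numeric variables
#' only. A model specification is a set of terms that is hierarchically
#' closed: every non-empty subset of every term's variables is itself a
#' term of the model, so a 5-way interaction brings along all its 4-, 3-,
#' and 2-way interactions and main effects.
#'
#' @name term-algebra
NULL

#' Construct a term from variable labels
#'
#' @param vars Character vector of distinct variable labels.
#' @return Sorted character vector with class checks applied.
#' @export
new_term <- function(vars) {
  vars <- as.character(vars)
  if (length(vars) == 0L) stop("a term must contain at least one variable")
  if (anyDuplicated(vars)) stop("duplicate variable labels in term")
  if (length(vars) >= 2L && any(vars %in% poly_vars()))
    stop("polynomial labels may appear only in main-effect terms")
  sort(vars)
}

#' Serialize a term as its sorted `+`-joined label
#' @param vars Term (character vector of labels).
#' @return Single string, e.g. `"COPD+DEM+sex_female"`.
#' @export
term_label <- function(vars) paste(sort(vars), collapse = "+")

#' Parse a serialized term label
#' @param label String produced by [term_label()].
#' @return Sorted character vector of labels.
#' @export
parse_term <- function(label) new_term(strsplit(label, "+", fixed = TRUE)[[1L]])

term_order <- function(vars) length(vars)

# All non-empty proper+improper subsets of a variable set, as labels.
term_subsets <- function(vars) {
  n <- length(vars)
  out <- character(0)
  for (k in seq_len(n)) {
    cmb <- utils::combn(vars, k, simplify = FALSE)
    out <- c(out, vapply(cmb, term_label, ""))
  }
  out
}

#' Construct a model specification
#'
#' @param terms List of terms (character vectors) or serialized labels.
#' @param mode One of `"ALL"`, `"DIO"`, `"OME"`, `"STABLE"`.
#' @return A `model_spec`: named list of terms keyed by label, with mode.
#' @export
model_spec <- function(terms = list(), mode = "ALL") {
  if (length(terms) && is.character(terms)) terms <- as.list(terms)
  terms <- lapply(terms, function(t)
    if (length(t) == 1L && grepl("+", t, fixed = TRUE)) parse_term(t) else new_term(t))
  labels <- vapply(terms, term_label, "")
  terms <- terms[!duplicated(labels)]
  names(terms) <- labels[!duplicated(labels)]
  terms <- terms[order(lengths(terms), names(terms))]
  out <- structure(list(terms = terms, mode = mode), class = "model_spec")
  validate_model_spec(out)
  out
}

#' Validate hierarchical closure of a model specification
#' @param model A `model_spec`.
#' @return The model, invisibly; errors if not hierarchically closed.
#' @export
validate_model_spec <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  labs <- names(model$terms)
  for (t in model$terms) {
    if (length(t) < 2L) next
    miss <- setdiff(term_subsets(t), labs)
    if (length(miss))
      stop("model is not hierarchically closed: term '", term_label(t),
           "' lacks subset term(s) ", paste(miss, collapse = ", "))
  }
  if (identical(model$mode, "OME") && any(lengths(model$terms) > 1L))
    stop("OME models contain only main-effect terms")
  invisible(model)
}

#' @export
print.model_spec <- function(x, ...) {
  ords <- lengths(x$terms)
  cat("model_spec (mode ", x$mode, "): ", length(x$terms), " terms",
      if (length(ords)) paste0(", max order ", max(ords)), "\n", sep = "")
  if (length(ords)) {
    tab <- table(factor(ords, levels = seq_len(max(ords))))
    cat("  terms by order:", paste(sprintf("%d-way: %d", seq_along(tab), tab),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchical closure of a term set
#'
#' Returns the minimal superset of `terms` that is hierarchically closed,
#' i.e. also contains every lower-order interaction and main effect implied
#' by each term.
#'
#' @param terms List of terms (character vectors) or serialized labels.
#' @param mode Mode tag for the resulting [model_spec()].
#' @return A hierarchically closed `model_spec`.
#' @export
close_hierarchy <- function(terms = list(), mode = "ALL") {
  if (length(terms) && is.character(terms)) terms <- as.list(terms)
  terms <- lapply(terms, function(t)
    if (length(t) == 1L && grepl("+", t, fixed = TRUE)) parse_term(t) else new_term(t))
  all_labels <- unique(unlist(lapply(terms, term_subsets)))
  model_spec(lapply(all_labels, parse_term), mode = mode)
}

# Does the model contain this term?
has_term <- function(model, vars) term_label(vars) %in% names(model$terms)

# Add a term (and its hierarchical closure) to a model.
add_term_closed <- function(model, vars) {
  model_spec(c(model$terms, lapply(term_subsets(new_term(vars)), parse_term)),
             mode = model$mode)
}

# Drop one term by label (caller must keep closure valid).
drop_term <- function(model, label) {
  model_spec(model$terms[setdiff(names(model$terms), label)], mode = model$mode)
}

# Terms of order >= 2 with no retained superset: the only ones whose removal
# keeps the model hierarchically closed.
removable_terms <- function(model, within = NULL) {
  labs <- names(model$terms)
  cand <- labs[lengths(model$terms) >= 2L]
  if (!is.null(within)) cand <- intersect(cand, within)
  keep <- vapply(cand, function(lab) {
    t <- model$terms[[lab]]
    !any(vapply(model$terms, function(o)
      length(o) > length(t) && all(t %in% o), logical(1)))
  }, logical(1))
  cand[keep]
}

#' Enumerate candidate k-way interaction terms
#'
#' All k-subsets of `allowed_vars` not already in the model for which at
#' least one (k-1)-subset is present — the "add a single k-way interaction
#' to an already existing (k-1)-way interaction" rule of the hierarchical
#' forward search. Polynomial labels never enter interactions.
#'
#' @param model Hierarchically closed `model_spec`.
#' @param k Interaction order, `k >= 2`.
#' @param allowed_vars Variables eligible for interactions (diseases plus,
#'   outside diseases-only mode, the linear intrinsic variables).
#' @return List of candidate terms (sorted character vectors).
#' @export
candidate_k_terms <- function(model, k, allowed_vars) {
  if (k < 2L) stop("interaction order k must be >= 2")
  validate_model_spec(model)
  allowed_vars <- setdiff(allowed_vars, poly_vars())
  if (length(allowed_vars) < k) return(list())
  labs <- names(model$terms)
  cmb <- utils::combn(sort(allowed_vars), k, simplify = FALSE)
  keep <- vapply(cmb, function(s) {
    if (term_label(s) %in% labs) return(FALSE)
    subs <- utils::combn(s, k - 1L, simplify = FALSE)
    any(vapply(subs, term_label, "") %in% labs)
  }, logical(1))
  cmb[keep]
}

#' Expand one term into design-matrix columns
#'
#' A term's columns are the row-wise product of its component variables'
#' columns. The education factor contributes one dummy column per
#' non-reference level, so any term containing education expands to 5
#' columns; all other variables contribute a single column.
#'
#' @param term Term (character vector of labels).
#' @param data data.frame of interval covariates (disease indicators,
#'   `sex_female`, `edu_*` dummies, centered `age`/`cal` and polynomials).
#' @return Numeric matrix with one column per expanded design column.
#' @export
design_columns <- function(term, data) {
  term <- new_term(term)
  cols_per_var <- lapply(term, var_columns)
  missing <- setdiff(unlist(cols_per_var), names(data))
  if (length(missing))
    stop("covariate column(s) missing from interval data: ",
         paste(missing, collapse = ", "))
  grid <- expand.grid(cols_per_var, stringsAsFactors = FALSE)
  out <- matrix(0, nrow = nrow(data), ncol = nrow(grid))
  nm <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    comp <- sort(unlist(grid[i, ], use.names = FALSE))
    v <- rep(1, nrow(data))
    for (cn in comp) v <- v * data[[cn]]
    out[, i] <- v
    nm[i] <- paste(comp, collapse = ":")
  }
  colnames(out) <- nm
  out
}

# Full design matrix for a model over interval data; returns the matrix and
# a column->term map used for block selection/removal and LRT df counting.
build_design <- function(model, data) {
  validate_model_spec(model)
  design_for_terms(model$terms, data)
}

# Same, for a plain named list of terms (no closure validation) — used where
# the term universe is closed by construction. Exploits hierarchical
# closure: a k-way term's columns are its (k-1)-way parent's columns times
# one more base column, so each design column costs one elementwise
# multiply.
design_for_terms <- function(terms, data) {
  if (is.null(names(terms)))
    names(terms) <- vapply(terms, term_label, "")
  terms <- terms[order(lengths(terms), names(terms))]
  cache <- new.env(parent = emptyenv())
  mats <- vector("list", length(terms))
  names(mats) <- names(terms)
  for (ti in seq_along(terms)) {
    t <- terms[[ti]]
    lab <- names(terms)[ti]
    m <- NULL
    if (length(t) >= 2L) {
      # drop a non-education variable whose removal leaves a cached parent
      for (drop_v in rev(setdiff(t, "education"))) {
        parent <- get0(term_label(setdiff(t, drop_v)), envir = cache)
        if (!is.null(parent)) {
          col <- data[[drop_v]]
          m <- parent * col
          colnames(m) <- vapply(strsplit(colnames(parent), ":", fixed = TRUE),
                                function(cc) paste(sort(c(cc, drop_v)),
                                                   collapse = ":"), "")
          break
        }
      }
    }
    if (is.null(m)) m <- design_columns(t, data)
    assign(lab, m, envir = cache)
    mats[[ti]] <- m
  }
  X <- do.call(cbind, c(mats, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(0, nrow(data), 0)
  colmap <- data.frame(
    column = unlist(lapply(mats, colnames), use.names = FALSE),
    term = rep(names(terms), vapply(mats, ncol, 0L)),
    stringsAsFactors = FALSE)
  colnames(X) <- colmap$column
  list(X = X, colmap = colmap)
}
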