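#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_invalid(name, " must be a single integer >= ", min)
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_invalid(name, " must be a single nonnegative number")
  as.numeric(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("a single numeric seed is required")
  as.integer(seed %% .Machine$integer.max)
}

#' Run code with a local RNG seed
#'
#' Evaluates `expr` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb each other.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(check_seed(seed))
  expr
}

## Deterministic per-stage seed derived from a global seed and a stage name,
## kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

check_square_labeled <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_invalid(name, " must be a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_invalid(name, " must carry row and column labels")
  if (!identical(rownames(m), colnames(m)))
    stop_invalid(name, " row and column labels must match")
  if (any(!is.finite(m))) stop_invalid(name, " must contain finite values")
  invisible(m)
}

check_distance_matrix <- function(m, name = "distance matrix", tol = 1e-12) {
  check_square_labeled(m, name)
  if (any(abs(m - t(m)) > tol)) stop_invalid(name, " must be symmetric")
  if (any(abs(diag(m)) > tol)) stop_invalid(name, " must have a zero diagonal")
  if (any(m < -tol)) stop_invalid(name, " must be nonnegative")
  invisible(m)
}

upper_pairs <- function(m) m[upper.tri(m)]

## Align matrix b's labels to matrix a's label order, erroring with the
## symmetric difference when the label sets disagree.
align_labels <- function(a, b, what = "matrices") {
  la <- rownames(a); lb <- rownames(b)
  if (!setequal(la, lb)) {
    miss <- c(setdiff(la, lb), setdiff(lb, la))
    stop_invalid("label sets of the two ", what, " differ: ",
                 paste(sort(miss), collapse = ", "))
  }
  b[la, la, drop = FALSE]
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid(name, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
  invisible(df)
}

## One-sided permutation p with the plus-one correction; never exactly 0.
perm_pvalue <- function(observed, null_values, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    (1 + sum(null_values >= observed)) / (length(null_values) + 1)
  } else {
    (1 + sum(abs(null_values) >= abs(observed))) / (length(null_values) + 1)
  }
}
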