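#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor hclust cutree as.dist phyper p.adjust t.test quantile
#'   rnorm runif sd setNames aggregate
#' @importFrom utils read.delim write.table packageVersion
NULL

# Consistent argument-error helper: all user-facing validation failures go
# through here so tests can match on the class.
abort_arg <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("syncomr_arg_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_arg("`seed` must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_arg("`%s` must be a single integer >= %d (got %s)", name, min,
              paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_arg("`%s` must be a single number", name)
  }
  if (strict && x <= min) abort_arg("`%s` must be > %g", name, min)
  if (!strict && x < min) abort_arg("`%s` must be >= %g", name, min)
  as.numeric(x)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_arg("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the pair-counting contingency table. Used throughout the
#' test-suite to score recovery of planted module structure.
#'
#' @param a,b vectors of cluster labels over the same items (matched by
#'   names when both are named, otherwise by position).
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort_arg("label vectors cover different item sets")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) abort_arg("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
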