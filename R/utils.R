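#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so seeded package operations never perturb the global
#' random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed for a named stage from one master seed.
# Keeps the result in [0, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483646)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Spot labels: 'A', 'B', ... then 'AA', 'AB', ... for pathological cases.
spot_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}

# Validate an expression matrix: numeric, finite, labelled, unique labels.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("`%s` must be a numeric matrix", arg)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("`%s` must carry gene rownames and sample colnames", arg)
  }
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate gene identifiers: %s",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stopf("duplicate sample identifiers: %s",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (!all(is.finite(x))) stopf("`%s` contains non-finite values", arg)
  invisible(x)
}

# Validate a sample -> class assignment against a matrix's samples.
check_classes <- function(classes, x) {
  classes <- as.character(classes[colnames(x)])
  names(classes) <- colnames(x)
  if (anyNA(classes)) {
    stopf("samples without class assignment: %s",
          paste(colnames(x)[is.na(classes)], collapse = ", "))
  }
  classes
}
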