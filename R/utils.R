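#' @importFrom withr with_seed
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Consistent error constructor so callers can grep message prefixes.
.stop <- function(..., call. = FALSE) stop(..., call. = call.)

# Validate a genes x samples expression matrix (possibly duplicated rownames
# before probe collapse).  Returns the matrix invisibly.
.check_expression <- function(x, require_unique_genes = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    .stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(colnames(x)))
    .stop("sample ids must be unique")
  if (require_unique_genes && anyDuplicated(rownames(x)))
    .stop("gene ids must be unique at this stage")
  if (anyNA(x) || any(!is.finite(x)))
    .stop("expression matrix contains missing or non-finite values")
  invisible(x)
}

# Validate a clinical table: sample_id, time (> 0), event (0/1).
.check_clinical <- function(clinical) {
  need <- c("sample_id", "time", "event")
  if (!is.data.frame(clinical) || !all(need %in% names(clinical)))
    .stop("clinical table must have columns sample_id, time, event")
  if (anyDuplicated(clinical$sample_id))
    .stop("clinical sample ids must be unique")
  if (!is.numeric(clinical$time) || any(!is.finite(clinical$time)) ||
      any(clinical$time <= 0))
    .stop("clinical time must be positive and finite")
  ev <- clinical$event
  if (!is.numeric(ev) || !all(ev %in% c(0, 1)))
    .stop("clinical event must be 0 (censored) or 1 (event)")
  invisible(clinical)
}

#' Align an expression matrix and clinical table on shared samples
#'
#' Samples present in only one of the two inputs are dropped with a warning;
#' the clinical rows are reordered to match the expression columns.
#'
#' @param expression numeric genes x samples matrix with sample colnames.
#' @param clinical data frame with columns `sample_id`, `time`, `event`.
#' @return list with elements `expression` and `clinical`, sample-aligned.
#' @export
align_cohort <- function(expression, clinical) {
  .check_expression(expression)
  .check_clinical(clinical)
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (length(shared) == 0L)
    .stop("no samples shared between expression and clinical tables")
  dropped <- (ncol(expression) - length(shared)) +
    (nrow(clinical) - length(shared))
  if (dropped > 0L)
    warning(sprintf("dropping %d sample(s) absent from one of the tables",
                    dropped), call. = FALSE)
  expression <- expression[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expression = expression, clinical = clinical)
}
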