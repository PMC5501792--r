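#' Generate a synthetic expression cohort with subtype-linked survival
#'
#' Emulates the structure the clustering pipeline assumes in real cohorts:
#' a z-scored genes x samples matrix with `k` latent subtypes of differing
#' mean profiles, and censored exponential survival whose hazard depends on
#' the subtype.  Subtype memberships are multinomial (resampled until every
#' subtype is represented); the first `g` genes are informative, split into
#' `k` disjoint contiguous blocks, with the block of subtype `c` shifted by
#' `delta` in that subtype's samples; the remaining `p - g` genes are pure
#' standard-normal noise.  Survival times are exponential with rate
#' `lambdas[subtype]`; censoring is independent uniform on `(0, u)` with
#' `u` solved numerically so the expected censoring fraction equals
#' `censor_rate`.  The expression matrix is finally z-scored per gene.
#'
#' @param n samples.
#' @param p genes.
#' @param k subtypes.
#' @param g informative genes (`g <= p`).
#' @param delta mean shift of the informative blocks (in pre-z-score
#'   standard-deviation units).
#' @param lambdas `k` positive exponential hazard rates (per study time
#'   unit, e.g. per month).
#' @param censor_rate target fraction of censored samples in `[0, 1)`.
#' @param seed integer seed; the cohort is reproducible from the
#'   parameters plus this seed.
#' @param weights optional subtype mixture weights (default uniform).
#' @return object of class `synthetic_cohort`: `expression` (z-scored
#'   p x n matrix), `clinical` (data frame `sample_id`, `time`, `event`),
#'   `true_labels` (named integer vector in 1..k), `params`.
#' @export
generate_cohort <- function(n, p = 2000L, k = 3L, g = 150L, delta = 1,
                            lambdas = NULL, censor_rate = 0.4, seed,
                            weights = NULL) {
  if (k < 2L) .stop("k must be at least 2")
  if (g > p) .stop("g must not exceed p")
  if (n < 2L * k) .stop("need at least 2 samples per subtype on average")
  if (censor_rate < 0 || censor_rate >= 1)
    .stop("censor_rate must be in [0, 1)")
  lambdas <- lambdas %||% (0.03 * 2^(seq_len(k) - 1L))
  if (length(lambdas) != k || any(lambdas <= 0))
    .stop("lambdas must be k positive rates")
  weights <- weights %||% rep(1 / k, k)
  .with_seed(seed, {
    labels <- .sample_full_labels(n, k, weights)
    mat <- matrix(stats::rnorm(p * n), nrow = p, ncol = n)
    if (g > 0L) {
      block <- sort(rep(seq_len(k), length.out = g))
      for (c_i in seq_len(k)) {
        rows <- which(block == c_i)
        cols <- which(labels == c_i)
        mat[rows, cols] <- mat[rows, cols] + delta
      }
    }
    dimnames(mat) <- list(sprintf("G%05d", seq_len(p)),
                          sprintf("S%04d", seq_len(n)))
    mat <- suppressWarnings(zscore_genes(mat))
    t_event <- stats::rexp(n, rate = lambdas[labels])
    if (censor_rate > 0) {
      u <- .censor_horizon(lambdas[labels], censor_rate)
      t_cens <- stats::runif(n, 0, u)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    time <- pmax(time, .Machine$double.eps)
    clinical <- data.frame(sample_id = colnames(mat), time = time,
                           event = event)
    structure(
      list(expression = mat, clinical = clinical,
           true_labels = stats::setNames(labels, colnames(mat)),
           params = list(n = n, p = p, k = k, g = g, delta = delta,
                         lambdas = lambdas, censor_rate = censor_rate,
                         weights = weights, seed = as.integer(seed))),
      class = "synthetic_cohort")
  })
}

# Multinomial subtype labels, redrawn until every subtype is represented.
.sample_full_labels <- function(n, k, weights) {
  for (i in seq_len(1000L)) {
    labels <- sample.int(k, n, replace = TRUE, prob = weights)
    if (length(unique(labels)) == k) return(labels)
  }
  .stop("could not populate all subtypes; increase n")
}

# Upper censoring horizon u such that, averaged over the cohort's hazard
# rates, P(C < T) = censor_rate for C ~ U(0, u), T ~ Exp(lambda):
# P(censored | lambda) = P(T > C) = (1 - exp(-lambda u)) / (lambda u),
# which decreases from 1 (u -> 0) to 0 (u -> Inf).
.censor_horizon <- function(lambda, censor_rate) {
  f <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u)) - censor_rate
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Write a deterministic suite of synthetic cohort fixtures
#'
#' Materializes a few small cohorts as plain text (expression TSV,
#' clinical TSV, true-label TSV and a JSON parameter sidecar per cohort)
#' for command-line and integration tests.  Repeated invocation with the
#' same seed reproduces the files byte for byte.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; each cohort derives its own sub-seed.
#' @param specs list of per-cohort parameter lists; the default covers
#'   n = 60/120/200 with k = 2/3/4.
#' @return character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(dir, seed,
                               specs = list(
                                 list(n = 60L, k = 2L),
                                 list(n = 120L, k = 3L),
                                 list(n = 200L, k = 4L))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    co <- generate_cohort(n = sp$n, p = sp$p %||% 300L, k = sp$k,
                          g = sp$g %||% 60L, delta = sp$delta %||% 3,
                          censor_rate = sp$censor_rate %||% 0.3,
                          seed = seed + i)
    stem <- file.path(dir, sprintf("cohort_n%d_k%d", sp$n, sp$k))
    write_expression(co$expression, paste0(stem, "_expression.tsv"))
    utils::write.table(co$clinical, paste0(stem, "_clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(co$true_labels),
                 subtype = unname(co$true_labels)),
      paste0(stem, "_truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(co$params, paste0(stem, "_params.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, paste0(stem, c("_expression.tsv", "_clinical.tsv",
                                         "_truth.tsv", "_params.json")))
  }
  invisible(written)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "synthetic_cohort: n = %d, p = %d, k = %d, g = %d, delta = %g\n",
    p$n, p$p, p$k, p$g, p$delta))
  cat(sprintf("events: %d / %d\n", sum(x$clinical$event), p$n))
  invisible(x)
}
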