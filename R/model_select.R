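#' One run of the Nystrom spectral clustering pipeline
#'
#' Composition of the core steps: sample `l` landmarks, build the Gaussian
#' similarity blocks, compute the row-normalized Nystrom embedding, and
#' cluster its rows with [lloyd_kmeans()].  The run is fully determined by
#' `(x, sigma, k, l, seed)`: the landmark draw and the k-means
#' initialization both derive from `seed`.
#'
#' @param x z-scored genes x samples expression matrix.
#' @param sigma Gaussian bandwidth.
#' @param k number of subtypes.
#' @param l landmark count; defaults to half the cohort,
#'   `floor(n / 2)`.  `l = n` is allowed and uses every sample as a
#'   landmark (the exact, approximation-free regime).
#' @param seed integer seed.
#' @param self_similarity diagonal convention of the kernel (see
#'   [gaussian_similarity_full()]).
#' @return a `cluster_assignment` with extra fields `sigma`, `l`,
#'   `landmarks`.
#' @export
run_csiscn_once <- function(x, sigma, k, l = NULL, seed,
                            self_similarity = 0) {
  n <- ncol(x)
  l <- as.integer(l %||% max(k + 1L, floor(n / 2)))
  if (l > n) .stop("l must not exceed n")
  landmarks <- if (l == n) seq_len(n) else
    sample_landmarks(n, l, seed)$landmarks
  blocks <- gaussian_similarity_blocks(x, landmarks, sigma, self_similarity)
  emb <- nystrom_embedding(blocks, k)
  U <- emb$U_tilde
  rownames(U) <- colnames(x)
  out <- lloyd_kmeans(U, k, seed)
  out$sigma <- sigma
  out$l <- l
  out$landmarks <- landmarks
  out
}

#' Survival-driven selection of the Gaussian bandwidth
#'
#' The training protocol: for every candidate bandwidth the pipeline is run
#' `n_runs` times (each run re-draws landmarks and the k-means
#' initialization from its own seed, `base_seed ... base_seed + n_runs - 1`),
#' every run's subtypes are scored by the log-rank p-value against the
#' cohort's survival, the per-candidate p-values are aggregated (median by
#' default; `min` and `mean` are available), and the bandwidth with the
#' smallest aggregate is selected, ties going to the smaller value.  A run
#' that fails (e.g. a degenerate degree vector at an extreme bandwidth) is
#' recorded with p = 1 and a warning, so the report always has the full
#' candidates x runs matrix.
#'
#' @param x z-scored genes x samples matrix.
#' @param clinical clinical table aligned (or alignable) to `x`; see
#'   [align_cohort()].
#' @param k number of subtypes.
#' @param candidates candidate bandwidths; default `c(20, 30, 40, 50)`.
#' @param n_runs pipeline runs per candidate (default 10).
#' @param base_seed first run seed.
#' @param l landmark count; default half the cohort.
#' @param aggregate how to summarize the runs' p-values per candidate.
#' @return object of class `sigma_selection`: `candidates`, `p_values`
#'   (|candidates| x n_runs matrix), `summary_p`, `chosen_sigma`, `k`,
#'   `n_runs`, `seeds`, `aggregate`.
#' @export
select_sigma <- function(x, clinical, k,
                         candidates = c(20, 30, 40, 50),
                         n_runs = 10L, base_seed = 1L, l = NULL,
                         aggregate = c("median", "min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(candidates) == 0L) .stop("no candidate bandwidths")
  if (any(candidates <= 0)) .stop("bandwidth candidates must be positive")
  al <- align_cohort(x, clinical)
  x <- al$expression
  clinical <- al$clinical
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  p <- matrix(NA_real_, nrow = length(candidates), ncol = n_runs,
              dimnames = list(paste0("sigma=", candidates),
                              paste0("run", seq_len(n_runs))))
  for (i in seq_along(candidates)) {
    for (r in seq_len(n_runs)) {
      p[i, r] <- tryCatch({
        cl <- run_csiscn_once(x, candidates[i], k, l = l, seed = seeds[r])
        logrank_test(clinical$time, clinical$event, cl$labels)$p_value
      }, error = function(e) {
        warning(sprintf("run failed for sigma = %g (seed %d): %s; p set to 1",
                        candidates[i], seeds[r], conditionMessage(e)),
                call. = FALSE)
        1
      })
    }
  }
  summary_p <- apply(p, 1L, aggregate)
  best <- which(summary_p == min(summary_p))
  chosen <- min(candidates[best])
  structure(
    list(candidates = candidates, p_values = p,
         summary_p = stats::setNames(summary_p, paste0("sigma=", candidates)),
         chosen_sigma = chosen, k = as.integer(k),
         n_runs = as.integer(n_runs), seeds = seeds, aggregate = aggregate),
    class = "sigma_selection")
}

#' Apply a selected bandwidth to a (test) cohort
#'
#' Runs the pipeline once with the given bandwidth and `l` equal to half
#' the cohort (the test-cohort convention), then evaluates the resulting
#' subtypes: per-subtype Kaplan-Meier curves, the k-sample log-rank test,
#' and (for `k = 2` with events in both subtypes) the Mantel-Haenszel
#' hazard ratio.
#'
#' @inheritParams select_sigma
#' @param sigma bandwidth, typically `chosen_sigma` from a prior
#'   [select_sigma()] on the training cohort.
#' @param seed run seed.
#' @return list with `assignment` (a `cluster_assignment`), `logrank`
#'   (a `logrank_result`), `km` (named list of `km_curve`), and
#'   `hazard_ratio` (a `hazard_ratio` or NULL), plus `sigma`, `k`, `l`.
#' @export
apply_to_cohort <- function(x, clinical, sigma, k, seed, l = NULL) {
  al <- align_cohort(x, clinical)
  x <- al$expression
  clinical <- al$clinical
  cl <- run_csiscn_once(x, sigma, k, l = l, seed = seed)
  lr <- logrank_test(clinical$time, clinical$event, cl$labels)
  km <- km_by_group(clinical$time, clinical$event, cl$labels)
  hr <- NULL
  if (k == 2L && all(lr$per_group_observed > 0))
    hr <- hazard_ratio_two_group(clinical$time, clinical$event, cl$labels)
  list(assignment = cl, logrank = lr, km = km, hazard_ratio = hr,
       sigma = sigma, k = as.integer(k), l = cl$l)
}

#' @export
print.sigma_selection <- function(x, ...) {
  cat(sprintf("sigma_selection: k = %d, %d run(s) per candidate (%s p)\n",
              x$k, x$n_runs, x$aggregate))
  print(data.frame(sigma = x$candidates,
                   summary_p = signif(x$summary_p, 4)),
        row.names = FALSE)
  cat("chosen sigma:", x$chosen_sigma, "\n")
  invisible(x)
}
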