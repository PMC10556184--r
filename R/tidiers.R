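#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_lmm Coefficient table as a plain tibble.
#' @param x A `pupil_fit`.
#' @param ... Unused.
#' @export
tidy.pupil_fit <- function(x, ...) {
  out <- x
  attributes(out)[c("converged", "n_used", "n_dropped", "formula",
                    "alpha", "window")] <- NULL
  class(out) <- setdiff(class(out), "pupil_fit")
  tibble::as_tibble(out)
}

#' @describeIn fit_lmm One-row model summary (n used/dropped, convergence).
#' @export
glance.pupil_fit <- function(x, ...) {
  tibble::tibble(
    n_used = attr(x, "n_used") %||% NA_integer_,
    n_dropped = attr(x, "n_dropped") %||% 0L,
    converged = attr(x, "converged") %||% NA
  )
}

#' @describeIn cluster_permutation_test Per-cluster table with p-values.
#' @param x A `pupil_clusterperm`.
#' @param ... Unused.
#' @export
tidy.pupil_clusterperm <- function(x, ...) {
  cl <- x$clusters
  dt <- 1000 / x$rate_hz
  cl$start_ms <- x$t0_ms + cl$start * dt
  cl$end_ms <- x$t0_ms + cl$end * dt
  cl
}

#' @describeIn cluster_permutation_test One-row summary: number of clusters,
#'   smallest cluster p (1 when no cluster exists), permutation count.
#' @export
glance.pupil_clusterperm <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    min_p_cluster = if (nrow(x$clusters)) min(x$clusters$p_cluster) else 1,
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}

#' @describeIn crossval_test Per-effect results with tested samples.
#' @param x A `pupil_cvtest`.
#' @param ... Unused.
#' @export
tidy.pupil_cvtest <- function(x, ...) {
  res <- x$results
  res$tested_samples <- apply(x$chosen, 1, function(v) {
    paste(sort(unique(v)), collapse = ",")
  })[match(res$term, rownames(x$chosen))]
  res
}

#' @describeIn crossval_test One-row summary of the cross-validation setup.
#' @export
glance.pupil_cvtest <- function(x, ...) {
  tibble::tibble(
    n_folds = length(unique(x$folds)),
    n_trials = length(x$folds),
    random = x$random,
    alpha = x$alpha
  )
}
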