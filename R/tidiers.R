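# broom-style tidy()/glance() methods for the fitted result objects.

#' Tidy a kinetic clustering result
#'
#' @param x A [cluster_kinetics()] result.
#' @param ... Unused.
#' @return The per-cluster summary tibble (label, size, direction,
#'   monotonicity rho, half-time, retention flag).
#' @export
tidy.kinetic_clusters <- function(x, ...) {
  as_tibble(x$clusters)
}

#' One-row summary of a kinetic clustering result
#'
#' @param x A [cluster_kinetics()] result.
#' @param ... Unused.
#' @return Tibble with the number of clusters, retained clusters and
#'   clustered genes.
#' @export
glance.kinetic_clusters <- function(x, ...) {
  tibble(
    k = nrow(x$clusters),
    n_retained = sum(x$clusters$retained),
    n_genes = nrow(x$members)
  )
}

#' Tidy a super-enhancer call
#'
#' @param x A [call_super_enhancers()] result.
#' @param ... Unused.
#' @return The stitched-region tibble with ranks and super-enhancer flags.
#' @export
tidy.se_call <- function(x, ...) {
  as_tibble(x$regions)
}

#' One-row summary of a super-enhancer call
#'
#' @param x A [call_super_enhancers()] result.
#' @param ... Unused.
#' @return Tibble with region and super-enhancer counts and the elbow
#'   cutoff signal.
#' @export
glance.se_call <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    n_super = sum(x$regions$is_super),
    cutoff_signal = x$cutoff_signal
  )
}

#' Tidy a burst-comparison result
#'
#' @param x A [compare_conditions()] result.
#' @param ... Unused.
#' @return Long tibble of the per-condition statistics.
#' @export
tidy.burst_comparison <- function(x, ...) {
  tibble(
    condition = c("condition0", "condition1"),
    n_cells = c(x$n_cells0, x$n_cells1),
    burst_fraction = c(x$fraction0, x$fraction1),
    mean_size = c(x$size_mean0, x$size_mean1)
  )
}

#' One-row summary of a burst-comparison result
#'
#' @param x A [compare_conditions()] result.
#' @param ... Unused.
#' @return Tibble with both test p-values and the modulation verdict.
#' @export
glance.burst_comparison <- function(x, ...) {
  tibble(
    fisher_p = x$fisher_p,
    size_t_p = x$size_t_p,
    modulation = x$modulation
  )
}

#' Tidy an enhancer-link result
#'
#' @param x A [link_enhancers()] result.
#' @param ... Unused.
#' @return The per-pair link tibble.
#' @export
tidy.enhancer_links <- function(x, ...) {
  as_tibble(x$links)
}

#' One-row summary of an enhancer-link result
#'
#' @param x A [link_enhancers()] result.
#' @param ... Unused.
#' @return Tibble with pair and link counts and the contact threshold used.
#' @export
glance.enhancer_links <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$links),
    n_linked = sum(x$links$linked),
    n_flagged = sum(x$links$flagged),
    c_min = x$c_min
  )
}
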