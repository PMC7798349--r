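#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a correlation network into its edge table
#'
#' @param x A `cor_network`.
#' @param ... Unused.
#' @return The edge tibble (one row per edge).
#' @export
tidy.cor_network <- function(x, ...) as_tibble(x$edges)

#' One-row topology summary of a network
#'
#' @inheritParams tidy.cor_network
#' @return The [network_topology()] tibble.
#' @export
glance.cor_network <- function(x, ...) network_topology(x)

#' Tidy NMDS sample coordinates
#'
#' @param x An `nmds` object.
#' @param ... Unused.
#' @return Tibble of per-sample ordination coordinates.
#' @export
tidy.nmds <- function(x, ...) x$points

#' One-row NMDS fit summary
#'
#' @inheritParams tidy.nmds
#' @return Tibble with `stress`, `k`, `iterations`, `converged`.
#' @export
glance.nmds <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, iterations = x$iterations,
         converged = x$converged)
}
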