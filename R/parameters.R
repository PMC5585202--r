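#' Density of an anatomical network
#'
#' Fraction of realized links among the `N (N - 1) / 2` possible ones:
#' `D = 2 K / (N (N - 1))`. Used in AnNA as a proxy for morphological
#' complexity — more contacts among parts allow more functional combinations.
#'
#' @param net an [anatomical_network()] with at least two nodes.
#' @return density in `[0, 1]`.
#' @export
density_parameter <- function(net) {
  nk <- network_size(net)
  if (nk[["N"]] < 2) stop("density is undefined for N < 2")
  2 * nk[["K"]] / (nk[["N"]] * (nk[["N"]] - 1))
}

#' Mean clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' `c_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` counts links among the
#' neighbours of node `i`; it measures the density of triangular motifs and is
#' used as a proxy for local integration of parts.
#'
#' @param net an [anatomical_network()].
#' @param low_degree how nodes with degree < 2 (for which `c_i` is undefined)
#'   enter the average: `"zero"` (default) counts them as 0, `"exclude"`
#'   drops them.
#' @return mean clustering coefficient in `[0, 1]`.
#' @details The two conventions differ in the published literature and cannot
#'   be discriminated from summary tables alone, hence both are exposed.
#' @export
clustering_coefficient <- function(net, low_degree = c("zero", "exclude")) {
  low_degree <- match.arg(low_degree)
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  if (low_degree == "exclude") {
    keep <- deg >= 2
    if (!any(keep)) return(0)
    return(mean(ci[keep]))
  }
  ci[deg < 2] <- 0
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered pairs of distinct nodes,
#' with every link one unit long. In AnNA it proxies the effective proximity
#' of anatomical parts (their potential to work together).
#'
#' @param net a connected [anatomical_network()] with at least two nodes.
#' @return mean shortest-path length (>= 1, with equality iff complete).
#' @export
characteristic_path_length <- function(net) {
  nk <- network_size(net)
  if (nk[["N"]] < 2) stop("path length is undefined for N < 2")
  conn <- is_connected(net)
  if (!conn$connected)
    stop("network is disconnected (component sizes: ",
         paste(conn$component_sizes, collapse = ", "),
         "); path length is undefined")
  Dm <- igraph::distances(as_igraph(net))
  mean(Dm[upper.tri(Dm)])
}

#' Degree heterogeneity
#'
#' Ratio of the standard deviation to the mean of the degree sequence. In
#' AnNA, heterogeneity proxies anisomerism: how unevenly connected (and hence
#' how differentiated) the parts of the structure are. `H = 0` iff all nodes
#' have the same degree.
#'
#' @param net an [anatomical_network()] with at least one link.
#' @param sd_type `"population"` (divide by N; default) or `"sample"`
#'   (divide by N - 1). Summary tables in the literature rarely state which
#'   estimator was used, so both are available.
#' @return nonnegative dimensionless ratio.
#' @export
heterogeneity <- function(net, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (network_size(net)[["K"]] < 1)
    stop("heterogeneity is undefined when the mean degree is 0")
  deg <- degree_sequence(net)$degree
  m <- mean(deg)
  v <- if (sd_type == "sample") stats::var(deg) else
    sum((deg - m)^2) / length(deg)
  sqrt(v) / m
}

#' Compute all six network parameters
#'
#' Returns the standard AnNA parameter tuple: nodes (N), links (K), density
#' (D), mean clustering coefficient (C), characteristic path length (L) and
#' degree heterogeneity (H).
#'
#' @inheritParams characteristic_path_length
#' @inheritParams clustering_coefficient
#' @inheritParams heterogeneity
#' @return an object of class `network_parameters`: a one-row data frame with
#'   columns `taxon`, `N`, `K`, `D`, `C`, `L`, `H`.
#' @examples
#' net <- generate_limb_network(limb_config(seed = 1))$network
#' network_parameters(net)
#' @export
network_parameters <- function(net, low_degree = c("zero", "exclude"),
                               sd_type = c("population", "sample")) {
  nk <- network_size(net)
  out <- data.frame(
    taxon = net$name,
    N = nk[["N"]],
    K = nk[["K"]],
    D = density_parameter(net),
    C = clustering_coefficient(net, low_degree),
    L = characteristic_path_length(net),
    H = heterogeneity(net, sd_type),
    stringsAsFactors = FALSE)
  class(out) <- c("network_parameters", "data.frame")
  out
}

#' Round half away from zero
#'
#' Published parameter tables round ties away from zero (e.g. a density of
#' 0.0505 is printed as 0.051), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a parameter table for reporting
#'
#' Rounds `D`, `C`, `L`, `H` half-away-from-zero to three decimals, the
#' convention of published comparative tables.
#'
#' @param params data frame as returned by [network_parameters()] (possibly
#'   several rows).
#' @param digits decimal places (default 3).
#' @return data frame with rounded numeric columns.
#' @export
format_parameter_table <- function(params, digits = 3) {
  for (col in intersect(c("D", "C", "L", "H"), colnames(params)))
    params[[col]] <- round_half_up(params[[col]], digits)
  params
}
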