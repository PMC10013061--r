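#' Build a patient's deviation-weighted network
#'
#' Nodes are the clinical variables appearing in at least one reference
#' pair; variables never screened into the reference set are excluded
#' entirely. An undirected edge joins each reference pair present in the
#' patient's profile, weighted by the orthogonal deviation. Pairs absent
#' because of missing data leave their nodes isolated.
#'
#' @param profile Named deviation vector from [compute_profile()], or a
#'   one-patient row of [compute_cohort_profiles()] output (`NA` = absent).
#' @param refset A [build_reference_set()] result.
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
build_network <- function(profile, refset) {
  stopifnot(inherits(refset, "parenclitic_refset"))
  pairs <- refset$pairs
  nodes <- intersect(clinical_variables(),
                     unique(c(pairs$x_var, pairs$y_var)))
  w <- unlist(profile[pairs$pair], use.names = FALSE)
  if (is.null(w)) w <- rep(NA_real_, nrow(pairs))
  present <- !is.na(w)
  edges <- data.frame(from = pairs$x_var[present],
                      to = pairs$y_var[present],
                      weight = w[present],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Global topology indices of a deviation-weighted network
#'
#' Deviations are read as distances: a larger deviation means a longer
#' path, i.e. weaker physiological connectivity. Indices:
#' \describe{
#'   \item{degree centrality}{weighted degree (strength): sum of incident
#'     edge weights per node; reported as its mean and sample (n-1)
#'     standard deviation over nodes.}
#'   \item{characteristic path length}{mean shortest-path distance over
#'     connected (finite) node pairs.}
#'   \item{diameter}{largest finite shortest-path distance.}
#'   \item{global efficiency}{mean of 1/distance over all node pairs, with
#'     unreachable pairs contributing 0.}
#' }
#' An edgeless graph returns 0 for every index.
#'
#' @param net Graph from [build_network()] (any undirected `igraph` graph
#'   with non-negative `weight` attribute).
#' @return List with `degree` (named vector), `mean_centrality`,
#'   `sd_centrality`, `char_path_length`, `diameter`, `global_efficiency`.
#' @export
compute_topology <- function(net) {
  n <- igraph::vcount(net)
  zero <- list(degree = stats::setNames(numeric(n), igraph::V(net)$name),
               mean_centrality = 0, sd_centrality = 0,
               char_path_length = 0, diameter = 0, global_efficiency = 0)
  if (n == 0 || igraph::ecount(net) == 0) return(zero)
  deg <- igraph::strength(net, weights = igraph::E(net)$weight)
  D <- igraph::distances(net, weights = igraph::E(net)$weight)
  d <- D[upper.tri(D)]
  fin <- d[is.finite(d)]
  list(degree = deg,
       mean_centrality = mean(deg),
       sd_centrality = if (n > 1) stats::sd(deg) else 0,
       char_path_length = if (length(fin)) mean(fin) else 0,
       diameter = if (length(fin)) max(fin) else 0,
       global_efficiency = if (length(d)) {
         mean(ifelse(is.finite(d) & d > 0, 1 / d,
                     ifelse(d == 0, Inf, 0)))
       } else 0)
}

#' Topology indices for a whole cohort
#'
#' @param profiles Output of [compute_cohort_profiles()].
#' @param refset A [build_reference_set()] result.
#' @return Data frame: `patient_id` plus one column per global index.
#' @export
compute_cohort_topology <- function(profiles, refset) {
  idx <- lapply(seq_len(nrow(profiles)), function(i) {
    net <- build_network(profiles[i, , drop = FALSE], refset)
    t <- compute_topology(net)
    c(mean_centrality = t$mean_centrality,
      sd_centrality = t$sd_centrality,
      char_path_length = t$char_path_length,
      diameter = t$diameter,
      global_efficiency = t$global_efficiency)
  })
  out <- as.data.frame(do.call(rbind, idx))
  out <- cbind(data.frame(patient_id = profiles$patient_id,
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
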