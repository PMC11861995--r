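#' Configuration for the two-cohort synthetic connectome generator
#'
#' Describes a synthetic stand-in for a two-cohort structural-connectome study:
#' an adult and a pediatric cohort of weighted, symmetric, non-negative
#' streamline-density-like connectivity matrices with (a) a planted sex effect
#' on a fixed subset of edges, (b) a cohort-level distribution shift mimicking
#' protocol and age differences, and (c) configurable class balance.
#'
#' Edge weights are built on the log scale and exponentiated, which guarantees
#' non-negative, heavy-tailed weights: for subject \eqn{i} and edge \eqn{(u,v)},
#' \deqn{A_{uv} = \exp(\mu_{uv} + c \cdot 1[\mathrm{pediatric}] +
#'       \beta M_{uv} \cdot 1[\mathrm{female}] + \varepsilon_{uv}),}
#' where \eqn{\mu_{uv}} encodes block (community) structure, \eqn{c} is
#' `cohort_shift`, \eqn{\beta} is `sex_effect_size`, \eqn{M} is a symmetric 0/1
#' mask drawn once per dataset covering `sex_edge_fraction` of off-diagonal
#' edges, and \eqn{\varepsilon_{uv} \sim N(0, \mathrm{noise\_sd}^2)} is
#' subject-specific edge noise. The mask is shared by all subjects so the group
#' difference is consistent and learnable.
#'
#' @param n_regions Number of atlas regions (graph nodes). Default 379, the
#'   size of the HCP-MMP1.0 parcellation; small values are fine for tests.
#' @param n_adult,n_pediatric Cohort sizes. Defaults 309 and 135.
#' @param female_fraction_adult,female_fraction_pediatric Probability of the
#'   female label (coded 1) per cohort. Defaults 0.534 and 0.563.
#' @param sex_effect_size Multiplicative log-scale shift applied to masked
#'   edges of female subjects. 0 plants no signal.
#' @param sex_edge_fraction Fraction of off-diagonal edge positions carrying
#'   the sex effect.
#' @param cohort_shift Global log-scale offset added to every edge of the
#'   pediatric cohort (the adult cohort is the reference).
#' @param noise_sd Standard deviation of subject-level Gaussian edge noise on
#'   the log scale.
#' @param n_blocks Number of communities in the base graph; within-block edges
#'   get a higher base weight.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @seealso [generate_dataset()]
#' @export
synthetic_config <- function(n_regions = 379,
                             n_adult = 309,
                             n_pediatric = 135,
                             female_fraction_adult = 0.534,
                             female_fraction_pediatric = 0.563,
                             sex_effect_size = 1.2,
                             sex_edge_fraction = 0.1,
                             cohort_shift = 0.3,
                             noise_sd = 0.2,
                             n_blocks = 5,
                             seed = 1L) {
  assert_scalar_number(n_regions, "n_regions", lower = 2)
  assert_scalar_number(n_adult, "n_adult", lower = 0)
  assert_scalar_number(n_pediatric, "n_pediatric", lower = 0)
  assert_scalar_number(female_fraction_adult, "female_fraction_adult", 0, 1)
  assert_scalar_number(female_fraction_pediatric, "female_fraction_pediatric", 0, 1)
  assert_scalar_number(sex_effect_size, "sex_effect_size", lower = 0)
  assert_scalar_number(sex_edge_fraction, "sex_edge_fraction", 0, 1)
  assert_scalar_number(cohort_shift, "cohort_shift", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(n_blocks, "n_blocks", lower = 1)
  assert_scalar_number(seed, "seed")
  structure(list(
    n_regions = as.integer(n_regions),
    n_adult = as.integer(n_adult),
    n_pediatric = as.integer(n_pediatric),
    female_fraction_adult = female_fraction_adult,
    female_fraction_pediatric = female_fraction_pediatric,
    sex_effect_size = sex_effect_size,
    sex_edge_fraction = sex_edge_fraction,
    cohort_shift = cohort_shift,
    noise_sd = noise_sd,
    n_blocks = as.integer(n_blocks),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Construct a single-subject connectome graph
#'
#' @param adjacency Symmetric, non-negative numeric matrix with zero diagonal
#'   (arbitrary streamline-density units).
#' @param label Binary sex label, 1 = female, 0 = male.
#' @param cohort `"adult"` or `"pediatric"`.
#' @param subject_id Subject identifier string.
#' @param node_features Optional numeric matrix with one row per region.
#'
#' @return An object of class `connectome_graph`.
#' @export
connectome_graph <- function(adjacency, label, cohort, subject_id,
                             node_features = NULL) {
  check_square_symmetric_nonneg(adjacency)
  if (any(diag(adjacency) != 0)) {
    stop("adjacency must have a zero diagonal", call. = FALSE)
  }
  if (!label %in% c(0, 1)) stop("label must be 0 (male) or 1 (female)", call. = FALSE)
  cohort <- match.arg(cohort, c("adult", "pediatric"))
  if (!is.null(node_features)) {
    if (!is.matrix(node_features) || nrow(node_features) != nrow(adjacency)) {
      stop("node_features must be a matrix with one row per region", call. = FALSE)
    }
  }
  structure(list(
    adjacency = adjacency,
    node_features = node_features,
    label = as.integer(label),
    cohort = cohort,
    subject_id = as.character(subject_id)
  ), class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf("<connectome_graph> %s: %d regions, %s, %s\n",
              x$subject_id, nrow(x$adjacency), x$cohort,
              if (x$label == 1) "female" else "male"))
  invisible(x)
}

#' Generate a synthetic two-cohort connectome dataset
#'
#' Draws `n_adult + n_pediatric` subjects under the log-additive edge model
#' described in [synthetic_config()]. Female counts per cohort are the rounded
#' target fractions (deterministic given the config); which subjects carry the
#' label is randomized under the config seed. Node features default to the
#' connectivity profile (each node's row of the adjacency matrix).
#'
#' @param config A [synthetic_config()].
#' @param features Node feature scheme passed to [make_node_features()];
#'   `"none"` leaves features unset.
#' @return A `connectome_dataset`: a list of [connectome_graph()] objects with
#'   the generating config attached as an attribute.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_regions = 20, n_adult = 6,
#'                                         n_pediatric = 4, seed = 1))
#' length(ds)
#' @export
generate_dataset <- function(config,
                             features = c("connectivity_profile", "degree",
                                          "one_hot", "none")) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created with synthetic_config()", call. = FALSE)
  }
  features <- match.arg(features)
  n <- config$n_regions
  set.seed(config$seed)

  # Base community structure: contiguous blocks, higher base log-weight within.
  blocks <- sort(rep_len(seq_len(config$n_blocks), n))
  same_block <- outer(blocks, blocks, "==")
  base_mu <- ifelse(same_block, 1.0, 0.0)

  ut <- upper.tri(matrix(0, n, n))
  n_edges <- sum(ut)

  # Sex-effect mask: one draw per dataset, shared by all subjects.
  n_masked <- round(config$sex_edge_fraction * n_edges)
  mask_vec <- rep(0, n_edges)
  if (n_masked > 0) mask_vec[sample.int(n_edges, n_masked)] <- 1
  M <- matrix(0, n, n)
  M[ut] <- mask_vec
  M <- M + t(M)

  build_cohort <- function(n_subj, female_fraction, cohort) {
    if (n_subj == 0) return(list())
    n_female <- round(n_subj * female_fraction)
    labels <- rep(0L, n_subj)
    if (n_female > 0) labels[sample.int(n_subj, n_female)] <- 1L
    shift <- if (cohort == "pediatric") config$cohort_shift else 0
    lapply(seq_len(n_subj), function(i) {
      L <- base_mu + shift + config$sex_effect_size * M * (labels[i] == 1)
      noise <- matrix(0, n, n)
      noise[ut] <- rnorm(n_edges, sd = config$noise_sd)
      noise <- noise + t(noise)
      A <- exp(L + noise)
      A[A < 0] <- 0
      diag(A) <- 0
      A <- (A + t(A)) / 2
      connectome_graph(A, labels[i], cohort,
                       sprintf("%s_%04d", cohort, i))
    })
  }

  graphs <- c(build_cohort(config$n_adult, config$female_fraction_adult, "adult"),
              build_cohort(config$n_pediatric, config$female_fraction_pediatric,
                           "pediatric"))
  ds <- structure(graphs, class = "connectome_dataset", config = config)
  if (features != "none") ds <- make_node_features(ds, scheme = features)
  ds
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cohorts <- vapply(x, `[[`, character(1), "cohort")
  labels <- vapply(x, `[[`, integer(1), "label")
  cat(sprintf("<connectome_dataset> %d subjects (%d adult, %d pediatric), %d regions, %.1f%% female\n",
              length(x), sum(cohorts == "adult"), sum(cohorts == "pediatric"),
              if (length(x)) nrow(x[[1]]$adjacency) else 0,
              if (length(x)) 100 * mean(labels) else NA_real_))
  invisible(x)
}

#' Summarise a connectome dataset as a tibble
#'
#' One row per subject with cohort, label and basic edge-weight summaries.
#' @param x A `connectome_dataset`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.connectome_dataset <- function(x, ...) {
  purrr::map_dfr(x, function(g) {
    w <- g$adjacency[upper.tri(g$adjacency)]
    tibble::tibble(subject_id = g$subject_id, cohort = g$cohort,
                   label = g$label,
                   mean_weight = mean(w), max_weight = max(w))
  })
}

#' Attach node features to connectome graphs
#'
#' The atlas defines nodes but no intrinsic node attributes, so features are
#' derived from the graph itself:
#' `connectivity_profile` sets \eqn{X = A} (each node described by its row of
#' edge weights, `d = n_regions`, the default), `degree` uses the weighted
#' degree (row sums, `d = 1`), and `one_hot` uses the identity matrix.
#'
#' @param x A `connectome_graph` or `connectome_dataset`.
#' @param scheme Feature scheme.
#' @return Object of the same class with `node_features` set.
#' @export
make_node_features <- function(x, scheme = c("connectivity_profile", "degree",
                                             "one_hot")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "connectome_dataset")) {
    out <- structure(lapply(x, make_node_features, scheme = scheme),
                     class = "connectome_dataset", config = attr(x, "config"))
    return(out)
  }
  if (!inherits(x, "connectome_graph")) {
    stop("x must be a connectome_graph or connectome_dataset", call. = FALSE)
  }
  A <- x$adjacency
  x$node_features <- switch(scheme,
    connectivity_profile = A,
    degree = matrix(rowSums(A), ncol = 1),
    one_hot = diag(nrow(A)))
  x
}
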