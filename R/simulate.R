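#' Sample a random unrooted binary tree
#'
#' Topology by sequential random joins of lineages (coalescent-like);
#' branch lengths i.i.d. exponential with mean `branch_scale`.
#'
#' @param n_taxa number of tips (`>= 2`).
#' @param branch_scale mean branch length, in expected replacements per
#'   site.
#' @param seed optional integer for a reproducible draw.
#' @return An [ape::phylo] tree with tips `t1..tn`.
#' @export
sample_random_tree <- function(n_taxa, branch_scale = 0.1, seed = NULL) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("t", seq_len(n_taxa))
  while (length(nodes) > 3L) {
    i <- sample.int(length(nodes), 2L)
    nodes <- c(nodes[-i], sprintf("(%s,%s)", nodes[i[1L]], nodes[i[2L]]))
  }
  nwk <- paste0("(", paste(nodes, collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_scale)
  tr
}

#' Simulation configuration
#'
#' Describes one synthetic data set: a generating mixture model, a tree
#' (supplied or drawn), and masking.  The generating model's gamma
#' component, if any, supplies the discrete site-rate categories.
#'
#' @param n_taxa,n_sites alignment dimensions.
#' @param true_model the generating [mixture_model].
#' @param tree optional [ape::phylo]; when `NULL` a random tree with
#'   `n_taxa` tips is drawn.
#' @param branch_scale mean branch length for a drawn tree.
#' @param missing_fraction i.i.d. probability that a cell is masked
#'   (shown as `-`); must lie in `[0, 0.5]`.
#' @param seed integer seed making the simulation reproducible.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa, n_sites, true_model, tree = NULL,
                              branch_scale = 0.1, missing_fraction = 0,
                              seed = 1L) {
  stopifnot(n_taxa >= 2L, n_sites >= 1L,
            missing_fraction >= 0, missing_fraction <= 0.5,
            inherits(true_model, "mixture_model"))
  if (!is.null(tree) && length(tree$tip.label) != n_taxa) {
    stop("tree size disagrees with n_taxa")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
                 true_model = true_model, tree = tree,
                 branch_scale = branch_scale,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an alignment along a tree under a mixture model
#'
#' Per site: a mixture component is drawn from the generating weights (or
#' by a Chinese-restaurant draw for a DP truth), a rate category from the
#' discrete-gamma categories (rate 1 without gamma), the root state from
#' the component profile, and states evolve down the tree with
#' [transition_matrix] applied to `rate * branch_length`.  Cells are then
#' masked i.i.d. with `missing_fraction`.
#'
#' @param cfg a [simulation_config].
#' @return List with `alignment` (an [aa_alignment]), `tree`, and `truth`
#'   (data frame: `site`, `component`, `rate`, 1-based site indices).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  if (is.null(tree)) tree <- sample_random_tree(cfg$n_taxa, cfg$branch_scale)
  model <- cfg$true_model
  N <- cfg$n_sites
  C <- nrow(model$components)
  if (model$spec$profile_mode == "dp") {
    comp <- integer(N)
    counts <- numeric(0)
    for (i in seq_len(N)) {
      p <- c(counts, model$dp_alpha)
      z <- sample.int(length(p), 1L, prob = p)
      if (z > length(counts)) counts <- c(counts, 0)
      counts[z] <- counts[z] + 1
      comp[i] <- z
    }
    if (max(comp) > C) stop("DP truth needs at least ", max(comp), " profiles")
  } else {
    comp <- sample.int(C, N, replace = TRUE, prob = model$weights)
  }
  rates <- if (is.null(model$gamma)) {
    cat_idx <- rep(1L, N)
    rep(1, N)
  } else {
    cat_idx <- sample.int(model$gamma$n_cat, N, replace = TRUE)
    model$gamma$rates[cat_idx]
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1L]
  nnode <- max(tr$edge)
  states <- matrix(0L, nnode, N)
  for (cc in seq_len(C)) {
    sel <- comp == cc
    if (any(sel)) {
      states[root, sel] <- sample.int(20L, sum(sel), replace = TRUE,
                                      prob = model$components[cc, ])
    }
  }
  Qs <- lapply(seq_len(C), function(cc)
    build_rate_matrix(model$components[cc, ], model$exch))
  # preorder: reverse postorder visits parents before children
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    t_e <- tr$edge.length[e]
    for (cc in seq_len(C)) {
      for (g in unique(cat_idx[comp == cc])) {
        sel <- comp == cc & cat_idx == g
        r <- if (is.null(model$gamma)) 1 else model$gamma$rates[g]
        P <- transition_matrix(Qs[[cc]], r * t_e)
        ps <- states[parent, sel]
        cs <- integer(length(ps))
        for (s in unique(ps)) {
          take <- ps == s
          cs[take] <- sample.int(20L, sum(take), replace = TRUE, prob = P[s, ])
        }
        states[child, sel] <- cs
      }
    }
  }
  m <- matrix(AA_ORDER[states[seq_len(ntip), , drop = FALSE]], ntip, N)
  if (cfg$missing_fraction > 0) {
    mask <- matrix(stats::runif(ntip * N) < cfg$missing_fraction, ntip, N)
    m[mask] <- "-"
  }
  rownames(m) <- tr$tip.label
  list(alignment = aa_alignment(m), tree = tree,
       truth = data.frame(site = seq_len(N), component = comp, rate = rates))
}

#' Benchmark fixtures
#'
#' Deterministic synthetic data sets used throughout the test suite:
#' \describe{
#'   \item{f81}{single profile, Poisson exchangeabilities, no gamma;
#'     8 taxa x 2000 sites.}
#'   \item{gtr_gamma}{single profile, GTR exchangeabilities, gamma shape
#'     0.5 with 4 categories; 8 taxa x 5000 sites.}
#'   \item{mix3}{three well-separated profiles (70% of the mass on
#'     disjoint amino acid triples, remainder uniform), equal weights,
#'     Poisson exchangeabilities, no gamma; 10 taxa x 3000 sites.}
#'   \item{smoke}{single profile with gamma and 10% missing cells;
#'     4 taxa x 50 sites.}
#' }
#' All generating parameters are drawn deterministically from `seed`;
#' trees use mean branch length 0.15.
#'
#' @param seed integer master seed.
#' @param which optional character vector selecting fixtures by name.
#' @return Named list of simulations (each as [simulate_alignment]
#'   returns, plus the generating `model` and `config`).
#' @export
make_benchmark_suite <- function(seed = 1L, which = NULL) {
  defs <- list(
    f81 = function(s) {
      set.seed(s)
      model <- list(spec = model_spec("poisson", "single", gamma = FALSE),
                    exch = exchangeabilities("poisson"),
                    components = rdirichlet(1, rep(5, 20)),
                    weights = 1, gamma = NULL,
                    site_allocation = NULL, dp_alpha = NULL)
      class(model) <- "mixture_model"
      simulation_config(8L, 2000L, model, branch_scale = 0.15, seed = s + 1L)
    },
    gtr_gamma = function(s) {
      set.seed(s)
      model <- list(spec = model_spec("gtr", "single", gamma = TRUE),
                    exch = exchangeabilities("gtr", rgamma(190, 1)),
                    components = rdirichlet(1, rep(5, 20)),
                    weights = 1,
                    gamma = discretize_gamma(0.5, 4L),
                    site_allocation = NULL, dp_alpha = NULL)
      class(model) <- "mixture_model"
      simulation_config(8L, 5000L, model, branch_scale = 0.15, seed = s + 2L)
    },
    mix3 = function(s) {
      comps <- matrix(0.3 / 17, 3L, 20L)
      for (k in 1:3) comps[k, (3 * k - 2):(3 * k)] <- 0.7 / 3
      model <- list(spec = model_spec("poisson", "free", n_components = 3L,
                                      gamma = FALSE),
                    exch = exchangeabilities("poisson"),
                    components = comps, weights = rep(1 / 3, 3L),
                    gamma = NULL, site_allocation = NULL, dp_alpha = NULL)
      class(model) <- "mixture_model"
      simulation_config(10L, 3000L, model, branch_scale = 0.15, seed = s + 3L)
    },
    smoke = function(s) {
      set.seed(s + 10L)
      model <- list(spec = model_spec("poisson", "single", gamma = TRUE),
                    exch = exchangeabilities("poisson"),
                    components = rdirichlet(1, rep(2, 20)),
                    weights = 1, gamma = discretize_gamma(1, 4L),
                    site_allocation = NULL, dp_alpha = NULL)
      class(model) <- "mixture_model"
      simulation_config(4L, 50L, model, branch_scale = 0.15,
                        missing_fraction = 0.1, seed = s + 4L)
    })
  if (is.null(which)) which <- names(defs)
  out <- lapply(which, function(nm) {
    cfg <- defs[[nm]](seed)
    sim <- simulate_alignment(cfg)
    sim$model <- cfg$true_model
    sim$config <- cfg
    sim
  })
  names(out) <- which
  out
}
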