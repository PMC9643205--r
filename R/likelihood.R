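# Prepare a (tree, alignment) pair for pruning: postorder edge list with
# tip rows of the state matrix arranged in tip-id order.
prep_tree <- function(tree, aln) {
  check_tree_taxa(tree, aln$taxa)
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- aln$states[match(tr$tip.label, aln$taxa), , drop = FALSE]
  states[is.na(states)] <- 0L
  storage.mode(states) <- "integer"
  list(edge = tr$edge, t = tr$edge.length, ntip = length(tr$tip.label),
       states = states, tree = tr)
}

# Eigendecompositions and mixing weights for every (component, rate
# category) slot of a mixture model.  Slots are component-major: slot
# (c-1)*G + g.  Branch-length rate multipliers are folded into lambda.
model_slots <- function(model) {
  C <- nrow(model$components)
  rates <- if (is.null(model$gamma)) 1 else model$gamma$rates
  G <- length(rates)
  U <- lam <- V <- vector("list", C * G)
  piMat <- matrix(0, 20L, C * G)
  for (cc in seq_len(C)) {
    Q <- build_rate_matrix(model$components[cc, ], model$exch)
    d <- decompose_generator(Q)
    for (g in seq_len(G)) {
      k <- (cc - 1L) * G + g
      U[[k]] <- d$U
      lam[[k]] <- d$lambda * rates[g]
      V[[k]] <- d$V
      piMat[, k] <- attr(Q, "pi")
    }
  }
  logw <- rep(log(model$weights), each = G) - log(G)
  list(U = U, lam = lam, V = V, piMat = piMat, logw = logw, C = C, G = G)
}

# K x N matrix of per-site log conditional likelihoods, one row per
# (component, category) slot
site_loglik_slots <- function(ptree, model, bl = ptree$t, sites = NULL) {
  st <- ptree$states
  if (!is.null(sites)) st <- st[, sites, drop = FALSE]
  sl <- model_slots(model)
  out <- matrix(0, length(sl$U), ncol(st))
  for (k in seq_along(sl$U)) {
    out[k, ] <- cpp_prune_one(st, ptree$edge, ptree$ntip, sl$U[[k]],
                              sl$lam[[k]], sl$V[[k]], bl, sl$piMat[, k])
  }
  out
}

# per-site marginal (or allocated) log-likelihoods from the slot matrix
mix_slot_loglik <- function(slots_ll, model, alloc = NULL) {
  G <- if (is.null(model$gamma)) 1L else model$gamma$n_cat
  if (is.null(alloc)) {
    logw <- rep(log(model$weights), each = G) - log(G)
    mix_rows(slots_ll + logw)
  } else {
    N <- ncol(slots_ll)
    Y <- matrix(0, G, N)
    base <- (alloc - 1L) * G
    for (g in seq_len(G)) {
      Y[g, ] <- slots_ll[cbind(base + g, seq_len(N))]
    }
    mix_rows(Y - log(G))
  }
}

# column-wise log-sum-exp of a matrix, vectorized across columns
mix_rows <- function(Y) {
  if (is.null(dim(Y))) return(Y)
  K <- nrow(Y)
  if (K == 1L) return(Y[1L, ])
  m <- Y[1L, ]
  for (k in 2:K) m <- pmax(m, Y[k, ])
  s <- exp(Y[1L, ] - m)
  for (k in 2:K) s <- s + exp(Y[k, ] - m)
  m + log(s)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Conditional site likelihood for one profile and rate
#'
#' Felsenstein pruning for a single alignment column under one rate
#' matrix, with every branch length multiplied by `rate`.  Missing
#' symbols contribute a partial vector of ones; the root is summed
#' against the stationary profile.
#'
#' @param aln an [aa_alignment].
#' @param site column index (1-based).
#' @param tree an [ape::phylo] tree whose tips match the alignment taxa.
#' @param profile an [aa_profile] (or 20 frequencies).
#' @param exch an [exchangeabilities] object.
#' @param rate positive branch-length multiplier.
#' @return Probability of the column on the natural scale.
#' @export
site_conditional_likelihood <- function(aln, site, tree, profile, exch,
                                        rate = 1) {
  if (rate <= 0) stop("rate must be positive")
  pt <- prep_tree(tree, aln)
  Q <- build_rate_matrix(profile, exch)
  d <- decompose_generator(Q)
  ll <- cpp_prune_one(pt$states[, site, drop = FALSE], pt$edge, pt$ntip,
                      d$U, d$lambda * rate, d$V, pt$t, attr(Q, "pi"))
  exp(ll[1L])
}

#' Site likelihood under a mixture model
#'
#' Marginal mode averages the conditional likelihood over mixture
#' components (by weight) and gamma categories (equal weight); allocated
#' mode conditions on the site's assigned component, still averaging over
#' gamma categories.
#'
#' @param aln an [aa_alignment].
#' @param site column index.
#' @param tree an [ape::phylo].
#' @param model a [mixture_model] (see [instantiate_model]).
#' @param mode `"marginal"` or `"allocated"`.
#' @return List with `site_index`, `value` (natural scale), `log`, and
#'   `per_component` (components x categories matrix of conditional
#'   likelihoods).
#' @export
site_likelihood <- function(aln, site, tree, model,
                            mode = c("marginal", "allocated")) {
  mode <- match.arg(mode)
  if (nrow(model$components) == 0L) stop("empty mixture")
  pt <- prep_tree(tree, aln)
  sl <- site_loglik_slots(pt, model, sites = site)
  G <- if (is.null(model$gamma)) 1L else model$gamma$n_cat
  alloc <- NULL
  if (mode == "allocated") {
    if (is.null(model$site_allocation)) stop("model carries no site allocation")
    alloc <- model$site_allocation[site]
  }
  lv <- mix_slot_loglik(sl, model, alloc)
  list(site_index = site, value = exp(lv), log = lv,
       per_component = matrix(exp(sl[, 1L]), nrow(model$components), G,
                              byrow = TRUE))
}

#' Alignment log-likelihood under a mixture model
#'
#' Sum over sites of the log marginal site likelihoods.  Identical
#' columns are collapsed to unique patterns with multiplicities before
#' pruning (`collapse = FALSE` disables this; the result is unchanged).
#'
#' @param aln an [aa_alignment].
#' @param tree an [ape::phylo] whose tips match the alignment taxa (its
#'   edge lengths are used unless `bl` is given).
#' @param model a [mixture_model].
#' @param bl optional branch-length vector overriding the tree's, in the
#'   tree's postorder edge order.
#' @param collapse collapse identical site patterns?
#' @return Scalar natural-log likelihood.
#' @export
log_likelihood <- function(aln, tree, model, bl = NULL, collapse = TRUE) {
  pt <- prep_tree(tree, aln)
  if (is.null(bl)) bl <- pt$t
  if (collapse) {
    key <- apply(pt$states, 2L, paste, collapse = ",")
    uq <- !duplicated(key)
    mult <- as.vector(table(factor(key, levels = key[uq])))
    sl <- site_loglik_slots(pt, model, bl = bl, sites = which(uq))
    sum(mult * mix_slot_loglik(sl, model))
  } else {
    sum(mix_slot_loglik(site_loglik_slots(pt, model, bl = bl), model))
  }
}

#' Brute-force site likelihood (test oracle)
#'
#' Explicit sum over all internal-node state assignments of the product
#' of the root profile and branch transition probabilities.  Limited to
#' five taxa (at most 20^3 internal assignments, plus the root).
#'
#' @inheritParams site_conditional_likelihood
#' @return Probability of the column on the natural scale.
#' @export
brute_force_site_likelihood <- function(aln, site, tree, profile, exch,
                                        rate = 1) {
  if (aln$n_taxa > 5L) stop("brute force limited to 5 taxa")
  pt <- prep_tree(tree, aln)
  Q <- build_rate_matrix(profile, exch)
  pi <- attr(Q, "pi")
  P <- lapply(pt$t, function(t) transition_matrix(Q, rate * t))
  obs <- pt$states[, site]
  internal <- sort(unique(pt$edge[, 1L]))
  idx <- stats::setNames(seq_along(internal), internal)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  root <- pt$edge[nrow(pt$edge), 1L]
  lik <- pi[grid[, idx[as.character(root)]]]
  for (e in seq_len(nrow(pt$edge))) {
    pstate <- grid[, idx[as.character(pt$edge[e, 1L])]]
    child <- pt$edge[e, 2L]
    if (child <= pt$ntip) {
      if (obs[child] == 0L) next  # missing: sums to one
      lik <- lik * P[[e]][cbind(pstate, obs[child])]
    } else {
      lik <- lik * P[[e]][cbind(pstate, grid[, idx[as.character(child)]])]
    }
  }
  sum(lik)
}
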