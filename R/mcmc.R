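#' Prior configuration
#'
#' Branch lengths are exponential with mean `branch_length_mean` per
#' branch; profiles, exchangeabilities and mixture weights have uniform
#' Dirichlet priors on their simplices; the gamma shape and the DP
#' concentration have exponential priors.
#'
#' @param branch_length_mean mean of the per-branch exponential prior.
#' @param alpha_mean mean of the exponential prior on the gamma shape.
#' @param dp_alpha_mean mean of the exponential prior on the DP
#'   concentration.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(branch_length_mean = 0.1, alpha_mean = 1,
                         dp_alpha_mean = 1) {
  stopifnot(branch_length_mean > 0, alpha_mean > 0, dp_alpha_mean > 0)
  structure(list(branch_length_mean = branch_length_mean,
                 alpha_mean = alpha_mean, dp_alpha_mean = dp_alpha_mean),
            class = "prior_config")
}

#' Chain configuration
#'
#' @param n_cycles total MCMC cycles; one cycle sweeps every parameter
#'   block once (branch lengths, exchangeabilities, profiles, weights or
#'   DP allocation, gamma shape).
#' @param burn_in cycles discarded before draws are collected (must be
#'   `< n_cycles`); proposal widths are adapted only during burn-in.
#' @param thin record a posterior draw every `thin` post-burn-in cycles.
#' @param seed integer RNG seed; chains are bitwise reproducible.
#' @param checkpoint_every write a checkpoint every this many cycles when
#'   `checkpoint_path` is set; an existing checkpoint is resumed from.
#' @param checkpoint_path optional checkpoint file path.
#' @param trace_path optional path; the trace is written there via
#'   [write_trace] when the chain finishes.
#' @param dp_new_m Monte Carlo draws for the DP new-component
#'   prior-predictive term.
#' @param verbose print progress every 100 cycles.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_cycles = 2200L, burn_in = 200L, thin = 1L,
                         seed = 1L, checkpoint_every = 100L,
                         checkpoint_path = NULL, trace_path = NULL,
                         dp_new_m = 10L, verbose = FALSE) {
  stopifnot(n_cycles >= 1L, burn_in >= 0L, burn_in < n_cycles, thin >= 1L)
  structure(list(n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path, trace_path = trace_path,
                 dp_new_m = as.integer(dp_new_m), verbose = verbose),
            class = "chain_config")
}

#' Multiplicative Metropolis-Hastings update of a positive scalar
#'
#' Proposes `x' = x exp(w (u - 1/2))` with `u ~ U(0,1)` and accepts with
#' the Hastings correction `x'/x` for the multiplicative proposal.  With
#' `width = 0` the proposal is the identity and is always accepted.
#'
#' @param x current (positive) value.
#' @param log_post function returning the log posterior kernel at a value.
#' @param width log-window width of the proposal.
#' @return List with `value` and `accepted`.
#' @export
mh_update_scalar <- function(x, log_post, width) {
  stopifnot(x > 0, width >= 0)
  x1 <- x * exp(width * (runif(1L) - 0.5))
  la <- log_post(x1) - log_post(x) + log(x1 / x)
  if (log(runif(1L)) < la) list(value = x1, accepted = TRUE)
  else list(value = x, accepted = FALSE)
}

#' Dirichlet Metropolis-Hastings update of a simplex parameter
#'
#' Proposes from a Dirichlet centered on the current value (parameters
#' `concentration * x + eps`) and accepts with the full Hastings ratio;
#' the proposal preserves the unit sum exactly.  Larger concentrations
#' make smaller steps.
#'
#' @param x current simplex (sums to one).
#' @param log_post function returning the log posterior kernel at a
#'   simplex.
#' @param concentration proposal concentration.
#' @param eps floor added to every proposal parameter.
#' @return List with `value` and `accepted`.
#' @export
dirichlet_mh_update <- function(x, log_post, concentration, eps = 0.1) {
  a_fwd <- concentration * x + eps
  y <- rdirichlet(1L, a_fwd)[1L, ]
  a_rev <- concentration * y + eps
  la <- log_post(y) - log_post(x) +
    ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
  if (log(runif(1L)) < la) list(value = y, accepted = TRUE)
  else list(value = x, accepted = FALSE)
}

ldirichlet <- function(x, a) {
  lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
}

#' One Gibbs sweep of the Chinese-restaurant allocation
#'
#' Each site in turn is removed from its component (components left empty
#' are deleted) and reseated: among occupied components with probability
#' proportional to `n_j * L_j(site)`, or at one of `m_new` auxiliary
#' components carrying fresh profile draws from the base distribution,
#' each with probability proportional to `(dp_alpha / m_new) * L_m(site)`
#' (the auxiliary-component realization of the CRP predictive).  A chosen
#' auxiliary becomes a real component with its drawn profile and is
#' replaced by a fresh base draw; a component emptied by a removal donates
#' its profile back to the auxiliary pool, so singleton states remain
#' reachable in both directions.  With `aln = NULL` the sweep is
#' data-free and realizes the CRP prior.
#'
#' @param model a [mixture_model] in DP mode carrying a `site_allocation`.
#' @param aln an [aa_alignment], or `NULL` for a data-free sweep.
#' @param tree an [ape::phylo] (required with data).
#' @param n_sites number of sites for a data-free sweep.
#' @param m_new number of auxiliary components.
#' @return The updated [mixture_model] (allocation, components,
#'   occupancy-derived weights).
#' @export
crp_gibbs_allocation <- function(model, aln = NULL, tree = NULL,
                                 n_sites = NULL, m_new = 10L) {
  stopifnot(inherits(model, "mixture_model"),
            model$spec$profile_mode == "dp",
            !is.null(model$site_allocation))
  if (is.null(aln)) {
    sw <- crp_core(alloc = model$site_allocation,
                   comps = model$components,
                   sitell = NULL, dp_alpha = model$dp_alpha,
                   aux = NULL, auxll = NULL, new_row_fn = NULL)
  } else {
    pt <- prep_tree(tree, aln)
    slots <- site_loglik_slots(pt, model)
    G <- if (is.null(model$gamma)) 1L else model$gamma$n_cat
    k <- nrow(model$components)
    sitell <- t(vapply(seq_len(k), function(cc) {
      mix_rows(slots[(cc - 1L) * G + seq_len(G), , drop = FALSE] - log(G))
    }, numeric(aln$n_sites)))
    if (k == 1L) sitell <- matrix(sitell, 1L)
    new_row_fn <- function(profile) comp_site_loglik(pt, model, profile)
    aux <- rdirichlet(m_new, rep(1, 20))
    auxll <- t(apply(aux, 1L, new_row_fn))
    sw <- crp_core(alloc = model$site_allocation, comps = model$components,
                   sitell = sitell, dp_alpha = model$dp_alpha,
                   aux = aux, auxll = auxll, new_row_fn = new_row_fn)
  }
  model$site_allocation <- sw$alloc
  model$components <- sw$comps
  counts <- tabulate(sw$alloc, nbins = nrow(sw$comps))
  model$weights <- counts / sum(counts)
  model
}

# Core CRP Gibbs loop over sites.  sitell is a (components x sites)
# matrix of per-site log-likelihoods and aux/auxll the auxiliary profile
# pool with its rows; all NULL for a data-free sweep, which realizes the
# CRP prior exactly (the auxiliary likelihoods are constant and cancel).
crp_core <- function(alloc, comps, sitell, dp_alpha, aux, auxll,
                     new_row_fn) {
  n <- length(alloc)
  counts <- tabulate(alloc, nbins = nrow(comps))
  data_free <- is.null(sitell)
  M <- if (data_free) 1L else nrow(aux)
  for (i in seq_len(n)) {
    z <- alloc[i]
    counts[z] <- counts[z] - 1L
    emptied_slot <- 0L
    if (counts[z] == 0L) {
      if (!data_free) {
        # the emptied component serves as one auxiliary for THIS site
        # only (it must be redrawn from the base before the next site,
        # or specialized profiles would linger and be recreated too
        # easily)
        emptied_slot <- sample.int(M, 1L)
        aux[emptied_slot, ] <- comps[z, ]
        auxll[emptied_slot, ] <- sitell[z, ]
        sitell <- sitell[-z, , drop = FALSE]
      }
      comps <- comps[-z, , drop = FALSE]
      counts <- counts[-z]
      alloc[alloc > z] <- alloc[alloc > z] - 1L
    }
    lp <- if (data_free) {
      c(log(counts), log(dp_alpha))
    } else {
      c(log(counts) + sitell[, i], log(dp_alpha / M) + auxll[, i])
    }
    lp <- lp - max(lp)
    z <- sample.int(length(lp), 1L, prob = exp(lp))
    if (z > length(counts)) {
      if (data_free) {
        comps <- rbind(comps, rdirichlet(1, rep(1, 20))[1L, ])
      } else {
        m <- z - length(counts)
        comps <- rbind(comps, aux[m, ])
        sitell <- rbind(sitell, auxll[m, ])
        aux[m, ] <- rdirichlet(1, rep(1, 20))[1L, ]
        auxll[m, ] <- new_row_fn(aux[m, ])
        if (emptied_slot == m) emptied_slot <- 0L
      }
      counts <- c(counts, 0L)
      z <- length(counts)
    }
    if (emptied_slot > 0L) {
      aux[emptied_slot, ] <- rdirichlet(1, rep(1, 20))[1L, ]
      auxll[emptied_slot, ] <- new_row_fn(aux[emptied_slot, ])
    }
    counts[z] <- counts[z] + 1L
    alloc[i] <- z
  }
  rownames(comps) <- NULL
  list(alloc = alloc, comps = comps, sitell = sitell, counts = counts)
}

# Greedy merge pass over DP components, used during burn-in only: the
# plain Gibbs sweep creates components easily but practically never
# empties a large one, so cold-started chains can lodge in fragmented
# high-k states even when (as the CRP prior's lgamma terms make typical)
# the merged state carries far more posterior mass.  Repeatedly merges
# the pair whose merge most improves the allocated log-likelihood plus
# the CRP partition term, with the merged profile set to the Dirichlet
# posterior mean of the pooled column counts.  Burn-in-only, like
# proposal-width adaptation, so detailed balance of the sampling phase
# is untouched.
dp_merge_pass <- function(model, pt, colcounts) {
  repeat {
    k <- nrow(model$components)
    if (k < 2L) break
    alloc <- model$site_allocation
    counts <- tabulate(alloc, nbins = k)
    sites_of <- lapply(seq_len(k), function(cc) which(alloc == cc))
    # score both sides at the Dirichlet posterior-mean profile of their
    # pooled column counts, so the comparison is optimized-vs-optimized
    # and does not reward merging merely because a table's current
    # profile has not converged yet
    opt_profile <- function(sites) {
      phi <- 1 + rowSums(colcounts[, sites, drop = FALSE])
      phi / sum(phi)
    }
    ll_of <- vapply(seq_len(k), function(cc) {
      sum(comp_site_loglik(pt, model, opt_profile(sites_of[[cc]]),
                           sites = sites_of[[cc]]))
    }, 0)
    best <- NULL
    best_delta <- 0
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        u <- c(sites_of[[a]], sites_of[[b]])
        phi <- opt_profile(u)
        ll_m <- sum(comp_site_loglik(pt, model, phi, sites = u))
        delta <- ll_m - ll_of[a] - ll_of[b] +
          lgamma(counts[a] + counts[b]) - lgamma(counts[a]) -
          lgamma(counts[b]) - log(model$dp_alpha)
        if (delta > best_delta) {
          best <- list(a = a, b = b, phi = phi)
          best_delta <- delta
        }
      }
    }
    if (is.null(best)) break
    alloc[alloc == best$b] <- best$a
    alloc[alloc > best$b] <- alloc[alloc > best$b] - 1L
    model$components[best$a, ] <- best$phi
    model$components <- model$components[-best$b, , drop = FALSE]
    model$site_allocation <- alloc
  }
  model$weights <- tabulate(model$site_allocation,
                            nbins = nrow(model$components))
  model$weights <- model$weights / sum(model$weights)
  model
}

# per-site log-likelihood row for one profile under the model's
# exchangeabilities and gamma categories (gamma-averaged)
comp_site_loglik <- function(pt, model, profile, sites = NULL) {
  Q <- build_rate_matrix(profile, model$exch)
  d <- decompose_generator(Q)
  rates <- if (is.null(model$gamma)) 1 else model$gamma$rates
  st <- pt$states
  if (!is.null(sites)) st <- st[, sites, drop = FALSE]
  Y <- vapply(rates, function(r) {
    as.numeric(cpp_prune_one(st, pt$edge, pt$ntip, d$U, d$lambda * r, d$V,
                             pt$t, attr(Q, "pi")))
  }, numeric(ncol(st)))
  mix_rows(t(Y) - log(length(rates)))
}

# Monte Carlo prior-predictive per-site log-likelihood for a fresh DP
# component: average over m profile draws from the Dirichlet(1) base
dp_new_loglik <- function(pt, model, m) {
  Y <- vapply(seq_len(m), function(j) {
    comp_site_loglik(pt, model, rdirichlet(1, rep(1, 20))[1L, ])
  }, numeric(ncol(pt$states)))
  mix_rows(t(Y) - log(m))
}

# 20 x N matrix of observed amino acid counts per column
column_counts <- function(aln) {
  apply(aln$states, 2L, function(s) tabulate(s[!is.na(s)], nbins = 20L))
}

#' Run an MCMC chain for one model on one data set
#'
#' Samples branch lengths, exchangeabilities (GTR modes), component
#' profiles, mixture weights (finite mixtures) or the Chinese-restaurant
#' allocation and DP concentration (CAT modes), and the gamma shape
#' (`+G` modes) from their posterior under the alignment, on the fixed
#' topology of `tree`.  Empirical mixtures update weights only; profiles
#' stay at their supplied values.  Each cycle sweeps every block once;
#' the branch-length block is a depth-first pass updating every branch
#' via cached directional partial likelihoods.  Proposal widths adapt
#' during burn-in only (targeting acceptance between 0.2 and 0.5) and
#' are frozen afterwards.
#'
#' @param aln an [aa_alignment] (the learning data).
#' @param tree an [ape::phylo] with branch lengths; its topology is fixed
#'   throughout, its lengths are the chain's starting values.
#' @param spec a [model_spec].
#' @param priors a [prior_config].
#' @param cfg a [chain_config].
#' @return Object of class `mixcv_fit`: list with the posterior `draws`
#'   (each a named list of parameter values), the per-cycle `trace` data
#'   frame, `K` (number of draws), the final `model` state, acceptance
#'   rates, and the inputs needed for prediction.
#' @seealso [cv_score] for scoring test columns against the fit,
#'   [predict.mixcv_fit], [sample_from_prior].
#' @export
run_chain <- function(aln, tree, spec, priors = prior_config(),
                      cfg = chain_config()) {
  run_chain_impl(aln, tree, spec, priors, cfg, null_lik = FALSE)
}

#' Sample the prior with the chain machinery
#'
#' Runs the identical cycle machinery with the likelihood term forced to
#' one, so every block targets its prior.  Used for Geweke-style
#' validation: marginal moments of the draws must match the analytic
#' prior moments.
#'
#' @param spec a [model_spec].
#' @param priors a [prior_config].
#' @param cfg a [chain_config].
#' @param n_taxa,n_sites size of the dummy data set (sets the number of
#'   branches and of DP-allocated sites).
#' @return A `mixcv_fit` (see [run_chain]).
#' @export
sample_from_prior <- function(spec, priors = prior_config(),
                              cfg = chain_config(), n_taxa = 4L,
                              n_sites = 10L) {
  m <- matrix("-", n_taxa, n_sites,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  aln <- aa_alignment(m)
  tree <- sample_random_tree(n_taxa, priors$branch_length_mean,
                             seed = cfg$seed)
  run_chain_impl(aln, tree, spec, priors, cfg, null_lik = TRUE)
}

run_chain_impl <- function(aln, tree, spec, priors, cfg, null_lik = FALSE) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(spec, "model_spec"),
            inherits(priors, "prior_config"), inherits(cfg, "chain_config"))
  set.seed(cfg$seed)
  pt <- prep_tree(tree, aln)
  N <- aln$n_sites
  E <- nrow(pt$edge)
  bl0 <- priors$branch_length_mean
  model <- instantiate_model(spec, N, priors = priors)
  bl <- if (is.null(pt$t)) rexp(E, 1 / bl0) else pt$t
  dp <- spec$profile_mode == "dp"
  free_profiles <- spec$profile_mode != "empirical"
  update_weights <- spec$profile_mode %in% c("empirical", "free") &&
    length(model$weights) > 1L
  gammaG <- function() if (is.null(model$gamma)) 1L else model$gamma$n_cat

  # Data-informed starting point (the stationary distribution is
  # unaffected by initialization; this shortens burn-in dramatically):
  # free profiles start near the observed amino acid frequencies, DP
  # tables are seeded from the column counts of randomly chosen sites,
  # and free exchangeabilities start even.
  if (!null_lik) {
    obs <- tabulate(pt$states[pt$states > 0L], nbins = 20L)
    emp <- (obs + 1) / sum(obs + 20)
    if (spec$profile_mode == "single") {
      model$components[1L, ] <- emp
    } else if (spec$profile_mode == "free") {
      model$components <- rdirichlet(nrow(model$components), 100 * emp)
    } else if (dp) {
      # seat sites by k-means on their column compositions, so tables
      # are compositionally sorted from the start; the burn-in merge
      # passes then consolidate redundant tables.  (The plain Gibbs
      # sweep sorts a mixed table only via slow singleton nucleation,
      # and practically never empties a large one, so unsorted starts
      # lodge in fragmented metastable states.)
      cc0 <- column_counts(aln)
      X <- t(cc0) / pmax(colSums(cc0), 1)
      centers <- min(12L, nrow(unique(X)))
      km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                           nstart = 3L, iter.max = 25L))
      model$site_allocation <- km$cluster
      model$components <- t(vapply(seq_len(centers), function(j) {
        phi <- 1 + rowSums(cc0[, km$cluster == j, drop = FALSE])
        phi / sum(phi)
      }, numeric(20L)))
      colnames(model$components) <- AA_ORDER
      w <- tabulate(km$cluster, nbins = centers)
      model$weights <- w / sum(w)
    }
    if (spec$exchangeability_mode == "gtr") {
      model$exch <- exchangeabilities("gtr", rep(1, 190L))
    }
  }

  slots <- NULL
  loglik <- 0
  colcounts <- if (dp && !null_lik) column_counts(aln)
  recompute <- function(mod = model, b = bl) {
    if (null_lik) return(NULL)
    site_loglik_slots(pt, mod, bl = b)
  }
  mixll <- function(sl, mod = model) {
    if (null_lik) return(0)
    sum(mix_slot_loglik(sl, mod, alloc = if (dp) mod$site_allocation))
  }
  if (!null_lik) {
    slots <- recompute()
    loglik <- mixll(slots)
  }

  # proposal concentrations scale with data size (posterior width shrinks
  # like 1/sqrt(N)); adaptation refines them during burn-in
  tune <- list(bl = 1, exch = max(5000, 20 * N),
               profile = max(500, round(N / 2)), weights = 300,
               alpha = 1, dp_alpha = 1)
  acc <- tot <- sapply(tune, function(x) 0)
  trace <- vector("list", cfg$n_cycles)
  draws <- list()
  start_cycle <- 1L

  ckpt <- cfg$checkpoint_path
  if (!is.null(ckpt) && file.exists(ckpt)) {
    st <- readRDS(ckpt)
    if (st$cycle >= cfg$n_cycles) {
      stop("checkpoint at cycle ", st$cycle, " is not before n_cycles = ",
           cfg$n_cycles, "; delete it or raise n_cycles")
    }
    model <- st$model; bl <- st$bl; tune <- st$tune
    trace[seq_along(st$trace)] <- st$trace
    draws <- st$draws
    start_cycle <- st$cycle + 1L
    .GlobalEnv$.Random.seed <- st$rng
    if (!null_lik) {
      slots <- recompute()
      loglik <- mixll(slots)
    }
  }

  slot_eigs <- function(mod) {
    sl <- model_slots(mod)
    sl
  }

  for (cycle in seq(start_cycle, length.out = max(0L, cfg$n_cycles - start_cycle + 1L))) {
    ## branch lengths
    if (null_lik) {
      for (e in seq_len(E)) {
        up <- mh_update_scalar(bl[e], function(t) -t / bl0, tune$bl)
        bl[e] <- up$value
        acc["bl"] <- acc["bl"] + up$accepted
        tot["bl"] <- tot["bl"] + 1
      }
    } else {
      sl <- slot_eigs(model)
      alloc_vec <- if (dp) as.integer(model$site_allocation) else integer(0)
      sw <- cpp_bl_sweep(pt$states, pt$edge, pt$ntip, sl$U, sl$lam, sl$V,
                         sl$piMat, sl$logw, alloc_vec, gammaG(), bl, slots,
                         1 / bl0, tune$bl)
      bl <- as.numeric(sw$t)
      loglik <- sw$log_likelihood
      acc["bl"] <- acc["bl"] + sw$accepts
      tot["bl"] <- tot["bl"] + E
      slots <- sw$slots
    }

    ## exchangeabilities (two proposal scales per cycle: coarse and fine)
    if (spec$exchangeability_mode == "gtr") {
      for (mult in c(1, 10)) {
        x <- model$exch$rho / 190
        a_fwd <- mult * tune$exch * x + 0.1
        y <- rdirichlet(1L, a_fwd)[1L, ]
        a_rev <- mult * tune$exch * y + 0.1
        mod1 <- model
        mod1$exch <- exchangeabilities("gtr", y)
        sl1 <- recompute(mod1)
        ll1 <- mixll(sl1, mod1)
        la <- (ll1 - loglik) + ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
        if (mult == 1) tot["exch"] <- tot["exch"] + 1
        if (log(runif(1L)) < la) {
          model <- mod1; slots <- sl1; loglik <- ll1
          if (mult == 1) acc["exch"] <- acc["exch"] + 1
        }
      }
    }

    ## component profiles
    if (free_profiles) {
      G <- gammaG()
      for (cc in seq_len(nrow(model$components))) {
        x <- model$components[cc, ]
        # occasional independence draw from the (uniform Dirichlet) prior;
        # its Hastings ratio cancels against the prior, helping the
        # random-walk kernel escape simplex corners
        indep <- runif(1L) < 0.1
        if (indep) {
          a_fwd <- a_rev <- rep(1, 20L)
        } else {
          a_fwd <- tune$profile * x + 0.1
        }
        y <- rdirichlet(1L, a_fwd)[1L, ]
        if (!indep) a_rev <- tune$profile * y + 0.1
        hast <- ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
        tot["profile"] <- tot["profile"] + 1
        if (null_lik) {
          if (log(runif(1L)) < hast) {
            model$components[cc, ] <- y
            acc["profile"] <- acc["profile"] + 1
          }
          next
        }
        if (dp) {
          sites <- which(model$site_allocation == cc)
          ll_cur <- sum(comp_site_loglik(pt, model, x, sites = sites))
          ll_new <- sum(comp_site_loglik(pt, model, y, sites = sites))
          la <- (ll_new - ll_cur) + hast
          changed <- FALSE
          if (log(runif(1L)) < la) {
            model$components[cc, ] <- y
            x <- y
            ll_cur <- ll_new
            changed <- TRUE
            acc["profile"] <- acc["profile"] + 1
          }
          # independence proposal from the Dirichlet posterior of the
          # component's aggregated column counts (proper Hastings ratio;
          # lets small or new components specialize in one step)
          a_ind <- 1 + rowSums(colcounts[, sites, drop = FALSE])
          y <- rdirichlet(1L, a_ind)[1L, ]
          ll_new <- sum(comp_site_loglik(pt, model, y, sites = sites))
          la <- (ll_new - ll_cur) +
            ldirichlet(x, a_ind) - ldirichlet(y, a_ind)
          if (log(runif(1L)) < la) {
            model$components[cc, ] <- y
            changed <- TRUE
          }
          if (changed) {
            rows <- (cc - 1L) * G + seq_len(G)
            slots[rows, ] <- comp_slot_rows(pt, model,
                                            model$components[cc, ], bl)
            loglik <- mixll(slots)
          }
        } else {
          rows <- (cc - 1L) * G + seq_len(G)
          new_rows <- comp_slot_rows(pt, model, y, bl)
          sl1 <- slots
          sl1[rows, ] <- new_rows
          ll1 <- mixll(sl1)
          la <- (ll1 - loglik) + hast
          if (log(runif(1L)) < la) {
            model$components[cc, ] <- y
            slots <- sl1; loglik <- ll1
            acc["profile"] <- acc["profile"] + 1
          }
          # second, finer proposal at 10x the concentration
          x <- model$components[cc, ]
          a_fwd <- 10 * tune$profile * x + 0.1
          y <- rdirichlet(1L, a_fwd)[1L, ]
          a_rev <- 10 * tune$profile * y + 0.1
          new_rows <- comp_slot_rows(pt, model, y, bl)
          sl1 <- slots
          sl1[rows, ] <- new_rows
          ll1 <- mixll(sl1)
          la <- (ll1 - loglik) +
            ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
          if (log(runif(1L)) < la) {
            model$components[cc, ] <- y
            slots <- sl1; loglik <- ll1
          }
        }
      }
    }

    ## mixture weights (finite mixtures; DP weights are occupancy-derived)
    if (update_weights) {
      x <- model$weights
      a_fwd <- tune$weights * x + 0.1
      y <- rdirichlet(1L, a_fwd)[1L, ]
      a_rev <- tune$weights * y + 0.1
      mod1 <- model
      mod1$weights <- y
      ll1 <- if (null_lik) 0 else mixll(slots, mod1)
      la <- (ll1 - loglik) + ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
      tot["weights"] <- tot["weights"] + 1
      if (log(runif(1L)) < la) {
        model <- mod1; loglik <- ll1
        acc["weights"] <- acc["weights"] + 1
      }
    }

    ## DP allocation and concentration
    if (dp) {
      G <- gammaG()
      if (null_lik) {
        sw <- crp_core(model$site_allocation, model$components, NULL,
                       model$dp_alpha, NULL, NULL, NULL)
      } else {
        k <- nrow(model$components)
        sitell <- t(vapply(seq_len(k), function(cc) {
          mix_rows(slots[(cc - 1L) * G + seq_len(G), , drop = FALSE] - log(G))
        }, numeric(N)))
        if (k == 1L) sitell <- matrix(sitell, 1L, N)
        new_row_fn <- function(profile) comp_site_loglik(pt, model, profile)
        aux <- rdirichlet(cfg$dp_new_m, rep(1, 20))
        auxll <- t(apply(aux, 1L, new_row_fn))
        sw <- crp_core(model$site_allocation, model$components, sitell,
                       model$dp_alpha, aux, auxll, new_row_fn)
      }
      model$site_allocation <- sw$alloc
      model$components <- sw$comps
      model$weights <- sw$counts / sum(sw$counts)
      # merge passes only near the end of burn-in, once components have
      # had time to specialize (merging averaged, still-mixed tables is
      # destructive)
      if (!null_lik && cycle <= cfg$burn_in && cycle %% 25L == 0L &&
          cycle >= max(100L, cfg$burn_in - 50L)) {
        model <- dp_merge_pass(model, pt, colcounts)
      }
      if (!null_lik) {
        slots <- recompute()
        loglik <- mixll(slots)
      }
      # Escobar-West Gibbs update of the concentration: with a
      # Gamma(1, 1/mean) prior, alpha | k, n is a two-component gamma
      # mixture after augmenting with eta ~ Beta(alpha + 1, n)
      k <- nrow(model$components)
      b0 <- 1 / priors$dp_alpha_mean
      eta <- rbeta(1L, model$dp_alpha + 1, N)
      w <- k / (k + N * (b0 - log(eta)))
      sh <- if (runif(1L) < w) 1 + k else k
      model$dp_alpha <- rgamma(1L, shape = sh, rate = b0 - log(eta))
      acc["dp_alpha"] <- acc["dp_alpha"] + 1
      tot["dp_alpha"] <- tot["dp_alpha"] + 1
    }

    ## gamma shape
    if (!is.null(model$gamma)) {
      a0 <- model$gamma$alpha
      a1 <- a0 * exp(tune$alpha * (runif(1L) - 0.5))
      mod1 <- model
      mod1$gamma <- discretize_gamma(a1, model$gamma$n_cat)
      sl1 <- recompute(mod1)
      ll1 <- mixll(sl1, mod1)
      la <- (ll1 - loglik) + (a0 - a1) / priors$alpha_mean + log(a1 / a0)
      tot["alpha"] <- tot["alpha"] + 1
      if (log(runif(1L)) < la) {
        model <- mod1; slots <- sl1; loglik <- ll1
        acc["alpha"] <- acc["alpha"] + 1
      }
    }

    ## adaptation during burn-in only
    if (cycle <= cfg$burn_in && cycle %% 10L == 0L) {
      for (nm in names(tune)) {
        if (tot[nm] == 0) next
        r <- acc[nm] / tot[nm]
        if (nm %in% c("bl", "alpha", "dp_alpha")) {
          if (r > 0.5) tune[[nm]] <- tune[[nm]] * 1.6
          if (r < 0.2) tune[[nm]] <- tune[[nm]] / 1.6
        } else {
          if (r > 0.5) tune[[nm]] <- max(tune[[nm]] / 1.6, 1)
          if (r < 0.2) tune[[nm]] <- tune[[nm]] * 1.6
          if (r < 0.03) tune[[nm]] <- tune[[nm]] * 2.5
        }
        acc[nm] <- 0; tot[nm] <- 0
      }
    }

    trace[[cycle]] <- data.frame(
      cycle = cycle, log_likelihood = loglik,
      alpha = if (is.null(model$gamma)) NA_real_ else model$gamma$alpha,
      dp_alpha = if (dp) model$dp_alpha else NA_real_,
      n_components = nrow(model$components),
      tree_length = sum(bl))

    if (cycle > cfg$burn_in && (cycle - cfg$burn_in) %% cfg$thin == 0L) {
      draws[[length(draws) + 1L]] <- list(
        bl = bl,
        rho = if (spec$exchangeability_mode == "gtr") model$exch$rho,
        components = model$components,
        weights = model$weights,
        alpha = if (!is.null(model$gamma)) model$gamma$alpha,
        dp_alpha = if (dp) model$dp_alpha,
        counts = if (dp) tabulate(model$site_allocation,
                                  nbins = nrow(model$components)),
        alloc = if (dp) model$site_allocation)
    }

    if (!is.null(ckpt) && cycle %% cfg$checkpoint_every == 0L) {
      saveRDS(list(cycle = cycle, model = model, bl = bl, tune = tune,
                   trace = trace[seq_len(cycle)], draws = draws,
                   rng = .GlobalEnv$.Random.seed), ckpt)
    }
    if (isTRUE(cfg$verbose) && cycle %% 100L == 0L) {
      message(sprintf("cycle %d  logL %.2f  accepted: %s", cycle, loglik,
                      paste(sprintf("%s %.2f", names(acc),
                                    ifelse(tot > 0, acc / tot, NA)),
                            collapse = ", ")))
    }
  }

  if (length(draws) == 0L) stop("zero post-burn-in draws")
  trace <- do.call(rbind, trace)
  if (!is.null(cfg$trace_path)) write_trace(trace, cfg$trace_path)
  fit <- structure(list(
    spec = spec, model = model, draws = draws, K = length(draws),
    trace = trace, tree = pt$tree, taxa = aln$taxa, n_sites = N,
    priors = priors, cfg = cfg,
    acceptance = ifelse(tot > 0, acc / tot, NA_real_),
    null_likelihood = null_lik), class = "mixcv_fit")
  fit
}

# slot rows (G x N) for one profile at given branch lengths
comp_slot_rows <- function(pt, model, profile, bl) {
  Q <- build_rate_matrix(profile, model$exch)
  d <- decompose_generator(Q)
  rates <- if (is.null(model$gamma)) 1 else model$gamma$rates
  t(vapply(rates, function(r) {
    as.numeric(cpp_prune_one(pt$states, pt$edge, pt$ntip, d$U, d$lambda * r,
                             d$V, bl, attr(Q, "pi")))
  }, numeric(ncol(pt$states))))
}

#' @export
print.mixcv_fit <- function(x, ...) {
  cat("MCMC fit: ", model_name(x$spec),
      if (x$null_likelihood) " (prior-only)", "\n", sep = "")
  cat(sprintf("%d cycles (%d burn-in), %d posterior draws\n",
              x$cfg$n_cycles, x$cfg$burn_in, x$K))
  post <- x$trace[x$trace$cycle > x$cfg$burn_in, ]
  cat(sprintf("post-burn-in log-likelihood: mean %.3f, sd %.3f\n",
              mean(post$log_likelihood), sd(post$log_likelihood)))
  invisible(x)
}

#' @export
summary.mixcv_fit <- function(object, ...) {
  post <- object$trace[object$trace$cycle > object$cfg$burn_in, ]
  vars <- c("log_likelihood", "alpha", "dp_alpha", "n_components",
            "tree_length")
  tab <- t(vapply(vars, function(v) {
    c(mean = mean(post[[v]]), sd = sd(post[[v]]))
  }, numeric(2L)))
  tab <- tab[!is.na(tab[, "mean"]), , drop = FALSE]
  structure(list(model = model_name(object$spec), K = object$K,
                 acceptance = object$acceptance, table = tab),
            class = "summary.mixcv_fit")
}

#' @export
print.summary.mixcv_fit <- function(x, ...) {
  cat("Model:", x$model, " (", x$K, "draws )\n")
  print(round(x$table, 4))
  cat("acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' @export
coef.mixcv_fit <- function(object, ...) {
  draws <- object$draws
  out <- c(tree_length = mean(vapply(draws, function(d) sum(d$bl), 0)))
  if (!is.null(draws[[1L]]$alpha)) {
    out["alpha"] <- mean(vapply(draws, function(d) d$alpha, 0))
  }
  if (!is.null(draws[[1L]]$dp_alpha)) {
    out["dp_alpha"] <- mean(vapply(draws, function(d) d$dp_alpha, 0))
    out["n_components"] <- mean(vapply(draws,
                                       function(d) length(d$weights), 0))
  }
  out
}

#' Posterior-mean component profiles
#'
#' For fixed-dimension models, the across-draw mean of each component
#' profile (components x 20).  Not defined for DP fits, whose component
#' count varies across draws.
#'
#' @param fit a `mixcv_fit`.
#' @return Matrix of posterior-mean profiles.
#' @export
posterior_mean_profiles <- function(fit) {
  if (fit$spec$profile_mode == "dp") {
    stop("DP fits have a varying number of components")
  }
  Reduce(`+`, lapply(fit$draws, `[[`, "components")) / fit$K
}

#' @export
logLik.mixcv_fit <- function(object, ...) {
  post <- object$trace[object$trace$cycle > object$cfg$burn_in, ]
  val <- mean(post$log_likelihood)
  df <- length(unlist(object$draws[[1L]]))
  structure(val, df = df, class = "logLik")
}

#' @export
plot.mixcv_fit <- function(x, ...) {
  has_alpha <- !all(is.na(x$trace$alpha))
  op <- par(mfrow = c(if (has_alpha) 2L else 1L, 1L), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$trace$cycle, x$trace$log_likelihood, type = "l",
       xlab = "cycle", ylab = "log-likelihood",
       main = model_name(x$spec), ...)
  abline(v = x$cfg$burn_in, lty = 2)
  if (has_alpha) {
    plot(x$trace$cycle, x$trace$alpha, type = "l", xlab = "cycle",
         ylab = "gamma shape", ...)
    abline(v = x$cfg$burn_in, lty = 2)
  }
  invisible(x)
}

#' Simulate alignments from the posterior
#'
#' Draws a posterior sample at random and simulates an alignment of
#' `n_sites` columns from it along the fitted tree (posterior branch
#' lengths).  For DP fits the draw's occupied components with their
#' occupancy weights are used.
#'
#' @param object a `mixcv_fit`.
#' @param nsim number of alignments.
#' @param seed optional seed.
#' @param n_sites columns per simulated alignment (defaults to the
#'   fitted data size).
#' @param ... unused.
#' @return List of simulation results (see [simulate_alignment]).
#' @export
simulate.mixcv_fit <- function(object, nsim = 1, seed = NULL,
                               n_sites = object$n_sites, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(j) {
    d <- object$draws[[sample.int(object$K, 1L)]]
    model <- draw_to_model(object, d)
    tree <- object$tree
    tree$edge.length <- d$bl
    cfg <- simulation_config(length(object$taxa), n_sites, model,
                             tree = tree, seed = sample.int(2^31 - 1, 1L))
    simulate_alignment(cfg)
  })
}

# reconstitute a mixture_model from one posterior draw
draw_to_model <- function(fit, d) {
  spec <- fit$spec
  exch <- if (spec$exchangeability_mode == "gtr") {
    exchangeabilities("gtr", d$rho)
  } else exchangeabilities("poisson")
  gamma <- if (!is.null(d$alpha)) discretize_gamma(d$alpha, spec$n_cat)
  structure(list(spec = spec, exch = exch, components = d$components,
                 weights = d$weights, gamma = gamma,
                 site_allocation = NULL, dp_alpha = d$dp_alpha),
            class = "mixture_model")
}
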