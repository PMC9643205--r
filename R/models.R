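#' Amino acid frequency profile
#'
#' A point on the 20-simplex in canonical order, floored and renormalized.
#'
#' @param freqs 20 nonnegative frequencies.
#' @param floor entry floor applied before renormalization (zero entries
#'   would make log-likelihoods minus infinity).
#' @return Named numeric vector of class `aa_profile`.
#' @export
aa_profile <- function(freqs, floor = 1e-8) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 20L) stop("a profile has 20 entries")
  if (any(freqs < 0) || !all(is.finite(freqs))) {
    stop("profile entries must be finite and nonnegative")
  }
  freqs <- pmax(freqs, floor)
  freqs <- freqs / sum(freqs)
  structure(stats::setNames(freqs, AA_ORDER), class = "aa_profile")
}

#' Exchangeability parameters
#'
#' The 190 symmetric pairwise exchangeabilities between amino acids.
#' `"poisson"` sets all equal; `"gtr"` takes 190 free nonnegative values.
#' Free values are identified by normalizing their sum to 190 (mean 1),
#' since their overall scale is confounded with branch lengths.
#'
#' @param mode `"poisson"` or `"gtr"`.
#' @param rho 190 nonnegative values (required for `"gtr"`, ignored for
#'   `"poisson"`); order is the upper triangle of the 20x20 matrix in
#'   canonical amino acid order, filled by column.
#' @return Object of class `exchangeabilities`: list with `mode` and
#'   `rho` (length 190, sum 190).
#' @export
exchangeabilities <- function(mode = c("poisson", "gtr"), rho = NULL) {
  mode <- match.arg(mode)
  if (mode == "poisson") {
    rho <- rep(1, 190L)
  } else {
    if (is.null(rho) || length(rho) != 190L) {
      stop("gtr exchangeabilities need 190 values")
    }
    if (any(rho < 0) || sum(rho) <= 0) stop("exchangeabilities must be nonnegative")
    rho <- 190 * rho / sum(rho)
  }
  structure(list(mode = mode, rho = rho), class = "exchangeabilities")
}

# 20x20 symmetric matrix with zero diagonal from the 190-vector
exch_matrix <- function(exch) {
  R <- matrix(0, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
  R[upper.tri(R)] <- exch$rho
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Build a reversible amino acid rate matrix
#'
#' Off-diagonal entries are `rho_ab * pi_b`, the diagonal is minus the row
#' sum, and the generator is normalized so that the expected replacement
#' rate at stationarity, `sum_a pi_a * (-q_aa)`, equals one: branch
#' lengths are expected replacements per site.
#'
#' @param profile an [aa_profile] (or 20 frequencies).
#' @param exch an [exchangeabilities] object.
#' @return 20x20 generator matrix with attributes `pi` (the stationary
#'   profile) used by [transition_matrix].
#' @export
build_rate_matrix <- function(profile, exch) {
  pi <- as.numeric(aa_profile(profile))
  if (any(pi <= 0)) stop("profile has a zero entry after flooring")
  R <- exch_matrix(exch)
  Q <- R * rep(pi, each = 20L)
  diag(Q) <- -rowSums(Q)
  z <- -sum(pi * diag(Q))
  Q <- Q / z
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  attr(Q, "pi") <- pi
  Q
}

# Symmetrized eigendecomposition of a reversible generator:
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric, so
# Q = U diag(lambda) V with U = D^-1/2 S, V = S' D^1/2, S orthogonal.
decompose_generator <- function(Q, pi = attr(Q, "pi")) {
  if (is.null(pi)) stop("generator lacks a stationary profile attribute")
  s <- sqrt(pi)
  B <- Q * (s / rep(s, each = 20L))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / s, lambda = e$values, V = t(e$vectors) * rep(s, each = 20L))
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed by symmetrized eigendecomposition (exact for
#' the reversible generators built by [build_rate_matrix]).  Tiny negative
#' entries arising from round-off are clamped at zero.
#'
#' @param Q generator from [build_rate_matrix].
#' @param t branch length times rate multiplier, `t >= 0`.
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("t must be nonnegative")
  d <- decompose_generator(Q)
  P <- d$U %*% (exp(d$lambda * t) * d$V)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Closed-form F81-type transition probabilities
#'
#' For even exchangeabilities the process is the amino acid analogue of
#' Felsenstein's 1981 nucleotide model and the transition probabilities
#' have the closed form
#' `P_ab(t) = pi_b (1 - exp(-beta t)) + delta_ab exp(-beta t)` with
#' `beta = 1 / (1 - sum_b pi_b^2)`.  Serves as an independent oracle for
#' [transition_matrix] under Poisson exchangeabilities.
#'
#' @param profile an [aa_profile] (or 20 frequencies).
#' @param t branch length, `t >= 0`.
#' @return 20x20 stochastic matrix.
#' @export
closed_form_f81_transition <- function(profile, t) {
  if (t < 0) stop("t must be nonnegative")
  pi <- as.numeric(aa_profile(profile))
  beta <- 1 / (1 - sum(pi^2))
  e <- exp(-beta * t)
  P <- (1 - e) * matrix(pi, 20L, 20L, byrow = TRUE) + e * diag(20L)
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' Discrete-gamma rate categories
#'
#' Site rates follow a mean-one gamma law with shape `alpha`, discretized
#' into `n_cat` equally weighted categories.  Category boundaries sit at
#' the `k/n_cat` quantiles and each category rate is the conditional mean
#' of the gamma law within its bin (so the mean rate is exactly one).
#'
#' @param alpha gamma shape, `> 0`; small values mean strong rate
#'   heterogeneity.
#' @param n_cat number of categories (default 4).
#' @return Object of class `discrete_gamma`: list with `alpha`, `n_cat`,
#'   `rates` (nondecreasing, mean 1) and `weights` (all `1/n_cat`).
#' @export
discretize_gamma <- function(alpha, n_cat = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  n_cat <- as.integer(n_cat)
  if (n_cat < 1L) stop("n_cat must be >= 1")
  b <- stats::qgamma(seq(0L, n_cat) / n_cat, shape = alpha, rate = alpha)
  # E[X 1(X < b)] for Gamma(alpha, alpha) is pgamma(b, alpha + 1, alpha)
  mass <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- n_cat * diff(mass)
  structure(list(alpha = alpha, n_cat = n_cat, rates = rates,
                 weights = rep(1 / n_cat, n_cat)),
            class = "discrete_gamma")
}

#' Declarative model specification
#'
#' Describes one model from the lattice studied by the package:
#' exchangeabilities (Poisson vs GTR) crossed with the profile structure
#' (single profile, empirical mixture with free weights, free finite
#' mixture, or Dirichlet-process mixture) and optional discrete-gamma
#' rates.  Printing follows the field's nomenclature: a single profile
#' with Poisson exchangeabilities is `F81`, with GTR exchangeabilities
#' `GTR`; mixtures print as e.g. `CATf=100-GTR+G`, `C60-Poisson`,
#' `CAT-GTR+G`.
#'
#' @param exchangeability_mode `"poisson"` or `"gtr"`.
#' @param profile_mode `"single"`, `"empirical"`, `"free"` or `"dp"`.
#' @param n_components number of components (free finite mixtures).
#' @param gamma logical; include discrete-gamma rate variation (`+G`)?
#' @param n_cat gamma category count (default 4).
#' @param profile_set a [profile_set] (required for `"empirical"`).
#' @param dp_concentration_mean mean of the exponential hyperprior on the
#'   Dirichlet-process concentration (DP mode).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(exchangeability_mode = c("poisson", "gtr"),
                       profile_mode = c("single", "empirical", "free", "dp"),
                       n_components = NULL, gamma = TRUE, n_cat = 4L,
                       profile_set = NULL, dp_concentration_mean = 1) {
  exchangeability_mode <- match.arg(exchangeability_mode)
  profile_mode <- match.arg(profile_mode)
  if (profile_mode == "empirical") {
    if (is.null(profile_set)) stop("empirical mixture requires a profile_set")
    stopifnot(inherits(profile_set, "profile_set"))
    n_components <- profile_set$n_components
  }
  if (profile_mode == "free") {
    if (is.null(n_components) || n_components < 1L) {
      stop("free finite mixture requires n_components >= 1")
    }
    n_components <- as.integer(n_components)
  }
  if (profile_mode == "single") n_components <- 1L
  structure(list(exchangeability_mode = exchangeability_mode,
                 profile_mode = profile_mode,
                 n_components = n_components,
                 gamma = isTRUE(gamma), n_cat = as.integer(n_cat),
                 profile_set = profile_set,
                 dp_concentration_mean = dp_concentration_mean),
            class = "model_spec")
}

#' Model name in standard nomenclature
#'
#' @param spec a [model_spec].
#' @return Single string, e.g. `"CAT-GTR+G"`.
#' @export
model_name <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  exch <- if (spec$exchangeability_mode == "poisson") "Poisson" else "GTR"
  base <- switch(spec$profile_mode,
    single = if (spec$exchangeability_mode == "poisson") "F81" else "GTR",
    empirical = paste0(spec$profile_set$name, "-", exch),
    free = paste0("CATf=", spec$n_components, "-", exch),
    dp = paste0("CAT-", exch))
  paste0(base, if (spec$gamma) "+G" else "")
}

#' @export
format.model_spec <- function(x, ...) model_name(x)

#' @export
print.model_spec <- function(x, ...) {
  cat(model_name(x), "\n", sep = "")
  invisible(x)
}

#' Draw an initial mixture-model state from the priors
#'
#' Profiles and weights are drawn from uniform Dirichlet priors, GTR
#' exchangeabilities from a uniform Dirichlet on the normalized
#' 190-vector, the gamma shape and DP concentration from their
#' exponential priors.  Empirical mode copies the profiles from the
#' spec's profile set and draws only the weights.  DP mode seats all
#' `n_sites` sites by a sequential Chinese-restaurant draw; its weights
#' are occupancy-derived.
#'
#' @param spec a [model_spec].
#' @param n_sites number of alignment columns (needed for the DP site
#'   allocation).
#' @param seed optional integer; when given, the draw is reproducible
#'   (the caller's RNG state is restored afterwards).
#' @param priors a [prior_config].
#' @return Object of class `mixture_model`: list with `spec`, `exch`,
#'   `components` (matrix, one row per component), `weights`, `gamma`
#'   (a `discrete_gamma` or `NULL`), `site_allocation` (DP mode) and
#'   `dp_alpha` (DP mode).
#' @export
instantiate_model <- function(spec, n_sites, seed = NULL,
                              priors = prior_config()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  exch <- if (spec$exchangeability_mode == "poisson") {
    exchangeabilities("poisson")
  } else {
    exchangeabilities("gtr", rdirichlet(1, rep(1, 190L))[1L, ])
  }
  gamma <- if (spec$gamma) {
    discretize_gamma(stats::rexp(1L, 1 / priors$alpha_mean), spec$n_cat)
  }
  alloc <- NULL
  dp_alpha <- NULL
  if (spec$profile_mode == "dp") {
    dp_alpha <- stats::rexp(1L, 1 / priors$dp_alpha_mean)
    alloc <- integer(n_sites)
    counts <- numeric(0)
    for (i in seq_len(n_sites)) {
      p <- c(counts, dp_alpha)
      z <- sample.int(length(p), 1L, prob = p)
      if (z > length(counts)) counts <- c(counts, 0)
      counts[z] <- counts[z] + 1
      alloc[i] <- z
    }
    components <- rdirichlet(length(counts), rep(1, 20L))
    weights <- counts / sum(counts)
  } else if (spec$profile_mode == "empirical") {
    components <- spec$profile_set$components
    weights <- rdirichlet(1, rep(1, spec$n_components))[1L, ]
  } else {
    components <- rdirichlet(spec$n_components, rep(1, 20L))
    weights <- if (spec$n_components == 1L) 1 else {
      rdirichlet(1, rep(1, spec$n_components))[1L, ]
    }
  }
  colnames(components) <- AA_ORDER
  structure(list(spec = spec, exch = exch, components = components,
                 weights = weights, gamma = gamma,
                 site_allocation = alloc, dp_alpha = dp_alpha),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Mixture model ", model_name(x$spec), ": ",
      nrow(x$components), " component(s)",
      if (!is.null(x$gamma)) sprintf(", gamma shape %.3f", x$gamma$alpha),
      if (!is.null(x$dp_alpha)) sprintf(", DP alpha %.3f", x$dp_alpha),
      "\n", sep = "")
  invisible(x)
}

# Dirichlet sampler (n draws x length(alpha)), floored away from zero so
# downstream log-likelihoods stay finite.
rdirichlet <- function(n, alpha, floor = 1e-8) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x <- pmax(x / rowSums(x), floor)
  x / rowSums(x)
}
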