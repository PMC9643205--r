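test_that("pruning matches brute-force enumeration on small trees", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:5, 1L)
    tr <- rand_tree(n)
    aln <- rand_aln(n, 1L, missing = 0.2)
    rownames(aln$seq) <- rownames(aln$states) <- aln$taxa <- tr$tip.label
    ex <- if (runif(1L) < 0.5) exchangeabilities("poisson") else rand_exch()
    pi <- rand_profile()
    r <- rexp(1L, 1) + 0.05
    a <- site_conditional_likelihood(aln, 1L, tr, pi, ex, rate = r)
    b <- brute_force_site_likelihood(aln, 1L, tr, pi, ex, rate = r)
    expect_lt(abs(a - b) / b, 1e-10)
  }
  expect_error(brute_force_site_likelihood(rand_aln(6L, 1L), 1L,
                                           rand_tree(6L), rand_profile(),
                                           exchangeabilities("poisson")),
               "5 taxa")
})

test_that("degenerate site likelihoods take their closed-form values", {
  tr0 <- read_tree("(A:0.0,B:0.0);")
  aln <- aa_alignment(c(A = "A", B = "A"))
  expect_equal(site_conditional_likelihood(aln, 1L, tr0, rep(1 / 20, 20),
                                           exchangeabilities("poisson")),
               0.05, tolerance = 1e-12)
  set.seed(32)
  tr <- rand_tree(4L)
  alnm <- aa_alignment(c(t1 = "-", t2 = "?", t3 = "X", t4 = "-"))
  expect_equal(site_conditional_likelihood(alnm, 1L, tr, rand_profile(),
                                           rand_exch()),
               1, tolerance = 1e-12)
})

test_that("mixture site likelihoods decompose over components", {
  set.seed(33)
  tr <- rand_tree(5L)
  aln <- rand_aln(5L, 4L)
  rownames(aln$seq) <- rownames(aln$states) <- aln$taxa <- tr$tip.label

  # single component: marginal = gamma-average of conditionals
  m1 <- instantiate_model(model_spec("poisson", "single", gamma = TRUE),
                          4L, seed = 1L)
  sl <- site_likelihood(aln, 2L, tr, m1)
  cond <- vapply(m1$gamma$rates, function(r) {
    site_conditional_likelihood(aln, 2L, tr, m1$components[1L, ], m1$exch,
                                rate = r)
  }, numeric(1L))
  expect_equal(sl$value, mean(cond), tolerance = 1e-12)

  # two identical components with equal weights: plain arithmetic mean
  m2 <- instantiate_model(model_spec("poisson", "free", n_components = 2L,
                                     gamma = FALSE), 4L, seed = 2L)
  m2$components[2L, ] <- m2$components[1L, ]
  m2$weights <- c(0.5, 0.5)
  s2 <- site_likelihood(aln, 1L, tr, m2)
  c1 <- site_conditional_likelihood(aln, 1L, tr, m2$components[1L, ], m2$exch)
  expect_equal(s2$value, c1, tolerance = 1e-12)

  # three components, no gamma: weighted sum of independent prunings
  m3 <- instantiate_model(model_spec("gtr", "free", n_components = 3L,
                                     gamma = FALSE), 4L, seed = 3L)
  s3 <- site_likelihood(aln, 3L, tr, m3)
  per <- vapply(1:3, function(cc) {
    site_conditional_likelihood(aln, 3L, tr, m3$components[cc, ], m3$exch)
  }, numeric(1L))
  expect_equal(s3$value, sum(m3$weights * per), tolerance = 1e-12)
  expect_lt(abs(s3$value - sum(m3$weights * s3$per_component)) /
              s3$value, 1e-10)
})

test_that("alignment log-likelihood sums sites and collapses patterns", {
  set.seed(34)
  tr <- rand_tree(5L)
  m <- instantiate_model(model_spec("gtr", "free", n_components = 2L,
                                    gamma = TRUE), 10L, seed = 4L)
  aln1 <- rand_aln(5L, 1L)
  rownames(aln1$seq) <- rownames(aln1$states) <- aln1$taxa <- tr$tip.label
  expect_equal(log_likelihood(aln1, tr, m),
               site_likelihood(aln1, 1L, tr, m)$log, tolerance = 1e-12)

  dup <- aln1[c(1L, 1L)]
  expect_equal(log_likelihood(dup, tr, m),
               2 * log_likelihood(aln1, tr, m), tolerance = 1e-12)

  aln10 <- rand_aln(5L, 10L, missing = 0.1)
  rownames(aln10$seq) <- rownames(aln10$states) <- aln10$taxa <- tr$tip.label
  expect_equal(log_likelihood(aln10, tr, m, collapse = TRUE),
               log_likelihood(aln10, tr, m, collapse = FALSE),
               tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  set.seed(35)
  tr <- rand_tree(6L)
  aln <- rand_aln(6L, 30L, missing = 0.1)
  rownames(aln$seq) <- rownames(aln$states) <- aln$taxa <- tr$tip.label
  m <- instantiate_model(model_spec("gtr", "single", gamma = TRUE), 30L,
                         seed = 6L)
  ll <- log_likelihood(aln, tr, m)
  for (tip in c("t1", "t4")) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(log_likelihood(aln, rooted, m), ll, tolerance = 1e-10)
  }
})

test_that("masking an observed symbol never decreases a site likelihood", {
  set.seed(36)
  tr <- rand_tree(5L)
  aln <- rand_aln(5L, 6L, missing = 0)
  rownames(aln$seq) <- rownames(aln$states) <- aln$taxa <- tr$tip.label
  m <- instantiate_model(model_spec("poisson", "free", n_components = 2L,
                                    gamma = FALSE), 6L, seed = 7L)
  for (s in 1:6) {
    base <- site_likelihood(aln, s, tr, m)$value
    for (tx in 1:5) {
      masked <- aln
      masked$seq[tx, s] <- "-"
      masked <- aa_alignment(masked$seq)
      expect_gte(site_likelihood(masked, s, tr, m)$value, base - 1e-15)
    }
  }
})

test_that("allocated mode conditions on the assigned component", {
  set.seed(37)
  tr <- rand_tree(4L)
  aln <- rand_aln(4L, 5L)
  rownames(aln$seq) <- rownames(aln$states) <- aln$taxa <- tr$tip.label
  m <- instantiate_model(model_spec("poisson", "dp", gamma = FALSE), 5L,
                         seed = 8L)
  s <- site_likelihood(aln, 2L, tr, m, mode = "allocated")
  cc <- m$site_allocation[2L]
  expect_equal(s$value,
               site_conditional_likelihood(aln, 2L, tr,
                                           m$components[cc, ], m$exch),
               tolerance = 1e-12)
})
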