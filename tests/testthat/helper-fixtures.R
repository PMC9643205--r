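# small random objects used across the suite (all deterministic given the
# caller's RNG state)

rand_profile <- function(conc = 2) aa_profile(rgamma(20, conc))

rand_exch <- function() exchangeabilities("gtr", rgamma(190, 1))

rand_aln <- function(n_taxa, n_sites, missing = 0.05) {
  syms <- c(aa_alphabet(), if (missing > 0) c("-", "?", "X"))
  prob <- c(rep((1 - missing) / 20, 20),
            if (missing > 0) rep(missing / 3, 3))
  m <- matrix(sample(syms, n_taxa * n_sites, replace = TRUE, prob = prob),
              n_taxa, n_sites,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  aa_alignment(m)
}

rand_tree <- function(n_taxa, scale = 0.2) {
  sample_random_tree(n_taxa, branch_scale = scale)
}

# a hand-built fit whose site likelihood is known exactly: two taxa joined
# by zero-length branches observe state 'A', so p(D | theta) = pi_A
fake_fit <- function(piA) {
  tree <- read_tree("(A:0,B:0);")
  spec <- model_spec("poisson", "single", gamma = FALSE)
  draws <- lapply(piA, function(p) {
    prof <- matrix(c(p, rep((1 - p) / 19, 19)), 1L)
    list(bl = c(0, 0), rho = NULL, components = prof, weights = 1,
         alpha = NULL, dp_alpha = NULL, counts = NULL, alloc = NULL)
  })
  structure(list(spec = spec, draws = draws, K = length(draws),
                 tree = tree, taxa = c("A", "B"), n_sites = 1L,
                 cfg = chain_config(n_cycles = 2L, burn_in = 1L),
                 null_likelihood = FALSE),
            class = "mixcv_fit")
}

# standard error of the mean of an autocorrelated chain via batch means
batch_se <- function(x, n_batches = 50L) {
  n <- length(x) %/% n_batches * n_batches
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batches))
  sd(bm) / sqrt(n_batches)
}
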