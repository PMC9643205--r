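new_fold <- function(replicate_id, test, n_sites) {
  test <- sort(unique(as.integer(test)))
  structure(list(replicate_id = as.integer(replicate_id),
                 test_indices = test,
                 learn_indices = setdiff(seq_len(n_sites), test),
                 n_sites = as.integer(n_sites)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("Fold %d: %d test / %d learning columns\n", x$replicate_id,
              length(x$test_indices), length(x$learn_indices)))
  invisible(x)
}

#' Random learning/testing column splits
#'
#' Each replicate independently draws a uniform random subset of
#' `round(fraction * n_sites)` columns as the testing set; the complement
#' is the learning set.  Replicates are independent resamplings, not a
#' disjoint partition (the usual protocol for this flavor of fivefold
#' cross-validation); `partition = TRUE` gives a strict disjoint 5-way
#' partition instead.
#'
#' @param n_sites number of alignment columns.
#' @param n_replicates number of replicates (default 5).
#' @param fraction test fraction (default 1/5), in `(0, 1)`.
#' @param seed integer seed; splits are reproducible.
#' @param partition use a strict disjoint partition instead of
#'   independent resampling.
#' @return List of `fold_split` objects.
#' @export
split_folds <- function(n_sites, n_replicates = 5L, fraction = 1 / 5,
                        seed = 1L, partition = FALSE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n_sites < n_replicates) stop("need n_sites >= n_replicates")
  set.seed(seed)
  if (partition) {
    perm <- sample.int(n_sites)
    grp <- cut(seq_len(n_sites), n_replicates, labels = FALSE)
    lapply(seq_len(n_replicates), function(r) {
      new_fold(r, perm[grp == r], n_sites)
    })
  } else {
    size <- round(fraction * n_sites)
    lapply(seq_len(n_replicates), function(r) {
      new_fold(r, sample.int(n_sites, size), n_sites)
    })
  }
}

#' Per-site posterior-predictive log-likelihoods of test columns
#'
#' For every posterior draw the site likelihoods of the test columns are
#' computed at that draw's parameters; the average over draws is taken on
#' the natural scale (via log-sum-exp) and logged.  Finite and empirical
#' mixtures are scored marginally over their components; DP draws are
#' scored by the Chinese-restaurant predictive rule: occupied components
#' weighted `n_j / (n + alpha)` plus `alpha / (n + alpha)` times a
#' prior-predictive term averaged over `m_new` fresh base-distribution
#' profiles.
#'
#' @param fit a `mixcv_fit` from [run_chain].
#' @param test_aln an [aa_alignment] of test columns (same taxa).
#' @param m_new Monte Carlo draws for the DP prior-predictive term.
#' @return Numeric vector, one log posterior-mean likelihood per column.
#' @export
site_predictive_loglik <- function(fit, test_aln, m_new = fit$cfg$dp_new_m) {
  stopifnot(inherits(fit, "mixcv_fit"), inherits(test_aln, "aa_alignment"))
  pt <- prep_tree(fit$tree, test_aln)
  N <- test_aln$n_sites
  dp <- fit$spec$profile_mode == "dp"
  L <- matrix(0, fit$K, N)
  for (k in seq_len(fit$K)) {
    d <- fit$draws[[k]]
    model <- draw_to_model(fit, d)
    slots <- site_loglik_slots(pt, model, bl = d$bl)
    if (dp) {
      G <- if (is.null(model$gamma)) 1L else model$gamma$n_cat
      kk <- nrow(model$components)
      compll <- t(vapply(seq_len(kk), function(cc) {
        mix_rows(slots[(cc - 1L) * G + seq_len(G), , drop = FALSE] - log(G))
      }, numeric(N)))
      if (kk == 1L) compll <- matrix(compll, 1L, N)
      ptfit <- list(states = pt$states, edge = pt$edge, ntip = pt$ntip,
                    t = d$bl)
      lnew <- dp_new_loglik(ptfit, model, m_new)
      n <- sum(d$counts)
      Y <- rbind(compll + log(d$counts), lnew + log(d$dp_alpha))
      L[k, ] <- mix_rows(Y) - log(n + d$dp_alpha)
    } else {
      L[k, ] <- mix_slot_loglik(slots, model)
    }
  }
  mix_rows(L) - log(fit$K)
}

#' @rdname site_predictive_loglik
#' @param object a `mixcv_fit`.
#' @param newdata an [aa_alignment] to score.
#' @param ... passed on.
#' @export
predict.mixcv_fit <- function(object, newdata, ...) {
  site_predictive_loglik(object, newdata, ...)
}

#' Cross-validation score of a test set under a fitted model
#'
#' The Monte Carlo cross-validation score
#' `sum_i ln( (1/K) sum_k p(D_i | theta_k) )`: for each test column the
#' site likelihood is averaged over the posterior draws on the natural
#' scale, logged, and summed over columns.
#'
#' @param test_aln an [aa_alignment] of test columns.
#' @param fit a `mixcv_fit` from the corresponding learning run.
#' @param replicate_id replicate label stored in the result.
#' @param ... passed to [site_predictive_loglik].
#' @return Object of class `cv_score`: list with `model_name`,
#'   `replicate_id`, `score` (natural-log units) and `K`.
#' @export
cv_score <- function(test_aln, fit, replicate_id = 1L, ...) {
  ll <- site_predictive_loglik(fit, test_aln, ...)
  if (any(!is.finite(ll))) stop("site with zero averaged likelihood")
  structure(list(model_name = model_name(fit$spec),
                 replicate_id = as.integer(replicate_id),
                 score = sum(ll), K = fit$K),
            class = "cv_score")
}

#' @export
print.cv_score <- function(x, ...) {
  cat(sprintf("cv-score %s replicate %d: %.4f (K = %d)\n", x$model_name,
              x$replicate_id, x$score, x$K))
  invisible(x)
}

# normalize a list of cv_score (or a data frame) to a data frame
scores_frame <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("model", "replicate", "score") %in% names(scores)))
    return(scores)
  }
  do.call(rbind, lapply(scores, function(s) {
    data.frame(model = s$model_name, replicate = s$replicate_id,
               score = s$score)
  }))
}

#' Best-model tally across replicates
#'
#' Counts, per model, the replicates where it attained the highest
#' cross-validation score.  Exact ties are all counted (and reported via
#' a message), so tied replicates contribute one count to each tied
#' model.
#'
#' @param scores list of [cv_score] objects, or a data frame with columns
#'   `model`, `replicate`, `score`.
#' @return Named integer vector of counts (zero-count models included).
#' @export
best_model_tally <- function(scores) {
  df <- scores_frame(scores)
  models <- unique(df$model)
  tally <- setNames(integer(length(models)), models)
  for (r in unique(df$replicate)) {
    sub <- df[df$replicate == r, ]
    best <- sub$model[sub$score == max(sub$score)]
    if (length(best) > 1L) {
      message("replicate ", r, ": exact tie between ",
              paste(best, collapse = ", "))
    }
    tally[best] <- tally[best] + 1L
  }
  tally
}

#' Reference-relative cross-validation report
#'
#' For every model, the per-replicate difference from the reference
#' model's score in the same replicate is computed; the report gives the
#' across-replicate mean and sample standard deviation (n - 1) of those
#' differences, plus the per-model count of replicates won.
#'
#' @param scores list of [cv_score] objects or a data frame (see
#'   [best_model_tally]); every model must have a score for every
#'   replicate.
#' @param reference reference model name (e.g. `"GTR+G"`).
#' @return Object of class `cv_report`: list with `table` (model, mean,
#'   sd, best), `reference`, `n_replicates` and the raw `scores`.
#' @export
relative_score_table <- function(scores, reference) {
  df <- scores_frame(scores)
  models <- unique(df$model)
  reps <- sort(unique(df$replicate))
  if (!reference %in% models) stop("reference model '", reference,
                                   "' has no scores")
  grid <- table(df$model, df$replicate)
  if (any(grid != 1L)) {
    gaps <- which(grid != 1L, arr.ind = TRUE)
    stop("missing or duplicated (model, replicate) scores: ",
         paste(sprintf("(%s, %s)", rownames(grid)[gaps[, 1L]],
                       colnames(grid)[gaps[, 2L]]), collapse = ", "))
  }
  ref <- df[df$model == reference, ]
  ref <- setNames(ref$score, ref$replicate)
  tally <- best_model_tally(df)
  tab <- do.call(rbind, lapply(models, function(m) {
    sub <- df[df$model == m, ]
    diffs <- sub$score - ref[as.character(sub$replicate)]
    data.frame(model = m, mean = mean(diffs),
               sd = if (length(diffs) > 1L) sd(diffs) else 0,
               best = as.integer(tally[m]))
  }))
  structure(list(table = tab, reference = reference,
                 n_replicates = length(reps), scores = df),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation scores relative to %s (%d replicates)\n",
              x$reference, x$n_replicates))
  tab <- x$table
  mark <- ifelse(tab$best >= 1L, " *", "")
  lines <- sprintf("  %-22s %10.1f +/- %.1f%s", tab$model, tab$mean,
                   tab$sd, mark)
  cat(lines, sep = "\n")
  cat("  (* best in at least one replicate)\n")
  cat("Replicates won:\n")
  won <- tab[tab$best > 0L, ]
  for (i in seq_len(nrow(won))) {
    cat(sprintf("  %-22s %d\n", won$model[i], won$best[i]))
  }
  invisible(x)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment] needs: the data (or a simulation
#' recipe), the models to compare, chain and fold settings, the reference
#' model and the output directory.
#'
#' @param models non-empty list of [model_spec]s.
#' @param alignment an [aa_alignment] (or `NULL` with `sim`).
#' @param tree an [ape::phylo] with branch lengths (fixed topology).
#' @param sim a [simulation_config] used when `alignment` is `NULL`.
#' @param chain a [chain_config] template (per-task seeds are derived
#'   from `seed`).
#' @param priors a [prior_config].
#' @param n_replicates,fraction,partition fold settings (see
#'   [split_folds]).
#' @param reference reference model name; must name one of `models`.
#' @param out_dir output directory.
#' @param seed master seed; every task seed is derived from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(models, alignment = NULL, tree = NULL,
                              sim = NULL, chain = chain_config(),
                              priors = prior_config(), n_replicates = 5L,
                              fraction = 1 / 5, partition = FALSE,
                              reference = "GTR+G", out_dir = "mixcv_out",
                              seed = 1L) {
  if (length(models) == 0L) stop("config error: empty model list")
  stopifnot(all(vapply(models, inherits, TRUE, "model_spec")))
  names(models) <- vapply(models, model_name, character(1L))
  if (!reference %in% names(models)) {
    stop("config error: reference model '", reference,
         "' not in model list")
  }
  if (is.null(alignment) && is.null(sim)) {
    stop("config error: either alignment+tree or sim required")
  }
  if (!is.null(alignment) && is.null(tree)) {
    stop("config error: alignment requires a tree")
  }
  structure(list(models = models, alignment = alignment, tree = tree,
                 sim = sim, chain = chain, priors = priors,
                 n_replicates = as.integer(n_replicates),
                 fraction = fraction, partition = isTRUE(partition),
                 reference = reference, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic per-task seed from master seed, replicate and model name
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(..., sep = "#"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(max(h, 1))
}

#' Run a full cross-validation experiment
#'
#' For every replicate and model: runs a learning chain on the learning
#' columns and scores the testing columns, then assembles the
#' reference-relative report and best-model tally.  All artifacts
#' (alignment, tree, folds, traces, fits, scores, report, manifest) are
#' written under the output directory.  Completed per-task fits found on
#' disk are reused rather than recomputed unless `force = TRUE`;
#' interrupted chains resume from their checkpoints.
#'
#' @param cfg an [experiment_config].
#' @param force recompute tasks even when their fit file exists.
#' @return The [relative_score_table] report (invisibly also written to
#'   disk), with the per-task fits' file paths in the manifest.
#' @export
run_experiment <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)

  if (is.null(cfg$alignment)) {
    sim <- simulate_alignment(cfg$sim)
    aln <- sim$alignment
    tree <- sim$tree
    write_alignment(aln, out("alignment.fasta"))
    ape::write.tree(tree, out("tree.nwk"))
    utils::write.table(sim$truth, out("truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(out("alignment.fasta")); note(out("tree.nwk")); note(out("truth.tsv"))
  } else {
    aln <- cfg$alignment
    tree <- cfg$tree
  }
  check_tree_taxa(tree, aln$taxa)

  folds <- split_folds(aln$n_sites, cfg$n_replicates, cfg$fraction,
                       seed = derive_seed(cfg$seed, "folds"),
                       partition = cfg$partition)
  write_folds(folds, out("folds.tsv"))
  note(out("folds.tsv"))

  scores <- list()
  for (f in folds) {
    learn <- aln[f$learn_indices]
    test <- aln[f$test_indices]
    for (nm in names(cfg$models)) {
      tag <- paste0(gsub("[^A-Za-z0-9]+", "_", nm), "_rep", f$replicate_id)
      fit_file <- out(paste0("fit_", tag, ".rds"))
      if (force && file.exists(fit_file)) unlink(fit_file)
      if (file.exists(fit_file)) {
        fit <- readRDS(fit_file)
      } else {
        ccfg <- cfg$chain
        ccfg$seed <- derive_seed(cfg$seed, f$replicate_id, nm)
        ccfg$trace_path <- out(paste0("trace_", tag, ".tsv"))
        ccfg$checkpoint_path <- out(paste0("ckpt_", tag, ".rds"))
        fit <- run_chain(learn, tree, cfg$models[[nm]], cfg$priors, ccfg)
        saveRDS(fit, fit_file)
        unlink(ccfg$checkpoint_path)
      }
      note(fit_file)
      note(out(paste0("trace_", tag, ".tsv")))
      scores[[length(scores) + 1L]] <- cv_score(test, fit, f$replicate_id)
    }
  }

  df <- scores_frame(scores)
  utils::write.table(df, out("scores.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  note(out("scores.tsv"))
  report <- relative_score_table(df, cfg$reference)
  writeLines(utils::capture.output(print(report)), out("report.txt"))
  note(out("report.txt"))
  writeLines(manifest, out("manifest.txt"))
  report
}
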