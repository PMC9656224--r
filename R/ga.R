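#' Genetic-algorithm configuration
#'
#' The published parameter set for the wrapper search is: 200 generations,
#' a population of 100 chromosomes, 10 parents retained per generation,
#' parent-sampling pools (tournaments) of size 4, and 3 gene flips per
#' offspring. Those are the defaults; every field is overridable, and the
#' fitness split fraction (held-out share of the inner accuracy
#' evaluation) mirrors the 85/15 protocol split.
#'
#' @param n_generations Number of generations (default 200).
#' @param n_parents Parents retained per generation (default 10).
#' @param population_size Chromosomes per generation (default 100).
#' @param pool_size Tournament size when sampling mates (default 4).
#' @param n_mutations Gene flips per offspring (default 3).
#' @param seed Seed controlling the whole run (default 0).
#' @param fitness_split Held-out fraction of the inner stratified split
#'   used to score a chromosome (default 0.15).
#' @param fitness_reps Number of inner splits a chromosome's accuracy is
#'   averaged over (default 1, a single fixed split; larger values give a
#'   finer-grained, less noisy fitness at proportional cost).
#' @param crossover `"single_point"` (default) or `"uniform"`.
#' @return List of class `emo_ga_config`.
#' @export
ga_config <- function(n_generations = 200L, n_parents = 10L,
                      population_size = 100L, pool_size = 4L,
                      n_mutations = 3L, seed = 0L, fitness_split = 0.15,
                      fitness_reps = 1L,
                      crossover = c("single_point", "uniform")) {
  crossover <- match.arg(crossover)
  stopifnot(population_size >= n_parents, n_parents >= 2L,
            n_mutations >= 0L, fitness_split > 0, fitness_split < 1,
            pool_size >= 1L, n_generations >= 0L, fitness_reps >= 1L)
  structure(list(n_generations = as.integer(n_generations),
                 n_parents = as.integer(n_parents),
                 population_size = as.integer(population_size),
                 pool_size = as.integer(pool_size),
                 n_mutations = as.integer(n_mutations),
                 seed = as.integer(seed), fitness_split = fitness_split,
                 fitness_reps = as.integer(fitness_reps),
                 crossover = crossover),
            class = "emo_ga_config")
}

# Stratified split: per-class round(frac * n_c) rows held out, at least 1
# and at most n_c - 1, drawn with the active RNG stream.
stratified_holdout <- function(y, frac) {
  test <- integer(0)
  for (lv in unique(as.character(y))) {
    idx <- which(as.character(y) == lv)
    k <- min(max(1L, round(frac * length(idx))), length(idx) - 1L)
    test <- c(test, sample(idx, k))
  }
  sort(test)
}

#' GA wrapper feature selection
#'
#' Binary chromosomes over the feature set are scored by the held-out
#' accuracy of a classifier trained on the masked features of an inner
#' stratified split (fixed once per run, so all chromosomes face the same
#' split). Each generation ranks the population, keeps the top
#' `n_parents`, and refills the population with offspring produced by
#' tournament-sampled parents, crossover, and `n_mutations` random gene
#' flips; the best chromosome ever seen is carried over (elitism), so the
#' best-fitness trace is non-decreasing by construction. All-zero
#' chromosomes are repaired by activating one random gene.
#'
#' @param X Windows x features numeric matrix with column names.
#' @param y Binary labels (low/high factor or 1-9 ratings).
#' @param classifier_kind Learner used as the fitness function
#'   (default `"svm"`, the cheapest).
#' @param cfg A [ga_config()].
#' @param classifier_config Extra config passed to [train_classifier()].
#' @return List of class `emo_selection`: `mask` (logical),
#'   `best_fitness_trace` (length `n_generations + 1`, entry 1 = best of
#'   the initial population), `selected_names`, `fitness`, `cfg`.
#' @export
ga_select <- function(X, y, classifier_kind = "svm", cfg = ga_config(),
                      classifier_config = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y <- dichotomize_if_needed(y)
  if (length(unique(as.character(y))) < 2L)
    stop("GA selection needs both classes present")
  p <- ncol(X)
  set.seed(cfg$seed)
  splits <- lapply(seq_len(cfg$fitness_reps), function(i) {
    test <- stratified_holdout(y, cfg$fitness_split)
    list(test = test, train = setdiff(seq_len(nrow(X)), test))
  })
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    acc <- mean(vapply(splits, function(sp) {
      model <- train_classifier(classifier_kind,
                                X[sp$train, mask, drop = FALSE],
                                y[sp$train], seed = cfg$seed,
                                config = classifier_config)
      accuracy(predict(model, X[sp$test, mask, drop = FALSE]), y[sp$test])
    }, numeric(1)))
    cache[[key]] <- acc
    acc
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(p, 1L)] <- TRUE
    mask
  }
  pop <- matrix(runif(cfg$population_size * p) < 0.5,
                cfg$population_size, p)
  pop <- t(apply(pop, 1L, repair))
  fits <- apply(pop, 1L, fitness)
  best_idx <- which.max(fits)
  best_mask <- pop[best_idx, ]
  best_fit <- fits[best_idx]
  trace <- best_fit
  tournament <- function(parent_fits) {
    cand <- sample.int(length(parent_fits), min(cfg$pool_size,
                                                length(parent_fits)))
    cand[which.max(parent_fits[cand])]
  }
  for (g in seq_len(cfg$n_generations)) {
    ord <- order(fits, decreasing = TRUE)
    parents <- pop[ord[seq_len(cfg$n_parents)], , drop = FALSE]
    pfits <- fits[ord[seq_len(cfg$n_parents)]]
    n_off <- cfg$population_size - cfg$n_parents
    offspring <- matrix(FALSE, n_off, p)
    for (i in seq_len(n_off)) {
      m1 <- parents[tournament(pfits), ]
      m2 <- parents[tournament(pfits), ]
      child <- if (cfg$crossover == "single_point") {
        pt <- sample.int(p - 1L, 1L)
        c(m1[seq_len(pt)], m2[(pt + 1L):p])
      } else {
        pick <- runif(p) < 0.5
        ifelse(pick, m1, m2)
      }
      if (cfg$n_mutations > 0L) {
        flip <- sample.int(p, min(cfg$n_mutations, p))
        child[flip] <- !child[flip]
      }
      offspring[i, ] <- repair(child)
    }
    pop <- rbind(parents, offspring)
    # elitism: the best chromosome ever seen stays in the population
    pop[1L, ] <- best_mask
    fits <- apply(pop, 1L, fitness)
    gi <- which.max(fits)
    if (fits[gi] > best_fit) {
      best_fit <- fits[gi]
      best_mask <- pop[gi, ]
    }
    trace <- c(trace, best_fit)
  }
  structure(list(mask = best_mask,
                 best_fitness_trace = trace,
                 selected_names = colnames(X)[best_mask],
                 fitness = best_fit, cfg = cfg,
                 classifier_kind = classifier_kind),
            class = "emo_selection")
}

#' Serialize a selection result to JSON
#'
#' @param sel An `emo_selection`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(mask = as.integer(sel$mask), trace = sel$best_fitness_trace,
         selected_names = sel$selected_names, fitness = sel$fitness,
         cfg = unclass(sel$cfg), classifier_kind = sel$classifier_kind),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
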