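#' Pareto dominance over (accuracy, precision, recall)
#'
#' All three objectives are maximised: `a` dominates `b` when `a` is at
#' least as good in every component and strictly better in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return `TRUE` iff `a` dominates `b`.
#' @examples
#' dominates(c(0.8, 0.7, 0.6), c(0.7, 0.7, 0.5))
#' @export
dominates <- function(a, b) all(a >= b) && any(a > b)

# n x n logical matrix: dom[i, j] is TRUE when row i dominates row j.
dominance_matrix <- function(obj) {
  n <- nrow(obj)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ge <- obj[i, 1L] >= obj[, 1L] & obj[i, 2L] >= obj[, 2L] &
          obj[i, 3L] >= obj[, 3L]
    gt <- obj[i, 1L] >  obj[, 1L] | obj[i, 2L] >  obj[, 2L] |
          obj[i, 3L] >  obj[, 3L]
    dom[i, ] <- ge & gt
  }
  dom
}

#' SPEA2 fitness assignment
#'
#' Computes, for every member of the pooled population-plus-archive, the
#' strength `S` (number of pool members it dominates), the raw fitness
#' `R` (sum of the strengths of its dominators, 0 exactly for
#' non-dominated members), the k-nearest-neighbour density
#' `D = 1 / (sigma_k + 2)` where `sigma_k` is the Euclidean distance in
#' objective space to the k-th nearest other member, and the fitness
#' `F = R + D`.  Because `D <= 1/2`, `F < 1` holds exactly for the
#' non-dominated members.
#'
#' @param obj numeric matrix of objective vectors, one row per pool
#'   member, columns (accuracy, precision, recall).
#' @param k neighbour index for the density estimate; defaults to
#'   `round(sqrt(n))` for a pool of size `n`, clamped to `[1, n - 1]`.
#' @return A list with numeric vectors `S`, `R`, `D`, `F` of length
#'   `nrow(obj)`, plus the distance matrix `dist` used for truncation.
#' @export
spea2_fitness <- function(obj, k = NULL) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 1L)
    return(list(S = 0, R = 0, D = 0.5, F = 0.5,
                dist = matrix(0, 1, 1)))
  dom <- dominance_matrix(obj)
  S <- rowSums(dom)
  R <- as.numeric(t(dom) %*% S)  # sum of dominators' strengths
  d <- as.matrix(stats::dist(obj))
  if (is.null(k)) k <- max(1L, round(sqrt(n)))
  k <- min(max(1L, k), n - 1L)
  # row includes the zero self-distance, so the k-th nearest OTHER member
  # sits at sorted position k + 1
  sigma_k <- unname(apply(d, 1L, function(row) sort(row)[k + 1L]))
  D <- 1 / (sigma_k + 2)
  list(S = S, R = R, D = D, F = R + D, dist = d, k = k)
}

#' Environmental selection with SPEA2 truncation
#'
#' All pool members with fitness `F < 1` (the non-dominated ones) enter
#' the next archive.  If they are fewer than `capacity`, the archive is
#' filled with dominated members in ascending `F` order (stable on ties).
#' If they exceed `capacity`, members are removed one at a time: the
#' member whose distance to its nearest neighbour (among the remaining
#' candidates) is smallest goes first, ties broken by the second-nearest
#' distance, then the third, and finally by lowest index.
#'
#' @param obj objective matrix of the pooled population and archive.
#' @param fitness result of [spea2_fitness()] on `obj`.
#' @param capacity archive capacity (>= 1).
#' @return Integer vector of selected row indices into `obj`.
#' @export
environmental_selection <- function(obj, fitness, capacity) {
  if (capacity < 1L) stop("config error: archive capacity must be >= 1")
  n <- nrow(obj)
  keep <- which(fitness$F < 1)
  if (length(keep) < capacity) {
    dominated <- setdiff(seq_len(n), keep)
    dominated <- dominated[order(fitness$F[dominated])]  # stable
    keep <- c(keep, dominated[seq_len(min(capacity - length(keep),
                                          length(dominated)))])
    return(keep)
  }
  d <- fitness$dist
  while (length(keep) > capacity) {
    sub <- d[keep, keep, drop = FALSE]
    diag(sub) <- Inf
    sorted <- apply(sub, 1L, sort)        # columns = members, rows = ranks
    victim <- 1L
    for (j in seq_along(keep)[-1L]) {
      cmp <- lexi_compare(sorted[, j], sorted[, victim])
      if (cmp < 0L) victim <- j          # strictly more crowded
    }
    keep <- keep[-victim]
  }
  keep
}

# -1 if a < b lexicographically, 1 if a > b, 0 if equal throughout
lexi_compare <- function(a, b) {
  neq <- which(a != b)
  if (length(neq) == 0L) return(0L)
  if (a[neq[1L]] < b[neq[1L]]) -1L else 1L
}

#' Binary tournament selection from the archive
#'
#' Draws two archive members uniformly with replacement and returns the
#' index of the one with the lower SPEA2 fitness `F`; on an exact tie the
#' first drawn wins.
#'
#' @param F_values numeric vector of archive fitness values.
#' @return Integer index of the winner.
#' @export
binary_tournament <- function(F_values) {
  n <- length(F_values)
  if (n == 0L) stop("selection error: empty archive")
  picks <- sample.int(n, 2L, replace = TRUE)
  if (F_values[picks[2L]] < F_values[picks[1L]]) picks[2L] else picks[1L]
}

#' Uniform crossover at feature-triple granularity
#'
#' With probability `p_c` the two parents exchange whole
#' `(incl, lo, hi)` triples: for each feature index independently, the
#' triple is swapped between the offspring with probability 1/2.
#' Otherwise the offspring are copies of the parents.  Keeping the triple
#' together preserves the coherence of each feature's interval.
#'
#' @param a,b parent [rule_genome()]s of equal length.
#' @param p_c crossover probability in \[0, 1\].
#' @return List of two offspring genomes.
#' @export
crossover <- function(a, b, p_c) {
  nf <- length(a$incl)
  if (length(b$incl) != nf) stop("parent genomes differ in length")
  if (stats::runif(1) >= p_c) return(list(a, b))
  swap <- stats::runif(nf) < 0.5
  child_a <- a; child_b <- b
  for (field in c("incl", "lo", "hi")) {
    tmp <- child_a[[field]][swap]
    child_a[[field]][swap] <- child_b[[field]][swap]
    child_b[[field]][swap] <- tmp
  }
  list(child_a, child_b)
}

#' Chaotic mutation
#'
#' Each gene (the concatenation `c(incl, lo, hi)`) independently mutates
#' with probability `p_m`; a mutating gene's value is replaced by the next
#' iterate of the shared guarded tent stream, so mutation is literally
#' chaotic value replacement rather than a local perturbation.
#'
#' @param g a [rule_genome()].
#' @param p_m per-gene mutation probability.
#' @param stream a [tent_stream()] shared across the run.
#' @return Mutated genome with all entries in (0, 1).
#' @export
chaotic_mutation <- function(g, p_m, stream) {
  v <- genome_to_vector(g)
  hit <- stats::runif(length(v)) < p_m
  n_hit <- sum(hit)
  if (n_hit > 0L) v[hit] <- tent_stream_next(stream, n_hit)
  vector_to_genome(v)
}

#' Evolution control parameters
#'
#' Bundles the settings of one evolutionary run.  The defaults mirror the
#' survey protocol: population and archive size 20, inclusion threshold
#' 0.5, crossover probability 0.8, mutation probability 0.1; the number
#' of generations (not reported in the protocol) defaults to 100.
#'
#' @param pop_size population size N (>= 2).
#' @param archive_size archive capacity (>= 2).
#' @param generations number of generations T (>= 0).
#' @param p_c crossover probability.
#' @param p_m per-gene mutation probability.
#' @param lambda inclusion threshold for genome decoding.
#' @param knn_k density neighbour index; default
#'   `round(sqrt(pop_size + archive_size))`.
#' @param chaos_seed tent stream seed in (0, 1).
#' @param prng_seed integer seed for all non-chaotic randomness
#'   (tournaments, crossover masks, mutation masks).
#' @return A list of class `spea2_control`.
#' @export
spea2_control <- function(pop_size = 20L, archive_size = 20L,
                          generations = 100L, p_c = 0.8, p_m = 0.1,
                          lambda = 0.5, knn_k = NULL,
                          chaos_seed = 0.7, prng_seed = 1L) {
  if (pop_size < 2L || archive_size < 2L) stop("sizes must be >= 2")
  if (p_c < 0 || p_c > 1 || p_m < 0 || p_m > 1)
    stop("probabilities must lie in [0, 1]")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  if (is.null(knn_k)) knn_k <- round(sqrt(pop_size + archive_size))
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k >= pop_size + archive_size)
    stop("knn_k must satisfy 1 <= k < pop_size + archive_size")
  if (chaos_seed <= 0 || chaos_seed >= 1)
    stop("chaos_seed must lie in (0, 1)")
  structure(list(pop_size = as.integer(pop_size),
                 archive_size = as.integer(archive_size),
                 generations = as.integer(generations),
                 p_c = p_c, p_m = p_m, lambda = lambda, knn_k = knn_k,
                 chaos_seed = chaos_seed,
                 prng_seed = as.integer(prng_seed)),
            class = "spea2_control")
}

# Decode + evaluate a list of genomes on the training matrix; returns the
# objective matrix and decoded rules.
evaluate_genomes <- function(genomes, schema, target_class, lambda, data) {
  rules <- lapply(genomes, decode_genome, schema = schema,
                  target_class = target_class,
                  lambda_threshold = lambda)
  obj <- t(vapply(rules, function(r) objectives(evaluate_rule(r, data)),
                  numeric(3)))
  colnames(obj) <- c("accuracy", "precision", "recall")
  list(rules = rules, obj = obj)
}

#' Run the chaos-embedded SPEA2 rule-mining loop for one target class
#'
#' Implements the evolutionary loop: tent-map chaotic initialisation of
#' the population, objective evaluation (accuracy, precision, recall of
#' each decoded rule on the training data, one-vs-rest), then `T`
#' generations of SPEA2 fitness assignment over population plus archive,
#' environmental selection into the archive (starting from an empty
#' archive), binary tournament mating from the archive, uniform
#' triple-level crossover and chaotic mutation, with full generational
#' replacement.  Fully deterministic given `control$chaos_seed` and
#' `control$prng_seed`.
#'
#' @param data labelled training data frame (schema features + `class`),
#'   containing the target class and at least one other class.
#' @param target_class class label the rules predict.
#' @param schema a [feature_schema]; default [cherry_schema()].
#' @param control a [spea2_control()].
#' @param trace logical; record per-generation diagnostics (archive size,
#'   best/mean objectives, fitness consistency)?
#' @return A list of class `pareto_rule_set` with elements `rules` (list
#'   of [interval_rule()]s, mutually non-dominated), `objectives`
#'   (matrix of their training accuracy/precision/recall), `genomes`,
#'   `target_class`, `control` and, when `trace = TRUE`, a `trace` data
#'   frame.
#' @export
evolve <- function(data, target_class, schema = cherry_schema(),
                   control = spea2_control(), trace = FALSE) {
  stopifnot_schema(schema)
  if (!"class" %in% names(data)) stop("'data' must have a class column")
  n_pos <- sum(data$class == target_class)
  if (n_pos == 0L || n_pos == nrow(data))
    stop("evolution error: training data must contain the target class ",
         "and at least one other class")
  nf <- n_features(schema)
  n_genes <- 3L * nf
  N <- control$pop_size

  # one continuous chaotic stream: initialisation consumes the first
  # N * n_genes iterates, mutation continues from there
  stream <- tent_stream(control$chaos_seed)
  init <- matrix(tent_stream_next(stream, N * n_genes),
                 nrow = N, ncol = n_genes, byrow = TRUE)
  pop <- lapply(seq_len(N), function(i) vector_to_genome(init[i, ]))
  trace_rows <- vector("list", control$generations + 1L)

  result <- with_seed(control$prng_seed, {
    archive_genomes <- list()
    archive_obj <- NULL
    for (gen in 0:control$generations) {
      ev <- evaluate_genomes(pop, schema, target_class, control$lambda,
                             data)
      pool_genomes <- c(pop, archive_genomes)
      pool_obj <- rbind(ev$obj, archive_obj)
      fit <- spea2_fitness(pool_obj, k = control$knn_k)
      sel <- environmental_selection(pool_obj, fit,
                                     control$archive_size)
      archive_genomes <- pool_genomes[sel]
      archive_obj <- pool_obj[sel, , drop = FALSE]
      if (trace) {
        nd <- fit$R == 0
        trace_rows[[gen + 1L]] <- data.frame(
          generation = gen,
          archive_size = length(sel),
          best_accuracy = max(pool_obj[, 1L]),
          mean_accuracy = mean(pool_obj[, 1L]),
          fitness_consistent = all((fit$F < 1) == nd))
      }
      if (gen == control$generations) break
      arch_F <- fit$F[sel]
      offspring <- vector("list", N)
      i <- 1L
      while (i <= N) {
        pa <- archive_genomes[[binary_tournament(arch_F)]]
        pb <- archive_genomes[[binary_tournament(arch_F)]]
        kids <- crossover(pa, pb, control$p_c)
        offspring[[i]] <- chaotic_mutation(kids[[1L]], control$p_m, stream)
        if (i + 1L <= N)
          offspring[[i + 1L]] <- chaotic_mutation(kids[[2L]], control$p_m,
                                                  stream)
        i <- i + 2L
      }
      pop <- offspring
    }
    # return decoded non-dominated archive
    fit_arch <- spea2_fitness(archive_obj, k = control$knn_k)
    nd <- which(fit_arch$R == 0)
    list(genomes = archive_genomes[nd],
         obj = archive_obj[nd, , drop = FALSE])
  })

  rules <- lapply(result$genomes, decode_genome, schema = schema,
                  target_class = target_class,
                  lambda_threshold = control$lambda)
  out <- list(rules = rules, objectives = result$obj,
              genomes = result$genomes, target_class = target_class,
              schema = schema, control = control)
  if (trace) out$trace <- do.call(rbind, trace_rows)
  class(out) <- "pareto_rule_set"
  out
}

#' @export
print.pareto_rule_set <- function(x, ...) {
  cat("Pareto rule set for class ", x$target_class, " (",
      length(x$rules), " non-dominated rule(s))\n\n", sep = "")
  for (i in seq_along(x$rules)) {
    cat(sprintf("%s   [Acc %.3f, Pre %.3f, Rec %.3f]\n",
                rule_to_text(x$rules[[i]]),
                x$objectives[i, 1L], x$objectives[i, 2L],
                x$objectives[i, 3L]))
  }
  invisible(x)
}

#' @export
length.pareto_rule_set <- function(x) length(x$rules)
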