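test_that("Pareto dominance is maximization-sense and strict", {
  expect_true(dominates(c(0.8, 0.7, 0.6), c(0.7, 0.7, 0.5)))
  expect_false(dominates(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)))
  expect_false(dominates(c(0.9, 0.2, 0.5), c(0.1, 0.9, 0.5)))
  expect_false(dominates(c(0.1, 0.9, 0.5), c(0.9, 0.2, 0.5)))
})

test_that("strength and raw fitness follow the domination-count formulas", {
  # chain A > B > C (A also dominates C)
  obj <- rbind(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
  fit <- spea2_fitness(obj, k = 1)
  expect_equal(fit$S, c(2, 1, 0))
  expect_equal(fit$R, c(0, 2, 3))   # R(B) = S(A), R(C) = S(A) + S(B)
  # mutually incomparable pool: all strengths and raw fitnesses are zero
  obj2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fit2 <- spea2_fitness(obj2, k = 1)
  expect_equal(fit2$S, c(0, 0, 0))
  expect_equal(fit2$R, c(0, 0, 0))
  # duplicated objective vectors do not dominate each other
  obj3 <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(spea2_fitness(obj3, k = 1)$S, c(0, 0))
})

test_that("density is the bounded kNN transform 1 / (sigma_k + 2)", {
  # two individuals at objective distance 1, k = 1
  obj <- rbind(c(0, 0, 0), c(1, 0, 0))
  fit <- spea2_fitness(obj, k = 1)
  expect_equal(fit$D, c(1 / 3, 1 / 3))
  # coincident individuals: sigma = 0 gives the upper bound 1/2
  obj2 <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(spea2_fitness(obj2, k = 1)$D, c(0.5, 0.5))
  # single-member pool convention
  expect_equal(spea2_fitness(matrix(c(1, 1, 1), 1), k = 1)$D, 0.5)
  # bound 0 < D <= 1/2 on random pools
  set.seed(5)
  obj3 <- matrix(runif(60), ncol = 3)
  D <- spea2_fitness(obj3, k = 4)$D
  expect_true(all(D > 0 & D <= 0.5))
})

test_that("fitness assignment matches the brute-force oracle", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    obj <- matrix(runif(3 * n), ncol = 3)
    k <- sample.int(n - 1, 1)
    fit <- spea2_fitness(obj, k = k)
    ora <- oracle_spea2(obj, k)
    expect_identical(fit$S, ora$S)
    expect_identical(fit$R, ora$R)
    expect_equal(fit$D, ora$D, tolerance = 1e-12)
    expect_equal(fit$F, ora$F, tolerance = 1e-12)
    # F < 1 exactly for the non-dominated members
    expect_identical(fit$F < 1, ora$R == 0)
  }
})

test_that("environmental selection truncates the most crowded member first", {
  # three non-dominated points; the middle one is closest to a neighbour
  obj <- rbind(c(0, 0, 1), c(0, 1, 0), c(0, 0.9, 0.1))
  fit <- spea2_fitness(obj, k = 1)
  sel <- environmental_selection(obj, fit, capacity = 2)
  expect_setequal(sel, c(1, 2))
  # non-dominated count equal to capacity: archive is exactly that set
  sel3 <- environmental_selection(obj, fit, capacity = 3)
  expect_setequal(sel3, 1:3)
  expect_error(environmental_selection(obj, fit, capacity = 0), "capacity")
})

test_that("an under-full archive is filled with the best dominated members", {
  # 2 non-dominated + 3 dominated with distinct raw fitness
  obj <- rbind(c(1, 0, 0), c(0, 1, 0),
               c(0.9, 0, 0), c(0.5, 0, 0), c(0.1, 0, 0))
  fit <- spea2_fitness(obj, k = 2)
  sel <- environmental_selection(obj, fit, capacity = 4)
  expect_setequal(sel[1:2], 1:2)
  # the two dominated members with lowest F join
  dominated_order <- order(fit$F[3:5]) + 2
  expect_setequal(sel, c(1, 2, dominated_order[1:2]))
})

test_that("truncation agrees with an exhaustive oracle on random fronts", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    # mutually non-dominated points on a simplex slice
    w <- matrix(runif(2 * n), ncol = 2)
    obj <- cbind(w, 2 - rowSums(w))  # constant sum => no domination
    fit <- spea2_fitness(obj, k = 2)
    cap <- sample(2:(n - 1), 1)
    sel <- environmental_selection(obj, fit, cap)
    expect_length(sel, cap)
    # oracle: iterative removal by lexicographic sorted-distance compare
    keep <- seq_len(n)
    d <- as.matrix(dist(obj))
    while (length(keep) > cap) {
      sub <- d[keep, keep]; diag(sub) <- Inf
      sorted <- apply(sub, 1, sort)
      victim <- 1
      for (j in seq_along(keep)[-1]) {
        cmp <- sorted[, j] - sorted[, victim]
        nz <- which(cmp != 0)
        if (length(nz) && cmp[nz[1]] < 0) victim <- j
      }
      keep <- keep[-victim]
    }
    expect_identical(sort(sel), keep)
  }
})

test_that("binary tournament prefers low fitness at the closed-form rate", {
  expect_error(binary_tournament(numeric(0)), "empty")
  set.seed(41)
  F_values <- c(0.2, 0.9)
  wins <- sum(replicate(10000, binary_tournament(F_values)) == 1L)
  # P(best wins) = P(drawn at least once) = 3/4
  expect_gt(wins / 10000, 0.73)
  expect_lt(wins / 10000, 0.77)
  # archive of size one always returns that member
  expect_equal(binary_tournament(0.4), 1L)
})

test_that("crossover conserves gene triples and respects p_c", {
  set.seed(51)
  a <- random_genome(6); b <- random_genome(6)
  off <- crossover(a, b, p_c = 0)
  expect_identical(off, list(a, b))
  for (i in 1:50) {
    off <- crossover(a, b, p_c = 1)
    for (j in 1:6) {
      tri_parents <- list(c(a$incl[j], a$lo[j], a$hi[j]),
                          c(b$incl[j], b$lo[j], b$hi[j]))
      tri_kids <- list(c(off[[1]]$incl[j], off[[1]]$lo[j], off[[1]]$hi[j]),
                       c(off[[2]]$incl[j], off[[2]]$lo[j], off[[2]]$hi[j]))
      expect_true(setequal(tri_parents, tri_kids))
    }
  }
})

test_that("chaotic mutation replaces genes with tent-stream values", {
  set.seed(61)
  g <- random_genome(5)
  s <- tent_stream(0.3)
  expect_identical(chaotic_mutation(g, 0, s), g)
  # p_m = 1: every gene replaced, in flat order c(incl, lo, hi)
  s2 <- tent_stream(0.3)
  mut <- chaotic_mutation(g, 1, s2)
  flat <- c(mut$incl, mut$lo, mut$hi)
  expect_equal(flat, tent_sequence(0.3, 15))
  # empirical mutation rate near p_m
  g10 <- random_genome(10)
  s3 <- tent_stream(0.7)
  hits <- 0; total <- 0
  for (i in 1:400) {
    m <- chaotic_mutation(g10, 0.1, s3)
    hits <- hits + sum(c(m$incl, m$lo, m$hi) != c(g10$incl, g10$lo, g10$hi))
    total <- total + 30
  }
  expect_gt(hits / total, 0.08)
  expect_lt(hits / total, 0.12)
  expect_true(all(c(m$incl, m$lo, m$hi) > 0 & c(m$incl, m$lo, m$hi) < 1))
})

test_that("evolve returns a mutually non-dominated archive and is reproducible", {
  set.seed(71)
  d <- random_labelled_data(60, toy_schema())
  ctl <- spea2_control(pop_size = 10, archive_size = 10, generations = 8,
                       chaos_seed = 0.41, prng_seed = 5)
  rs <- evolve(d, "L", schema = toy_schema(), control = ctl)
  expect_s3_class(rs, "pareto_rule_set")
  expect_gte(length(rs$rules), 1)
  obj <- rs$objectives
  for (i in seq_len(nrow(obj))) for (j in seq_len(nrow(obj)))
    if (i != j) expect_false(dominates(obj[i, ], obj[j, ]))
  rs2 <- evolve(d, "L", schema = toy_schema(), control = ctl)
  expect_identical(rs$objectives, rs2$objectives)
  expect_identical(lapply(rs$rules, rule_to_text),
                   lapply(rs2$rules, rule_to_text))
})

test_that("T = 0 reduces to environmental selection of the initial population", {
  set.seed(81)
  d <- random_labelled_data(40, toy_schema())
  ctl <- spea2_control(pop_size = 8, archive_size = 8, generations = 0,
                       chaos_seed = 0.3, prng_seed = 2)
  rs <- evolve(d, "M", schema = toy_schema(), control = ctl)
  # reconstruct by hand: decode + evaluate the chaotic initial population
  init <- chaotic_init_matrix(8, 6, 0.3)
  obj <- t(apply(init, 1, function(v) {
    g <- rule_genome(v[1:2], v[3:4], v[5:6])
    objectives(evaluate_rule(decode_genome(g, toy_schema(), "M"), d))
  }))
  fit <- spea2_fitness(obj, k = ctl$knn_k)
  nd <- obj[fit$R == 0, , drop = FALSE]
  got <- rs$objectives[order(rs$objectives[, 1], rs$objectives[, 2]), , drop = FALSE]
  want <- nd[order(nd[, 1], nd[, 2]), , drop = FALSE]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("evolve rejects single-class training data", {
  d <- data.frame(A = runif(10), B = runif(10), class = "L")
  expect_error(evolve(d, "L", schema = toy_schema()), "evolution error")
  expect_error(evolve(d, "M", schema = toy_schema()), "evolution error")
})
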