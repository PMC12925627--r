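test_that("mutation-step boundaries make all-A and all-B absorbing", {
  set.seed(1)
  g <- rep("A", 16)
  for (i in 1:50) g <- step_lineage(g, p = 1.0)
  expect_true(all(g == "A"))
  for (i in 1:500) g <- step_lineage(g, p = 0.0)
  expect_true(all(g == "B"))
  # integer scheme agrees at the boundaries too
  g <- rep("B", 4)
  for (i in 1:50) g <- step_lineage(g, p = 1.0, integer_scheme = TRUE)
  expect_true(all(g == "A"))
})

test_that("a single centromere transitions at rate 1 - p (Bernoulli check)", {
  set.seed(2)
  n_draws <- 1e5
  b <- 0
  for (i in seq_len(n_draws)) {
    b <- b + (step_lineage("A", p = 0.99) == "B")
  }
  se <- sqrt(0.01 * 0.99 / n_draws)
  expect_lt(abs(b / n_draws - 0.01), 4 * se)
})

test_that("vectorized replicate outcomes equal a literal step-by-step fold", {
  set.seed(33)
  for (trial in 1:20) {
    n <- sample(c(4L, 16L), 1)
    steps <- sample(c(10L, 50L, 200L), 1)
    p <- runif(1)
    idx <- sample.int(n, steps, replace = TRUE)
    becomes_b <- runif(steps) >= p
    # literal fold over the same draws
    g <- rep("A", n)
    for (s in seq_len(steps)) g[idx[s]] <- if (becomes_b[s]) "B" else "A"
    expect_equal(cenevo:::lineage_final_b(idx, becomes_b), sum(g == "B"))
  }
})

test_that("run_lineage is reproducible from its seed and respects ploidy", {
  cfg <- sim_config("haploid", p = 0.4, steps = 50, replicates = 200,
                    seed = 99)
  a <- run_lineage(cfg)
  b <- run_lineage(cfg)
  expect_identical(a$final_b, b$final_b)
  expect_equal(sum(a$distribution), 1)
  expect_equal(a$n, 16L)
  d <- run_lineage(sim_config("diploid", p = 0.4, steps = 50,
                              replicates = 10, seed = 1))
  expect_equal(d$n, 32L)
  # p = 1: no B ever
  pure <- run_lineage(sim_config("haploid", p = 1, steps = 1000,
                                 replicates = 500, seed = 3))
  expect_true(all(pure$final_b == 0L))
  expect_equal(pure$prop_full, 0)
})

test_that("markov_oracle matches exhaustive path enumeration (n=2, 3 steps)", {
  # enumerate all (centromere pick, outcome) paths: each step has 4 branches
  p <- 0.5
  enum <- c(`0` = 0, `1` = 0, `2` = 0)
  paths <- expand.grid(i1 = 1:2, o1 = 0:1, i2 = 1:2, o2 = 0:1,
                       i3 = 1:2, o3 = 0:1)
  for (r in seq_len(nrow(paths))) {
    g <- c(0, 0)
    prob <- 1
    for (s in 1:3) {
      i <- paths[[paste0("i", s)]][r]
      o <- paths[[paste0("o", s)]][r] # 1 = becomes B
      prob <- prob * 0.5 * (if (o == 1) 1 - p else p)
      g[i] <- o
    }
    k <- as.character(sum(g))
    enum[k] <- enum[k] + prob
  }
  expect_equal(sum(enum), 1)
  expect_equal(unname(markov_oracle(2, 0.5, 3)), unname(enum),
               tolerance = 1e-12)
})

test_that("markov_oracle boundary behaviour is exact", {
  expect_equal(unname(markov_oracle(16, 1, 500)), c(1, rep(0, 16)))
  d <- markov_oracle(16, 0, 5000)
  expect_gt(d["16"], 0.999) # all-B absorbing under p = 0
  expect_equal(sum(markov_oracle(32, 0.3, 100)), 1, tolerance = 1e-12)
})

test_that("simulator frequencies agree with the exact chain on a coarse grid", {
  # smaller replicate counts than the acceptance run, wider (5 SE) bands,
  # pooling states with tiny expectation into their neighbours
  reps <- 2000L
  for (n in c(2L, 16L)) {
    for (p in c(0, 0.5, 1)) {
      for (steps in c(20L, 100L)) {
        out <- run_lineage(sim_config("haploid", p = p, steps = steps,
                                      n_centromeres = n, replicates = reps,
                                      seed = 1000 + n + steps))
        exact <- markov_oracle(n, p, steps)
        big <- which(exact * reps >= 5)
        for (k in big) {
          se <- sqrt(exact[k] * (1 - exact[k]) / reps)
          expect_lt(abs(out$distribution[k] - exact[k]), 5 * se + 1e-9)
        }
        small <- setdiff(seq_along(exact), big)
        expect_lt(abs(sum(out$distribution[small]) - sum(exact[small])),
                  5 * sqrt(sum(exact[small]) / reps) + 0.005)
      }
    }
  }
})

test_that("relabeling A<->B with p -> 1-p mirrors the final distribution", {
  # mirroring swaps the types, the retention probability AND the start state
  for (p in c(0, 0.2, 0.5, 0.9)) {
    for (steps in c(20, 100)) {
      expect_equal(unname(markov_oracle(16, p, steps, start = 0)),
                   rev(unname(markov_oracle(16, 1 - p, steps, start = 16))),
                   tolerance = 1e-12)
    }
  }
  # the simulated all-A start agrees with the mirrored exact chain's mean
  a <- run_lineage(sim_config("haploid", p = 0.2, steps = 100,
                              replicates = 3000, seed = 42))
  mirror <- markov_oracle(16, 0.8, 100, start = 16)
  exp_mean <- 16 - sum(0:16 * mirror)
  expect_lt(abs(mean(a$final_b) - exp_mean),
            4 * sd(a$final_b) / sqrt(3000))
})

test_that("population simulation is seed-reproducible and p=1 stays all-A", {
  cfg <- sim_config("population", p = 1, steps = 100, replicates = 3,
                    meiosis = TRUE, seed = 5)
  out <- run_population(cfg)
  expect_true(all(out$total_b == 0L))
  expect_true(all(out$full_individuals == 0L))
  cfg2 <- sim_config("population", p = 0.01, steps = 120, replicates = 3,
                     meiosis = TRUE, seed = 6)
  expect_identical(run_population(cfg2)$total_b, run_population(cfg2)$total_b)
})

test_that("without meiosis the mutation supply bounds transitioned individuals", {
  out <- run_population(sim_config("population", p = 0.01, steps = 160,
                                   replicates = 4, meiosis = FALSE,
                                   seed = 11))
  # each step mutates one chromatid, so at most floor(steps / 32) individuals
  # can ever be fully transitioned
  expect_true(all(out$full_individuals <= floor(160 / 32)))
  # and no chromosome can fix population-wide (needs >= 200 hits)
  expect_true(all(out$fixed_chromosomes == 0L))
  expect_true(all(out$total_b <= 160L))
})

test_that("coupon-collector absorption time matches its closed form", {
  times <- time_to_full_transition(n = 16, replicates = 4000, seed = 8)
  h16 <- sum(1 / (1:16))
  expect_equal(mean(times), 16 * h16, tolerance = 3 * sd(times) /
                 sqrt(length(times)) / (16 * h16))
})
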