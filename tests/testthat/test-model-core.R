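test_that("selection coefficients are clamped draws with mean beta", {
  set.seed(42)
  s <- draw_selection_coefficient(1e6, sim_params())
  expect_true(all(s > 0) && all(s <= 1))

  # E[min(Exp(0.1), 1)] = 0.1 * (1 - exp(-10)); sd of one draw ~ beta
  mu <- clamped_mean_s(0.1)
  se <- 0.1 / sqrt(1e6)
  expect_lt(abs(mean(s) - mu), 3 * se)
  # and the clamp itself bites with probability exp(-10)
  p_clamp <- exp(-10) # 4.539993e-05
  se_clamp <- sqrt(p_clamp * (1 - p_clamp) / 1e6)
  expect_lt(abs(mean(s == 1) - p_clamp), 4 * se_clamp)
})

test_that("innovation registers only established tools, at rate N*p_inv*E[s]", {
  params <- sim_params()
  reg <- culturesim:::new_registry()

  # zero innovation rate: nothing ever happens
  p0 <- sim_params(p_inv = 0)
  set.seed(1)
  for (i in 1:50)
    expect_length(culturesim:::innovate_pop(integer(0), 200L, p0, reg,
                                            1L, i)$new, 0)
  expect_equal(culturesim:::reg_size(reg), 0L)

  # bookkeeping: new ids enter the repertoire and the registry with the
  # invention step and origin recorded
  set.seed(7)
  rep_ids <- integer(0)
  t_at <- integer(0)
  for (t in 1:5000) {
    out <- culturesim:::innovate_pop(rep_ids, 200L, params, reg, 3L, t)
    rep_ids <- out$rep
    t_at <- c(t_at, rep(t, length(out$new)))
  }
  expect_gt(length(rep_ids), 0)
  expect_identical(rep_ids, seq_along(rep_ids)) # consecutive fresh ids
  rdf <- as.data.frame(reg)
  expect_identical(rdf$t_invented, t_at)
  expect_true(all(rdf$origin_pop == 3L))
  expect_true(all(rdf$s > 0 & rdf$s <= 1))

  # establishment rate: E = N * p_inv * E[min(s,1)] per step
  set.seed(99)
  n_steps <- 2e5
  reg2 <- culturesim:::new_registry()
  total <- 0L
  for (t in seq_len(n_steps))
    total <- total + length(culturesim:::innovate_pop(integer(0), 200L,
                                                      params, reg2, 1L, t)$new)
  rate <- 200 * 0.001 * clamped_mean_s(0.1) # ~0.002
  se <- sqrt(rate * n_steps) / n_steps      # establishments ~ Poisson-like
  expect_lt(abs(total / n_steps - rate), 4 * se)
})

test_that("loss removes each tool independently with probability p_loss/N", {
  # zero loss rate
  set.seed(5)
  out <- culturesim:::lose_pop(1:40, 0)
  expect_identical(out$rep, 1:40)

  # per-tool probability is p_loss/N under the scaled model: exact values
  expect_equal(culturesim:::tool_loss_prob(c(200L, 400L), sim_params()),
               c(0.1 / 200, 0.1 / 400))
  # a population of size 2N has exactly half the per-tool loss probability
  p <- culturesim:::tool_loss_prob(c(200L, 400L), sim_params())
  expect_equal(p[2] / p[1], 0.5)

  # empirical frequency over a frozen repertoire of 40 tools, N = 200:
  # expected removals per step = 40 * (0.1/200) = 0.02
  set.seed(11)
  n_steps <- 1e5
  removed <- 0L
  for (i in seq_len(n_steps))
    removed <- removed + length(culturesim:::lose_pop(1:40, 0.1 / 200)$removed)
  expected <- 40 * (0.1 / 200) * n_steps # 2000
  se <- sqrt(40 * n_steps * (0.1 / 200) * (1 - 0.1 / 200))
  expect_lt(abs(removed - expected), 4 * se)

  # independent-individuals model: per-tool probability p_ind^N
  pi_ <- sim_params(loss_model = "independent_individuals", p_ind = 0.5)
  expect_equal(culturesim:::tool_loss_prob(10L, pi_), 0.5^10)
})

test_that("null dynamics leave the state unchanged and t_max = 0 is empty", {
  p_null <- tiny_params(p_inv = 0, p_loss = 0)
  sim <- run_simulation(metapopulation(c(100, 100), p_mig = 0), p_null,
                        seed = 3)
  expect_true(all(sim$sizes == 0))
  expect_equal(culturesim:::reg_size(sim$registry), 0L)

  # a state seeded with tools is untouched when all rates are zero
  st <- culture_state(metapopulation(50), p_null)
  ids <- culturesim:::reg_add(st$registry, rep(0.5, 5), 1L, 0L)
  st$reps[[1]] <- ids
  set.seed(8)
  sim_step(st)
  expect_identical(st$reps[[1]], ids)
  expect_equal(st$t, 1L)

  sim0 <- run_simulation(metapopulation(200), sim_params(t_max = 0), seed = 1)
  expect_equal(nrow(sim0$sizes), 0L)
  expect_length(sim0$repertoires[[1]], 0)
  expect_error(summary(sim0), "window")
})

test_that("identical seeds give bit-identical trajectories", {
  meta <- metapopulation(c(60, 120), p_mig = 1e-4)
  p <- tiny_params()
  a <- run_simulation(meta, p, seed = 123)
  b <- run_simulation(meta, p, seed = 123)
  expect_identical(a$sizes, b$sizes)
  expect_identical(a$repertoires, b$repertoires)
  expect_identical(a$unique, b$unique)
  expect_identical(as.data.frame(a$registry), as.data.frame(b$registry))
  c <- run_simulation(meta, p, seed = 124)
  expect_false(identical(a$sizes, c$sizes))
})

test_that("repertoires stay duplicate-free and every id resolves in the registry", {
  meta <- metapopulation(c(80, 150), p_mig = 5e-4)
  p <- tiny_params()
  for (seed in 1:4) {
    sim <- run_simulation(meta, p, seed = seed)
    n_reg <- culturesim:::reg_size(sim$registry)
    for (ids in sim$repertoires) {
      expect_false(anyDuplicated(ids) > 0)
      expect_true(all(ids >= 1L & ids <= n_reg))
    }
    # recorded sizes are consistent with the final state
    expect_equal(sim$sizes[nrow(sim$sizes), ], lengths(sim$repertoires))
  }
})

test_that("isolated-population equilibrium matches the analytic balance", {
  # P_inv * beta * N = P_loss * x / N  =>  x = P_inv*beta*N^2/P_loss;
  # reduced protocol (relaxation ~ N/p_loss steps << window start)
  p <- reduced_params()
  for (n in c(100L, 200L, 400L)) {
    reps <- vapply(1:8, function(r) {
      summary(run_simulation(metapopulation(n), p,
                             seed = 1000L * n + r,
                             record_unique = FALSE))$mean_repertoire
    }, numeric(1))
    target <- equilibrium_repertoire(n, p)
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - target), 3 * se + 0.02 * target)
  }
})

test_that("engine agrees with a per-individual, per-tool brute-force oracle", {
  # N = 5 for 50 steps at boosted rates (equilibrium ~2.9 tools) so the
  # final-size distribution is non-degenerate; the oracle loops over
  # individuals and tools explicitly, the engine uses binomial counts
  n <- 5L
  t_max <- 50L
  n_rep <- 4000L
  p <- sim_params(p_inv = 0.2, beta = 0.3, p_loss = 0.5,
                  t_max = t_max, window_start = 25L, window_end = 50L)

  set.seed(2024)
  oracle <- vapply(seq_len(n_rep), function(r)
    oracle_run_final_size(n, 0.2, 0.3, 0.5, t_max), numeric(1))
  engine <- vapply(seq_len(n_rep), function(r) {
    sim <- run_simulation(metapopulation(n), p, seed = 50000L + r,
                          record_unique = FALSE)
    sim$sizes[t_max, 1]
  }, numeric(1))

  # means agree within Monte-Carlo error
  se <- sqrt(var(oracle) / n_rep + var(engine) / n_rep)
  expect_lt(abs(mean(oracle) - mean(engine)), 4 * se)

  # full distributions agree (chi-squared homogeneity, simulated p-value)
  lev <- 0:max(oracle, engine)
  tab <- cbind(tabulate(oracle + 1, length(lev)),
               tabulate(engine + 1, length(lev)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE,
                                           B = 2000))
  expect_gt(ct$p.value, 0.001)
})
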