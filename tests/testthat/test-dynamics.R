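test_that("zero pulse probability introduces no agents", {
  w <- quiet_world()
  set.seed(1)
  for (k in 1:20) {
    res <- pulse_events(w)
    w <- res$world
    expect_equal(nrow(res$events), 0)
  }
  expect_equal(nrow(world_agents(w)), 0)
})

test_that("per-day pulses average 100 impulses per species per year", {
  p <- sim_params(pulse_mode = "per_day")
  set.seed(42)
  years <- 5
  nrep <- 10
  successes <- replicate(nrep, {
    w <- new_world(p)
    tot <- 0
    for (day in seq_len(365 * years)) {
      w$step <- (day - 1L) * 10L   # steps that open a simulated day
      res <- pulse_events(w)
      tot <- tot + sum(res$events$count[res$events$species == "teff"])
      w <- res$world
    }
    tot / years
  })
  se <- sqrt(365 * (100 / 365) * (1 - 100 / 365) / (nrep * years))
  expect_equal(mean(successes), 100, tolerance = 3 * se / 100)
})

test_that("per-day mode skips steps inside a day; per-step mode never does", {
  p <- sim_params(pulse_mode = "per_day", pulse_prob = 1)
  w <- new_world(p)
  w$step <- 5L                      # mid-day step
  set.seed(1)
  expect_equal(nrow(pulse_events(w)$events), 0)
  w$step <- 10L                     # day boundary
  expect_equal(sum(pulse_events(w)$events$count), 3)
  p2 <- sim_params(pulse_mode = "per_step", pulse_prob = 1)
  w2 <- new_world(p2); w2$step <- 5L
  expect_equal(sum(pulse_events(w2)$events$count), 3)
})

test_that("pulsed T cells arrive resting with life in 1..2*hlife", {
  p <- sim_params(pulse_prob = 1, grid_size = 11)
  set.seed(7)
  w <- pulse_events(new_world(p))$world
  ag <- world_agents(w)
  expect_setequal(as.character(ag$species), c("teff", "treg", "virus"))
  tc <- ag[ag$species != "virus", ]
  expect_true(all(tc$state == "resting"))
  expect_true(all(ag$life >= 1 & ag$life <= 2 * p$hlife))
  expect_true(all(is.na(ag$state[ag$species == "virus"])))
})

test_that("movement is a uniform choice among the 4 neighbours", {
  w <- quiet_world()
  w <- add_agent(w, "virus", life = 1000, row = 5, col = 5)
  set.seed(5)
  dest <- replicate(1e4, {
    a <- move_agent(w, 1)$agents
    paste(a$row, a$col)
  })
  freq <- table(dest) / 1e4
  expect_setequal(names(freq), c("4 5", "6 5", "5 4", "5 6"))
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("virus contact activates the T cell and consumes the virus", {
  w <- quiet_world()
  w <- add_agent(w, "teff", "resting", life = 50, row = 5, col = 5)
  # no virus anywhere -> nothing happens
  set.seed(1)
  res <- activate_by_virus(w, 1)
  expect_false(res$outcome)
  expect_identical(res$world$agents, w$agents)
  # virus at distance 2 (within radius 3) -> activation + consumption
  w2 <- add_agent(w, "virus", life = 50, row = 5, col = 7)
  res2 <- activate_by_virus(w2, 1)
  expect_true(res2$outcome)
  ag <- world_agents(res2$world)
  expect_equal(sum(ag$species == "virus"), 0)
  expect_equal(as.character(ag$state[ag$species == "teff"]), "active")
  # virus at distance 3.5 > radius 3 (inclusive boundary) -> no activation
  w3 <- add_agent(w, "virus", life = 50, row = 5, col = 9)  # distance 4
  expect_false(activate_by_virus(w3, 1)$outcome)
  # resting Tregs activate by the same rule
  w4 <- quiet_world()
  w4 <- add_agent(w4, "treg", "resting", life = 50, row = 0, col = 0)
  w4 <- add_agent(w4, "virus", life = 50, row = 0, col = 10) # wraps to dist 1
  res4 <- activate_by_virus(w4, 1)
  expect_true(res4$outcome)
  # calling it on an active cell is a contract violation
  w5 <- quiet_world()
  w5 <- add_agent(w5, "teff", "active", life = 50, row = 1, col = 1)
  expect_error(activate_by_virus(w5, 1), "resting")
})

test_that("myelin attack destroys eat_mye, floors at zero, gates eligibility", {
  w <- quiet_world()
  w <- add_agent(w, "teff", "active", life = 50, row = 3, col = 3)
  res <- teff_attack(w, 1)
  expect_true(res$outcome)
  expect_equal(res$world$myelin[4, 4], 95)   # matrices are 1-based in R
  # low myelin clamps at 0 but the attack still counts
  w$myelin[4, 4] <- 3
  res2 <- teff_attack(w, 1)
  expect_true(res2$outcome)
  expect_equal(res2$world$myelin[4, 4], 0)
  # a bare patch forbids attack (and hence duplication)
  w$myelin[4, 4] <- 0
  res3 <- teff_attack(w, 1)
  expect_false(res3$outcome)
  expect_equal(res3$world$myelin[4, 4], 0)
  # contract: resting Teff cannot attack
  w6 <- quiet_world()
  w6 <- add_agent(w6, "teff", "resting", life = 50, row = 3, col = 3)
  expect_error(teff_attack(w6, 1), "active Teff")
})

test_that("the duplication law matches hand evaluation and its bounds", {
  p <- sim_params()
  expect_equal(teff_duplication_probability(100, p, 0), 0.1)
  expect_equal(teff_duplication_probability(0, p, 57), 0)
  expect_equal(teff_duplication_probability(50, p, 10), 0.1 * 0.25 * 0.5)
  expect_error(teff_duplication_probability(101, p, 0), "init_mye")
  # monotone: non-decreasing in myelin, non-increasing in local Tregs
  mgrid <- seq(0, 100, by = 10)
  for (tr in c(0, 1, 5, 20)) {
    pe <- teff_duplication_probability(mgrid, p, tr)
    expect_true(all(diff(pe) >= 0))
    expect_true(all(pe <= p$eff_dup))
  }
  for (m in mgrid) {
    pe <- sapply(c(0, 1, 2, 5, 10, 50), function(tr)
      teff_duplication_probability(m, p, tr))
    expect_true(all(diff(pe) <= 0))
  }
})

test_that("Treg counting is active-only with an inclusive boundary", {
  w <- quiet_world()
  expect_equal(count_tregs_in_radius(w, c(5, 5), 3), 0)
  w <- add_agent(w, "treg", "active", life = 50, row = 5, col = 8) # dist 3
  expect_equal(count_tregs_in_radius(w, c(5, 5), 3), 1)
  w <- add_agent(w, "treg", "resting", life = 50, row = 5, col = 5)
  expect_equal(count_tregs_in_radius(w, c(5, 5), 3), 1)  # resting ignored
  w <- add_agent(w, "treg", "active", life = 50, row = 9, col = 5) # dist 4
  expect_equal(count_tregs_in_radius(w, c(5, 5), 3), 1)
  expect_equal(count_tregs_in_radius(w, c(5, 5), 4), 2)
})

test_that("duplication obeys the Bernoulli, density gate and bookkeeping", {
  base <- quiet_world()
  base <- add_agent(base, "teff", "active", life = 50, row = 5, col = 5)
  # impossible event
  set.seed(1)
  expect_false(attempt_duplication(base, 1, 0)$outcome)
  # certain event, parent alone: newborn active in a VN neighbour, life halved
  res <- attempt_duplication(base, 1, 1)
  expect_true(res$outcome)
  ag <- world_agents(res$world)
  expect_equal(nrow(ag), 2)
  expect_equal(ag$life[1], 25)
  newborn <- ag[2, ]
  expect_equal(as.character(newborn$state), "active")
  expect_equal(torus_distance(c(newborn$row, newborn$col), c(5, 5), 11), 1)
  # full patch: one relocation retry; if the destination is also full, no birth
  crowded <- base
  for (k in 1:2) crowded <- add_agent(crowded, "virus", life = 9, row = 5, col = 5)
  for (r in c(4, 6)) for (cc in c(4, 5, 6))
    for (k in 1:3) crowded <- add_agent(crowded, "virus", life = 9, row = r, col = cc)
  for (cc in c(4, 6)) for (k in 1:3)
    crowded <- add_agent(crowded, "virus", life = 9, row = 5, col = cc)
  set.seed(2)
  res2 <- attempt_duplication(crowded, 1, 1)
  expect_false(res2$outcome)                       # every neighbour is full
  expect_equal(sum(world_agents(res2$world)$species == "teff"), 1)
  expect_error(attempt_duplication(base, 1, 1.5), "prob")
})

test_that("suppression removes the nearest active Teff and moves the Treg", {
  w <- quiet_world()
  w <- add_agent(w, "treg", "active", life = 50, row = 5, col = 5)
  set.seed(1)
  expect_false(treg_suppress(w, 1)$outcome)        # nothing in range
  w2 <- add_agent(w, "teff", "active", life = 50, row = 5, col = 7)
  w2 <- add_agent(w2, "teff", "resting", life = 50, row = 5, col = 6)
  res <- treg_suppress(w2, 1)
  expect_true(res$outcome)
  ag <- world_agents(res$world)
  expect_equal(sum(ag$species == "teff" & ag$state == "active", na.rm = TRUE), 0)
  expect_equal(sum(ag$species == "teff"), 1)       # resting Teff untouched
  treg <- ag[ag$species == "treg", ]
  expect_equal(c(treg$row, treg$col), c(5, 7))     # moved onto the victim
  expect_error(treg_suppress(w, 2), "out of range")
})

test_that("equidistant suppression targets are chosen uniformly", {
  w <- quiet_world()
  w <- add_agent(w, "treg", "active", life = 50, row = 5, col = 5)
  w <- add_agent(w, "teff", "active", life = 50, row = 5, col = 7)
  w <- add_agent(w, "teff", "active", life = 50, row = 5, col = 3)
  set.seed(8)
  victim <- replicate(1e4, {
    ag <- world_agents(treg_suppress(w, 1)$world)
    ag$col[ag$species == "teff"]   # the survivor's column
  })
  # survivor at col 3 means victim was col 7 and vice versa
  expect_equal(mean(victim == 3), 0.5, tolerance = 0.05)
})

test_that("myelin recovery heals damaged patches but never lesions", {
  w <- quiet_world()
  res0 <- recover_myelin(w)
  expect_equal(res0$recovered, 0)                  # saturated lattice
  w$myelin[2, 2] <- 95
  w$myelin[3, 3] <- 0
  res <- recover_myelin(w)
  expect_equal(res$recovered, 1)
  expect_equal(res$world$myelin[2, 2], 96)
  expect_equal(res$world$myelin[3, 3], 0)          # a lesion stays a lesion
  # recovery caps at init_mye
  w2 <- quiet_world(rec_mye = 10)
  w2$myelin[2, 2] <- 95
  expect_equal(recover_myelin(w2)$world$myelin[2, 2], 100)
})

test_that("life decrement reaps exactly the agents that hit zero", {
  w <- quiet_world()
  expect_equal(decrement_life_and_reap(w)$removed, 0)
  w <- add_agent(w, "teff", "resting", life = 1, row = 1, col = 1)
  w <- add_agent(w, "virus", life = 2, row = 2, col = 2)
  res <- decrement_life_and_reap(w)
  expect_equal(res$removed, 1)
  ag <- world_agents(res$world)
  expect_equal(nrow(ag), 1)
  expect_equal(as.character(ag$species), "virus")
  expect_equal(ag$life, 1)
})

test_that("engine duplication frequency matches the stated probability", {
  # Monte-Carlo: an isolated active Teff with prob fixed by the law
  p <- sim_params(grid_size = 11, pulse_prob = 0)
  w <- new_world(p)
  w$myelin[] <- 60
  w <- add_agent(w, "teff", "active", life = 50, row = 5, col = 5)
  prob <- teff_duplication_probability(60, p, 0)
  n <- 1e4
  set.seed(13)
  hits <- sum(replicate(n, attempt_duplication(w, 1, prob)$outcome))
  se <- sqrt(prob * (1 - prob) / n)
  expect_equal(hits / n, prob, tolerance = 3 * se / prob)
})
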