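test_that("annular distance is the Chebyshev metric", {
  expect_identical(annular_distance(c(0, 0), c(0, 0)), 0)
  expect_identical(annular_distance(c(0, 0), c(2, 1)), 2)
  set.seed(12)
  a <- matrix(sample(-50:50, 2000, replace = TRUE), ncol = 2)
  b <- matrix(sample(-50:50, 2000, replace = TRUE), ncol = 2)
  got <- annular_distance(a, b)
  for (i in seq_len(nrow(a))) {
    expect_identical(got[i], max(abs(a[i, 1] - b[i, 1]),
                                 abs(a[i, 2] - b[i, 2])))
  }
})

test_that("seed selection spans the random-to-contagious continuum", {
  nr <- 10
  p <- matrix(0, nr, nr)
  eligible <- matrix(FALSE, nr, nr)
  eligible[1:5, ] <- TRUE                       # 50 eligible cells
  set.seed(3)
  p[eligible] <- runif(50, 0.1, 0.8)
  imax <- which(eligible)[which.max(p[eligible])]

  # contagious limit: n >= #eligible with a unique argmax is deterministic
  set.seed(4)
  picks <- replicate(200, select_seed(p, eligible, n = 50)$index)
  expect_true(all(picks == imax))

  # random limit: n = 1 is uniform over eligible cells
  set.seed(5)
  draws <- replicate(20000, select_seed(p, eligible, n = 1)$index)
  tab <- table(factor(draws, levels = which(eligible)))
  chi <- chisq.test(tab)
  expect_gt(chi$p.value, 0.001)

  # ties at the maximum break uniformly
  p2 <- matrix(0, nr, nr)
  p2[eligible] <- 0.5
  p2[1, 1] <- 0.9
  p2[1, 2] <- 0.9
  set.seed(6)
  picks2 <- replicate(10000, select_seed(p2, eligible, n = 50)$index)
  share <- mean(picks2 == which(eligible)[1])
  expect_lt(abs(share - 0.5), 0.02)

  expect_null(select_seed(p, matrix(FALSE, nr, nr), n = 5))
})

test_that("patch windows clip to county and flag candidates", {
  t1 <- random_grid(9, 9, seed = 2, p_bg = 0)
  v <- t1$values
  county <- matrix(TRUE, 9, 9)
  gen <- matrix(0.5, 9, 9)
  w1 <- build_patch_window(c(5, 5), 1, county, v, gen, "d")
  expect_identical(nrow(w1$cells), 1L)
  expect_identical(w1$r, 0L)

  w5 <- build_patch_window(c(5, 5), 5, county, v, gen, "d")
  expect_identical(nrow(w5$cells), 25L)
  expect_true(all(pmax(abs(w5$cells[, 1] - 5), abs(w5$cells[, 2] - 5)) <= 2))
  # candidate rule: current class not in {target, d, w} and positive prob
  expect_identical(w5$candidate,
                   !(v[w5$cells] %in% class_code(c("d", "w"))) &
                     gen[w5$cells] > 0)

  # seed one cell from a county edge: only the in-county subset remains
  county2 <- matrix(FALSE, 9, 9)
  county2[, 1:5] <- TRUE
  w <- build_patch_window(c(5, 4), 5, county2, v, gen, "d")
  brute <- 0L
  for (r in 3:7) for (c in 2:6) if (county2[r, c]) brute <- brute + 1L
  expect_identical(nrow(w$cells), brute)
  expect_true(all(w$cells[, 2] <= 5))

  expect_error(build_patch_window(c(5, 5), 4, county, v, gen, "d"), "odd")
})

fake_window <- function(prob, dist, r) {
  list(cells = cbind(seq_along(prob), 1L), dist = dist, prob = prob,
       candidate = rep(TRUE, length(prob)), r = r)
}

test_that("the distance modifier follows its closed form", {
  # sigma = 0: score = p + (1 - d/r); the rim is unchanged
  for (r in c(1, 2, 5)) {
    d <- 0:r
    w <- fake_window(rep(0.5, r + 1), d, r)
    expect_equal(distance_modify(w), 0.5 + (1 - d / r), info = paste("r =", r))
  }
  # dist = r leaves the score at p for any sigma
  w <- fake_window(c(0.3, 0.7), c(2, 2), 2)
  expect_equal(distance_modify(w), c(0.3, 0.7) + 0)

  # the center-to-rim spread equals (1 - sigma)
  for (sigma in c(0, 0.1, 0.3)) {
    p <- c(0.5 - sigma, 0.5 + sigma, 0.5 - sigma, 0.5 + sigma)  # pop SD = sigma
    expect_equal(seedalloc:::pop_sd(p), sigma)
    d <- c(0, 0, 3, 3)
    sc <- distance_modify(fake_window(p, d, 3))
    expect_equal(sc[1] - sc[3], 1 - sigma)
    expect_equal(sc[2] - sc[4], 1 - sigma)
  }

  # r = 0 passes probabilities through
  expect_equal(distance_modify(fake_window(0.42, 0, 0)), 0.42)
})

make_state <- function(t1, stack) {
  e <- new.env()
  e$values <- t1$values
  e$gen <- stack$generalized
  e
}

test_that("patch conversion honors k, scores, and per-donor quotas", {
  t1 <- grid_from_rows(rep("fffff", 5))
  st <- uniform_stack(t1, 0.5)
  county <- matrix(TRUE, 5, 5)

  # k = 3 with ample quota converts exactly the 3 highest-scoring cells
  state <- make_state(t1, st)
  led <- quota_ledger("c1", c("f->d" = 100L))
  w <- build_patch_window(c(3, 3), 5, county, state$values,
                          state$gen[["d"]], "d")
  sc <- distance_modify(w)
  done <- convert_patch(w, sc, 3, led, "d", state)
  expect_length(done, 3L)
  expect_identical(unname(ledger_converted(led)["f->d"]), 3L)
  # uniform probabilities: the seed and its nearest neighbours convert
  expect_true(all(abs((done - 1) %% 5 + 1 - 3) <= 1))

  # quota-limited: k = 9 but only 2 cells of f->d quota
  state2 <- make_state(t1, st)
  led2 <- quota_ledger("c1", c("f->d" = 2L))
  w2 <- build_patch_window(c(3, 3), 5, county, state2$values,
                           state2$gen[["d"]], "d")
  done2 <- convert_patch(w2, distance_modify(w2), 9, led2, "d", state2)
  expect_length(done2, 2L)

  # mixed donors: spent forest quota is skipped, agriculture still converts
  t1m <- grid_from_rows(c("fafaf", "afafa", "fafaf", "afafa", "fafaf"))
  stm <- uniform_stack(t1m, 0.5)
  state3 <- make_state(t1m, stm)
  led3 <- quota_ledger("c1", c("f->d" = 0L, "a->d" = 5L))
  w3 <- build_patch_window(c(3, 3), 5, county, state3$values,
                           state3$gen[["d"]], "d")
  done3 <- convert_patch(w3, distance_modify(w3), 4, led3, "d", state3)
  expect_length(done3, 4L)
  expect_true(all(t1m$values[done3] == class_code("a")))
  expect_identical(unname(ledger_converted(led3)["a->d"]), 4L)
  expect_identical(unname(ledger_converted(led3)["f->d"]), 0L)

  # converted cells are removed from every probability surface
  for (l in names(state3$gen)) {
    expect_true(all(state3$gen[[l]][done3] == 0))
  }
})

county4 <- function(t1) {
  nr <- nrow(t1$values)
  nc <- ncol(t1$values)
  labels <- matrix("c1", nr, nc)
  labels[, (nc %/% 2 + 1):nc] <- "c2"
  labels[(nr %/% 2 + 1):nr, 1:(nc %/% 2)] <- "c3"
  labels[(nr %/% 2 + 1):nr, (nc %/% 2 + 1):nc] <- "c4"
  county_partition(labels)
}

test_that("county allocation meets quotas exactly or reports shortfall", {
  land <- generate_landscape(shape = c(40, 40), county_grid = c(1, 1),
                             mixture = c(d = 0.1, f = 0.6, a = 0.2,
                                         w = 0.02, o = 0.08),
                             clumpiness = 0.6, seed = 17)
  t1 <- land$grid
  counties <- land$counties
  st <- uniform_stack(t1, 0.5)
  cid <- counties$county_ids[1]

  # zero quotas: the landscape is untouched
  led0 <- build_quota_ledgers(data.frame(county = character(),
                                         donor = character(),
                                         target = character(),
                                         cells = integer()),
                              counties = cid)
  r0 <- allocate_all(t1, counties, st, led0, list(),
                     seeding_config(n = 8, seed = 1))
  expect_identical(r0$t2$values, t1$values)

  # feasible quota: exactly 50 forest cells become developed
  led <- build_quota_ledgers(data.frame(county = cid, donor = "f",
                                        target = "d", cells = 50L),
                             counties = cid)
  r1 <- allocate_all(t1, counties, st, led, list(),
                     seeding_config(n = 8, seed = 1))
  changed <- which(r1$t2$values != t1$values)
  expect_length(changed, 50L)
  expect_true(all(t1$values[changed] == class_code("f")))
  expect_true(all(r1$t2$values[changed] == class_code("d")))
  expect_identical(unname(ledger_converted(led[[cid]])["f->d"]), 50L)

  # infeasible quota: all 30 eligible cells convert, shortfall 20
  t1s <- grid_from_rows(c("ffffffffff", "ffffffffff", "ffffffffff",
                          "dddddddddd", "dddddddddd", "dddddddddd"))
  cs <- single_county(t1s)
  sts <- uniform_stack(t1s, 0.5)
  leds <- build_quota_ledgers(data.frame(county = "c1", donor = "f",
                                         target = "d", cells = 50L))
  rs <- allocate_all(t1s, cs, sts, leds, list(),
                     seeding_config(n = 4, seed = 2))
  expect_identical(unname(ledger_converted(leds$c1)["f->d"]), 30L)
  expect_identical(unname(leds$c1$shortfall["f->d"]), 20L)
  expect_identical(unname(ledger_converted(leds$c1) +
                            leds$c1$shortfall)[which(names(leds$c1$initial) == "f->d")],
                   50L)
})

test_that("allocation is deterministic and order-independent across counties", {
  land <- generate_landscape(shape = c(40, 40), county_grid = c(2, 2),
                             clumpiness = 0.6, seed = 23)
  t1 <- land$grid
  counties <- land$counties
  st <- uniform_stack(t1, 0.5)
  quotas <- generate_quotas(t1, counties, c("f->d" = 0.1, "a->d" = 0.05,
                                            "o->a" = 0.1))
  cfg <- seeding_config(n = 16, seed = 31)

  run <- function(order) {
    ledgers <- build_quota_ledgers(quotas, counties = counties$county_ids)
    allocate_all(t1, counties, st, ledgers[order], list(), cfg)
  }
  ids <- counties$county_ids
  a <- run(ids)
  b <- run(rev(ids))
  c2 <- run(sample(ids))
  expect_identical(a$t2$values, b$t2$values)
  expect_identical(a$t2$values, c2$t2$values)

  # quotas only in one county leave the others bit-identical
  q1 <- quotas[quotas$county == ids[1], ]
  ledgers1 <- build_quota_ledgers(q1, counties = ids)
  r1 <- allocate_all(t1, counties, st, ledgers1, list(), cfg)
  other <- counties$labels != ids[1]
  expect_identical(r1$t2$values[other], t1$values[other])

  # Developed and Water cells never change class
  frozen <- t1$values %in% class_code(c("d", "w"))
  expect_identical(a$t2$values[frozen], t1$values[frozen])
})

test_that("adding a constant to all probabilities never changes the outcome", {
  land <- generate_landscape(shape = c(30, 30), county_grid = c(1, 1),
                             clumpiness = 0.5, seed = 41)
  t1 <- land$grid
  counties <- land$counties
  set.seed(43)
  base <- matrix(runif(900, 0.2, 0.6), 30, 30)
  mk_stack <- function(shift) {
    probability_stack(list("f->d" = base + shift,
                           "a->d" = base + shift,
                           "o->d" = base + shift), t1)
  }
  quotas <- generate_quotas(t1, counties, c("f->d" = 0.15, "a->d" = 0.1))
  pm <- list()  # fallback size-1 patches keep k fixed across runs
  run <- function(shift) {
    ledgers <- build_quota_ledgers(quotas, counties = counties$county_ids)
    allocate_all(t1, counties, mk_stack(shift), ledgers, pm,
                 seeding_config(n = 12, seed = 7))$t2$values
  }
  expect_identical(run(0), run(0.3))
})
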