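make_cluster_features <- function() {
  # two well-separated county archetypes: forested uplands vs developed plains
  set.seed(11)
  a <- data.frame(frac_f = rnorm(8, 0.8, 0.02), elev = rnorm(8, 900, 20),
                  pop = rnorm(8, 1e4, 500))
  b <- data.frame(frac_f = rnorm(8, 0.1, 0.02), elev = rnorm(8, 50, 20),
                  pop = rnorm(8, 5e5, 1e4))
  cbind(county = sprintf("c%02d", 1:16), rbind(a, b))
}

test_that("county clustering recovers separated groups and respects k", {
  feats <- make_cluster_features()
  one <- cluster_counties(feats, k = 1)
  expect_length(unique(one), 1L)

  two <- cluster_counties(feats, k = 2, seed = 3)
  expect_length(unique(two), 2L)
  # partition matches the generating clusters
  expect_length(unique(two[1:8]), 1L)
  expect_length(unique(two[9:16]), 1L)
  expect_false(two[1] == two[9])
  # deterministic under a fixed seed
  expect_identical(two, cluster_counties(feats, k = 2, seed = 3))

  ten <- cluster_counties(feats, k = 10, seed = 3)
  expect_length(unique(ten), 10L)
  expect_error(cluster_counties(feats, k = 17), "exceeds")
})

make_pair_with_transitions <- function(nr = 40, nc = 40, n_fd = 1000,
                                       n_oa = 12, seed = 5) {
  set.seed(seed)
  v1 <- matrix(class_code("f"), nr, nc)
  v1[1:10, ] <- class_code("o")
  v2 <- v1
  fcells <- which(v1 == class_code("f"))
  v2[sample(fcells, n_fd)] <- class_code("d")
  ocells <- which(v1 == class_code("o"))
  v2[sample(ocells, n_oa)] <- class_code("a")
  t1 <- lu_grid(v1)
  list(t1 = t1, t2 = lu_grid(v2), counties = single_county(t1),
       predictors = list(idx = matrix(seq_len(nr * nc), nr, nc)))
}

test_that("training samples cap at availability and census correctly", {
  px <- make_pair_with_transitions()
  s <- assemble_training_sample(px$t1, px$t2, px$predictors, px$counties,
                                "g1", per_label = 500, seed = 2)
  expect_identical(sum(s$label == "f->d"), 500L)
  expect_identical(sum(s$label == "o->a"), 12L)  # capped by availability
  # the idx predictor carries cell identity: recount each row's label from
  # the two grids and compare with the sample's labels
  recount <- transition_key(class_label(px$t1$values[s$idx]),
                            class_label(px$t2$values[s$idx]))
  expect_identical(as.character(s$label), recount)
  expect_false(anyDuplicated(s$idx) > 0)  # without replacement
  # Developed and Water never donate, so no d->* or w->* labels
  expect_false(any(grepl("^[dw]->", levels(s$label))))
})

test_that("the classifier adapter reports sane out-of-bag errors", {
  # perfectly separable labels: disjoint predictor supports
  set.seed(8)
  sep <- data.frame(
    label = factor(rep(c("f->d", "f->f"), each = 300)),
    x1 = c(rnorm(300, -8), rnorm(300, 8)),
    x2 = c(rnorm(300, 5), rnorm(300, -5)))
  m <- fit_grouping_model(sep, ntree = 150, seed = 1)
  expect_lt(m$oob_error, 0.05)

  # labels independent of predictors: error near 1 - 1/L
  set.seed(9)
  noise <- data.frame(label = factor(sample(c("f->d", "f->a", "f->f"),
                                            900, replace = TRUE)),
                      x1 = rnorm(900), x2 = rnorm(900))
  mn <- fit_grouping_model(noise, ntree = 150, seed = 1)
  expect_lt(abs(mn$oob_error - 2 / 3), 0.10)

  expect_error(fit_grouping_model(data.frame(label = factor(rep("f->d", 5)),
                                             x = 1:5)),
               "degenerate")

  p <- predict_grouping_model(m, data.frame(x1 = rnorm(20), x2 = rnorm(20)))
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-9)
})

test_that("probability stacks mask donors and collapse correctly", {
  t1 <- grid_from_rows(c("fa", "dw"))
  layers <- list(
    "f->d" = matrix(c(0.2, 0.9, 0.9, 0.9), 2, 2),
    "f->f" = matrix(0.7, 2, 2),
    "f->a" = matrix(0.1, 2, 2),
    "a->d" = matrix(0.4, 2, 2))
  st <- probability_stack(layers, t1)
  # donor masking: f layers are zero off the single forest cell (1,1)
  expect_equal(st$probs[["f->d"]][1, 1], 0.2)
  expect_equal(st$probs[["f->d"]][2, 1], 0)  # a developed cell
  expect_equal(st$probs[["a->d"]][1, 2], 0.4)
  expect_equal(st$probs[["a->d"]][1, 1], 0)
  # collapse: generalized probability equals the cell's own-donor layer
  expect_equal(st$generalized[["d"]][1, 1], 0.2)
  expect_equal(st$generalized[["d"]][1, 2], 0.4)
  expect_equal(st$generalized[["a"]][1, 1], 0.1)
  # masking idempotence: rebuilding from the masked layers changes nothing
  st2 <- probability_stack(st$probs, t1)
  expect_identical(st2$probs, st$probs)
  expect_identical(st2$generalized, st$generalized)
  expect_error(probability_stack(list("d->f" = matrix(0, 2, 2)), t1),
               "disallowed")
})

make_informative_landscape <- function(seed = 21) {
  land <- generate_landscape(shape = c(50, 50), county_grid = c(1, 1),
                             mixture = c(d = 0.15, f = 0.55, a = 0.2,
                                         w = 0.02, o = 0.08),
                             clumpiness = 0.75, seed = seed)
  # conversion to Developed concentrates where percent Developed is high
  set.seed(seed + 1)
  v2 <- land$grid$values
  p_conv <- land$predictors$pct_d_3 / 100 * 0.9
  fcells <- which(v2 == class_code("f"))
  conv <- fcells[runif(length(fcells)) < p_conv[fcells]]
  v2[conv] <- class_code("d")
  list(land = land, t2 = lu_grid(v2))
}

test_that("predicted development probability tracks an informative predictor", {
  ml <- make_informative_landscape()
  land <- ml$land
  s <- assemble_training_sample(land$grid, ml$t2, land$predictors,
                                land$counties, "g1", per_label = 400,
                                seed = 3)
  mod <- fit_grouping_model(s, ntree = 150, seed = 4)
  st <- predict_probability_stack(list(g1 = mod), land$grid,
                                  land$predictors, land$counties)
  fmask <- land$grid$values == class_code("f")
  pd3 <- land$predictors$pct_d_3[fmask]
  phat <- st$generalized[["d"]][fmask]
  top <- phat[pd3 >= quantile(pd3, 0.9)]
  bottom <- phat[pd3 <= quantile(pd3, 0.1)]
  expect_gt(mean(top), mean(bottom))

  # Developed cells never gain probability of leaving
  dmask <- land$grid$values == class_code("d")
  for (l in c("f", "a", "o", "w")) {
    expect_true(all(st$generalized[[l]][dmask] == 0))
  }

  # seeded determinism: identical inputs and seeds, bit-identical stacks
  mod2 <- fit_grouping_model(s, ntree = 150, seed = 4)
  st2 <- predict_probability_stack(list(g1 = mod2), land$grid,
                                   land$predictors, land$counties)
  expect_identical(st2$generalized, st$generalized)

  # per-cell masked mass never exceeds 1
  total <- Reduce(`+`, st$generalized)
  expect_true(all(total <= 1 + 1e-9))
})
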