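unit_square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)

test_that("delay embedding follows the Takens construction", {
  expect_equal(delay_embed(1:5, dim = 2, lag = 1),
               cbind(1:4, 2:5))
  expect_equal(delay_embed(c(3, 1, 4, 1, 5), dim = 3, lag = 2),
               matrix(c(3, 4, 5), 1))           # boundary: one point
  for (n in c(50, 256)) for (d in 2:4) for (lag in c(1, 5, 13)) {
    if (n > (d - 1) * lag) {
      expect_equal(nrow(delay_embed(rnorm(n), d, lag)), n - (d - 1) * lag)
    }
  }
  expect_error(delay_embed(1:4, dim = 3, lag = 2), "too short")
})

test_that("Rips degree-1 persistence matches brute-force reduction on small clouds", {
  for (cl in random_clouds()) {
    expect_diagrams_equal(rips_persistence_h1(cl), brute_rips_pairs(cl)$h1)
  }
  # degree 0 agrees as well
  cl <- random_clouds(seed = 3, sizes = 6, dims = 3, reps = 1)[[1]]
  expect_equal(sort(rips_persistence_h1(cl, degree = 0)$death),
               sort(brute_rips_pairs(cl)$h0$death))
})

test_that("canonical clouds give their known diagrams", {
  # three generic points never carry a 1-cycle
  set.seed(5)
  expect_equal(nrow(rips_persistence_h1(matrix(rnorm(6), 3, 2))), 0)
  # unit square: the loop closes at side length 1, dies at the diagonal
  d <- rips_persistence_h1(unit_square)
  expect_equal(nrow(d), 1)
  expect_equal(d$birth, 1)
  expect_equal(d$death, sqrt(2))
  # 20 points on the unit circle: birth is the chord between neighbours;
  # the full diagram matches brute force
  th <- 2 * pi * (0:19) / 20
  circ <- cbind(cos(th), sin(th))
  dc <- rips_persistence_h1(circ)
  expect_equal(dc$birth[which.max(dc$death - dc$birth)], 2 * sin(pi / 20))
  expect_diagrams_equal(dc, brute_rips_pairs(circ)$h1)
})

test_that("diagrams are isometry-invariant and scale-equivariant", {
  set.seed(17)
  cl <- delay_embed(rnorm(60), 3, 2)
  base <- rips_persistence_h1(cl)
  # rotation in the first two coordinates plus a translation
  ang <- 0.77
  rot <- diag(3); rot[1:2, 1:2] <- matrix(c(cos(ang), sin(ang),
                                            -sin(ang), cos(ang)), 2)
  moved <- sweep(cl %*% rot, 2, c(5, -3, 11), `+`)
  expect_diagrams_equal(rips_persistence_h1(moved), base, tol = 1e-9)
  for (c_scale in c(0.25, 3)) {
    scaled <- rips_persistence_h1(cl * c_scale)
    expect_equal(scaled$birth, base$birth * c_scale)
    expect_equal(scaled$death, base$death * c_scale)
    expect_equal(betti_area_exact(scaled),
                 betti_area_exact(base) * c_scale)
  }
})

test_that("deaths are capped at a user max_filtration", {
  d <- rips_persistence_h1(unit_square, max_filtration = 1.2)
  expect_equal(d$birth, 1)
  expect_equal(d$death, 1.2)   # still alive at the cap
  expect_equal(nrow(rips_persistence_h1(unit_square, max_filtration = 0.9)), 0)
})

test_that("Betti curve counts living pairs on the grid", {
  d <- rips_persistence_h1(unit_square)
  set.seed(2)
  empty <- rips_persistence_h1(matrix(rnorm(6), 3, 2))  # no degree-1 pairs
  expect_true(all(betti_curve(empty)$counts == 0))
  expect_equal(betti_area(betti_curve(empty)), 0)

  toy <- structure(data.frame(birth = c(0.5, 0.8), death = c(1.0, 1.2)),
                   class = c("persistence_diagram", "data.frame"),
                   degree = 1, max_filtration = 1.5)
  bc <- betti_curve(toy, grid_size = 601)
  expect_true(all(bc$counts[bc$grid >= 0.8 & bc$grid < 1.0] == 2))
  expect_true(all(bc$counts[bc$grid < 0.5 | bc$grid >= 1.2] == 0))
  expect_equal(betti_area(bc), 0.9, tolerance = 1.5 / 600 + 1e-9)

  one <- betti_curve(d, grid_size = 200)
  expect_true(all(one$counts %in% 0:1))
  expect_equal(betti_area(one), sqrt(2) - 1, tolerance = sqrt(2) / 199)
  expect_error(betti_curve(d, grid_size = 1), "grid_size")
})

test_that("grid area converges to total persistence", {
  set.seed(8)
  cl <- delay_embed(rnorm(120), 3, 3)
  d <- rips_persistence_h1(cl)
  exact <- betti_area_exact(d)
  err200 <- abs(betti_area(betti_curve(d, 200)) - exact)
  err4000 <- abs(betti_area(betti_curve(d, 4000)) - exact)
  expect_lt(err200, attr(d, "max_filtration") / 199 * max(betti_curve(d, 200)$counts))
  expect_lt(err4000, err200 + 1e-12)
})

test_that("window score sees a loop in a pure oscillation and is amplitude-invariant", {
  fs <- 128
  sine <- 50 * sin(2 * pi * 10 * (0:255) / fs)
  s <- tda_window_score(sine, fs)
  expect_gt(s, 0)
  # one dominant pair: the embedded loop
  emb <- delay_embed(as.vector(scale(sine)), 3, round(fs / 10))
  d <- rips_persistence_h1(emb)
  pers <- sort(d$death - d$birth, decreasing = TRUE)
  expect_gt(pers[1], 3 * max(pers[-1], 0))
  # z-scoring makes the score independent of amplitude
  expect_equal(tda_window_score(sine * 37, fs), s, tolerance = 1e-9)
  expect_error(tda_window_score(rep(1, 256), fs), "zero-variance")
})

test_that("noise and oscillation scores are reproducible fixtures", {
  set.seed(123)
  noise <- rnorm(256)
  expect_equal(tda_window_score(noise, 128), 10.241956, tolerance = 1e-5)
  sine <- 50 * sin(2 * pi * 10 * (0:255) / 128)
  expect_equal(tda_window_score(sine, 128), 1.175570, tolerance = 1e-5)
  # equal variance, very different topology
  expect_gt(tda_window_score(noise / stats::sd(noise), 128),
            tda_window_score(sine / stats::sd(sine), 128))
})

test_that("subsampling caps the cloud deterministically", {
  set.seed(31)
  x <- rnorm(2000)
  p_small <- utils::modifyList(bseeg_config()$tda, list(max_points = 100))
  s1 <- tda_window_score(x, 500, p_small)
  s2 <- tda_window_score(x, 500, p_small)
  expect_identical(s1, s2)
})

test_that("TDA aggregation is the median minus the centering offset", {
  expect_equal(aggregate_tda(c(0.1, 0.3, 0.2)), 0.2)
  p <- utils::modifyList(bseeg_config()$tda, list(center_offset = 0.2))
  expect_equal(aggregate_tda(c(0.1, 0.3, 0.2), p), 0)
  set.seed(77)
  v <- rexp(100)
  expect_equal(aggregate_tda(v), mean(sort(v)[50:51]))
  expect_warning(out <- aggregate_tda(numeric(0)), "no usable windows")
  expect_true(is.na(out))
})
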