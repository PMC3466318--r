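test_that("ordinal encoding maps categories and passes metric through", {
  scheme <- list(level = c(low = 1, high = 2), count = "metric")
  raw <- data.frame(species_id = c("s1", "s2", "s3"),
                    level = c("low", "high", "low"),
                    count = c(4.5, 2, 7), stringsAsFactors = FALSE)
  enc <- ordinal_encode(raw, scheme)
  expect_equal(enc$level, c(1, 2, 1))
  expect_equal(enc$count, c(4.5, 2, 7))

  raw$level[2] <- "medium"
  expect_error(ordinal_encode(raw, scheme), "medium")

  raw$level <- c("low", NA, "high")
  enc2 <- ordinal_encode(raw, scheme)
  expect_true(is.na(enc2$level[2]))
})

test_that("packaged example coding scheme loads and encodes", {
  scheme <- read_coding_scheme(system.file("extdata",
                                           "eco_coding_example.tsv",
                                           package = "archevo"))
  expect_length(scheme, 11)
  expect_identical(scheme$TPKNRP, "metric")
  expect_equal(unname(scheme$HostDep["obligate-host"]), 3)
})

test_that("spearman coefficient and exact permutation p-value", {
  s <- spearman_rho(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$r_s, 0.8)  # 1 - 6*4/(5*24)
  expect_equal(s$method, "exact")

  # monotone invariance: any strictly increasing transform leaves r_s at 1
  x <- c(0.3, 1.2, 2.9, 3.3, 5.5, 8, 13)
  for (f in list(function(v) v^3, exp, function(v) log(v + 1))) {
    expect_equal(spearman_rho(x, f(x))$r_s, 1)
  }

  # exact p equals full enumeration, with and without ties
  set.seed(5)
  for (rep in 1:4) {
    x6 <- sample(1:4, 6, replace = TRUE)  # forces ties
    y6 <- rnorm(6)
    if (sd(rank(x6)) == 0) next
    expect_equal(spearman_rho(x6, y6)$p, oracle_spearman_exact_p(x6, y6))
  }

  # agreement with cor.test's exact p when there are no ties
  set.seed(9)
  x8 <- rnorm(8); y8 <- rnorm(8)
  ct <- cor.test(x8, y8, method = "spearman", exact = TRUE)
  expect_equal(spearman_rho(x8, y8)$p, unname(ct$p.value), tolerance = 1e-12)

  # large-sample t approximation
  set.seed(10)
  x30 <- rnorm(30); y30 <- x30 + rnorm(30)
  s30 <- spearman_rho(x30, y30)
  expect_equal(s30$method, "t")
  ct30 <- cor.test(x30, y30, method = "spearman", exact = FALSE)
  expect_equal(s30$p, unname(ct30$p.value), tolerance = 1e-10)

  expect_true(spearman_rho(c(1, 1, 1, 1), 1:4)$degenerate)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("eta coefficient matches hand-computed sums of squares", {
  expect_equal(eta_coefficient(c("A", "A", "B", "B"), c(1, 2, 4, 6))$eta,
               sqrt(12.25 / 14.75))
  # all group means equal -> 0
  expect_equal(eta_coefficient(c("A", "A", "B", "B"), c(1, 3, 2, 2))$eta, 0)
  # constant within groups, different means -> 1
  expect_equal(eta_coefficient(c("A", "A", "B", "B"), c(5, 5, 9, 9))$eta, 1)
  # direction matters: grouping by y values against x gives a different value
  g <- c("A", "A", "B", "B"); y <- c(1, 2, 4, 6)
  expect_false(isTRUE(all.equal(eta_coefficient(g, y)$eta,
                                eta_coefficient(y, as.numeric(factor(g)))$eta)))
  expect_true(eta_coefficient(g, c(2, 2, 2, 2))$degenerate)
  expect_error(eta_coefficient(c("A", "A"), 1:2), "2 non-empty groups")
})

test_that("fisher-z power equals alpha at r = 0 and matches quadrature", {
  expect_equal(fisher_z_power(0, 53, 0.05), 0.05)
  expect_equal(fisher_z_power(0, 20, 0.10), 0.10)
  expect_equal(fisher_z_power(1, 10), 1)

  # strictly increasing in n for fixed r > 0
  pw <- vapply(5:60, function(n) fisher_z_power(0.4, n), numeric(1))
  expect_true(all(diff(pw) > 0))

  # quadrature oracle: integrate the normal density over the rejection region
  r <- 0.5; n <- 53; alpha <- 0.05
  z <- atanh(r); q <- qnorm(1 - alpha / 2); mu <- z * sqrt(n - 3)
  upper <- integrate(function(t) dnorm(t, mean = mu), lower = q,
                     upper = Inf, rel.tol = 1e-12)$value
  lower <- integrate(function(t) dnorm(t, mean = mu), lower = -Inf,
                     upper = -q, rel.tol = 1e-12)$value
  expect_equal(fisher_z_power(r, n, alpha), upper + lower, tolerance = 1e-10)
})

test_that("least-squares regression matches the normal equations", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5, 3)  # intercept last-free ordering below
  y <- beta[1] + X %*% beta[2:4] + rnorm(20, sd = 0.3)
  fit <- ols_regression(drop(y), X)
  M <- cbind(1, X)
  beta_hat <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta_hat)),
               tolerance = 1e-8)
  # residuals orthogonal to every column of the design
  expect_lt(max(abs(t(M) %*% fit$residuals)), 1e-8)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # exact linear response: zero residuals, unit R^2
  y_exact <- drop(1 + X %*% c(1, 2, 3))
  fit2 <- suppressWarnings(ols_regression(y_exact, X))  # "perfect fit" note
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1)

  # intercept-only model returns the mean
  fit3 <- ols_regression(c(2, 4, 6, 9), matrix(numeric(0), nrow = 4, ncol = 0))
  expect_equal(unname(fit3$coefficients), mean(c(2, 4, 6, 9)))

  Xdup <- cbind(X, d = X[, 1] * 2)
  expect_error(ols_regression(drop(y), Xdup), "collinear")
})

test_that("correlation battery reports pairwise n and flags sparse cells", {
  sf <- data.frame(species_id = paste0("s", 1:10),
                   rec_luxr = c(1:10), luxr = c(10:1), other = rep(0L, 10),
                   total = c(1:10) + c(10:1))
  eco <- data.frame(species_id = paste0("s", 1:10),
                    ranks = 1:10,
                    sparse = c(1, 2, rep(NA, 8)))
  b <- correlation_battery(sf, eco)
  cell <- b[b$subfamily == "rec_luxr" & b$variable == "ranks", ]
  expect_equal(cell$r_s, 1)
  expect_equal(cell$n, 10)
  sparse <- b[b$subfamily == "rec_luxr" & b$variable == "sparse", ]
  expect_equal(sparse$n, 2)
  expect_true(is.na(sparse$r_s))
  # zero-variance response: degenerate, not an error
  other <- b[b$subfamily == "other" & b$variable == "ranks", ]
  expect_true(is.na(other$r_s))
})

test_that("battery recovers a planted link and stays null when decoupled", {
  hits_pos <- 0; n_seeds <- 20
  for (s in 1:n_seeds) {
    w <- simulate_world(sim_config(seed = 4000 + s))
    sf <- census_subfamilies(w$census)
    b <- correlation_battery(sf, w$eco)
    cell <- b[b$subfamily == "total" & b$variable == "planted", ]
    if (!is.na(cell$r_s) && cell$r_s > 0 && cell$p < 0.05) {
      hits_pos <- hits_pos + 1
    }
  }
  expect_gte(hits_pos / n_seeds, 0.9)
})
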