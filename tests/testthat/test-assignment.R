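# Whole-fragment alignment scoring, null moments, extreme-value p-values,
# register assignment.

test_that("alignment scores are sums of log probabilities", {
  p <- matrix(1 / 20, 2, 20, dimnames = list(NULL, aa_alphabet()))
  p[1, "A"] <- 0.5
  p[2, "G"] <- 0.25
  expect_equal(score_alignment(p, "AG"), log(0.5) + log(0.25))
  expect_equal(score_alignment(p, "AG"), log(0.125))
  # perfect probabilities give score 0
  p1 <- matrix(1e-9, 3, 20, dimnames = list(NULL, aa_alphabet()))
  p1[cbind(1:3, match(c("M", "K", "V"), aa_alphabet()))] <- 1
  expect_equal(score_alignment(p1, "MKV"), 0)
  # 'X' contributes the background wildcard log(1/20)
  expect_equal(score_alignment(p, "AX"), log(0.5) + log(1 / 20))
  expect_error(score_alignment(p, "AGA"), class = "shape_mismatch")
})

test_that("null moments match hand arithmetic and Monte-Carlo moments", {
  # L = 1 hand case
  p <- matrix(1e-6, 1, 20, dimnames = list(NULL, aa_alphabet()))
  p[1, "A"] <- 0.9; p[1, "G"] <- 0.1
  q <- rep(0, 20); names(q) <- aa_alphabet()
  q[c("A", "G")] <- 0.5
  nm <- null_moments(p, q)
  mu_hand <- 0.5 * log(0.9) + 0.5 * log(0.1)
  var_hand <- 0.5 * log(0.9)^2 + 0.5 * log(0.1)^2 - mu_hand^2
  expect_equal(nm$mu, mu_hand, tolerance = 1e-12)
  expect_equal(nm$sigma, sqrt(var_hand), tolerance = 1e-12)
  # uniform profile: sigma degenerates, mu = L log(1/20)
  pu <- matrix(1 / 20, 7, 20)
  nmu <- null_moments(pu, rep(1 / 20, 20))
  expect_true(nmu$degenerate)
  expect_equal(nmu$mu, 7 * log(1 / 20))
  # Monte-Carlo agreement within 1%
  set.seed(30)
  L <- 12
  pm <- random_profile(L, concentration = 1)
  qv <- rep(1 / 20, 20)
  nm2 <- null_moments(pm, qv)
  lp <- log(pm)
  sc <- replicate(1e5, sum(lp[cbind(seq_len(L),
                                    sample.int(20, L, replace = TRUE))]))
  expect_equal(nm2$mu, mean(sc), tolerance = 0.01)
  expect_equal(nm2$sigma, sd(sc), tolerance = 0.01)
})

test_that("best_alignment equals brute-force enumeration", {
  set.seed(31)
  brute <- function(p, target) {
    tl <- strsplit(target, "")[[1]]
    L <- nrow(p); M <- length(tl)
    sc <- vapply(0:(M - L), function(o)
      sum(vapply(seq_len(L), function(i)
        log(p[i, match(tl[o + i], aa_alphabet())]), numeric(1))), numeric(1))
    list(offset = which.max(sc) - 1L, score = max(sc))
  }
  for (rep in 1:60) {
    L <- sample(2:20, 1); M <- sample(L:200, 1)
    p <- random_profile(L, concentration = 1)
    target <- random_target(M)
    ba <- best_alignment(p, target)
    bf <- brute(p, target)
    expect_identical(ba$offset, bf$offset)
    expect_equal(ba$score, bf$score, tolerance = 1e-9)
    expect_equal(ba$n_alignments, M - L + 1L)
  }
  # L = M: single alignment
  p <- random_profile(6)
  t6 <- random_target(6)
  expect_equal(best_alignment(p, t6)$n_alignments, 1L)
  expect_error(best_alignment(random_profile(10), t6), class = "no_alignment")
})

test_that("planted sub-profile is recovered at its true offset", {
  set.seed(32)
  target <- random_target(60)
  tl <- strsplit(target, "")[[1]]
  L <- 20
  p <- matrix(1e-9, L, 20)
  p[cbind(seq_len(L), match(tl[11:30], aa_alphabet()))] <- 1
  ba <- best_alignment(p, target)
  expect_equal(ba$offset, 10L)
  zs <- (ba$scores - ba$moments$mu) / ba$moments$sigma
  expect_equal(which.max(zs) - 1L, 10L)
})

test_that("extreme-value p-values: analytic limits and simulation agreement", {
  expect_equal(extreme_value_p(0, 1, 1), 0.5)
  expect_lt(extreme_value_p(20, 100, 10), 1e-15)
  expect_gt(extreme_value_p(-15, 100, 10), 1 - 1e-10)
  expect_equal(extreme_value_p(NA, 50, 10), 1)   # degenerate null
  # the redundancy correction shrinks the effective trial count, so the same
  # Z-score becomes more significant: p is monotone increasing in n_eff
  z <- 2.5
  p1 <- extreme_value_p(z, 200, 1)
  p10 <- extreme_value_p(z, 200, 10)
  expect_lt(p10, p1)
  expect_gt(extreme_value_p(z, 200, 10), extreme_value_p(z, 20, 10))
  # agreement with max-of-n-normals simulation within 20% relative
  set.seed(33)
  for (n in c(2, 10, 50)) {
    zmax <- apply(matrix(rnorm(5e4 * n), ncol = n), 1, max)
    for (ptarget in c(0.4, 0.1, 0.02)) {
      zq <- quantile(zmax, 1 - ptarget)
      p_emp <- mean(zmax >= zq)
      p_form <- extreme_value_p(zq, n, 1)
      expect_lt(abs(p_form - p_emp) / p_emp, 0.2)
    }
  }
})

test_that("uniform profiles yield p = 1 and no assignment", {
  prof <- probability_profile(matrix(1 / 20, 8, 20),
                              data.frame(fragment = rep("u", 8)))
  res <- assign_model(prof, random_target(40))
  expect_true(all(res$results$p_value == 1))
  expect_true(all(is.na(res$assigned$u)))
})

test_that("disjoint assignments do not conflict; overlapping ones do", {
  set.seed(34)
  target <- random_target(60)
  tl <- strsplit(target, "")[[1]]
  sharp <- function(idx) {
    p <- matrix(1e-9, length(idx), 20)
    p[cbind(seq_along(idx), match(tl[idx], aa_alphabet()))] <- 1
    p <- pmax(p, 1e-6); p / rowSums(p)
  }
  p_all <- rbind(sharp(1:20), sharp(31:45))
  prof <- probability_profile(p_all, data.frame(
    fragment = rep(c("f1", "f2"), c(20, 15))))
  res <- assign_model(prof, target)
  expect_equal(nrow(res$conflicts), 0)
  expect_equal(res$assigned$f1, tl[1:20])
  expect_equal(res$assigned$f2, tl[31:45])
  # two fragments claiming the same region conflict
  p_ovl <- rbind(sharp(1:20), sharp(10:25))
  prof2 <- probability_profile(p_ovl, data.frame(
    fragment = rep(c("a", "b"), c(20, 16))))
  res2 <- assign_model(prof2, target)
  expect_equal(nrow(res2$conflicts), 1)
})

test_that("all-too-long fragments raise a no-alignment error", {
  prof <- probability_profile(random_profile(30),
                              data.frame(fragment = rep("f", 30)))
  expect_error(assign_model(prof, random_target(10)), class = "no_alignment")
})
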