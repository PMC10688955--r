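test_that("the closed-form structure count matches exhaustive enumeration", {
  expect_equal(count_structures(7, 3), 12288)
  expect_equal(count_structures(0, 0), 3)
  expect_equal(count_structures(2, 1), 27)
  st <- enumerate_structures(factor_specs()$name, 3)
  expect_equal(nrow(st), 12288)
  key <- paste(st$sa_parents, st$scr_parents, st$edge)
  expect_equal(anyDuplicated(key), 0)
  sizes <- function(s) ifelse(s == "(none)", 0, lengths(strsplit(s, ",")))
  expect_true(all(sizes(st$sa_parents) <= 3))
  expect_true(all(sizes(st$scr_parents) <= 3))
})

test_that("enumeration agrees with a brute-force filter of the unconstrained space", {
  fac <- c("A", "B", "C", "D")
  st <- enumerate_structures(fac, 3)
  expect_equal(nrow(st), count_structures(4, 3))
  # independent oracle: every bitmask pair over 4 factors, filtered by size
  all_sets <- lapply(0:15, function(m) fac[bitwAnd(m, 2^(0:3)) > 0])
  ok <- vapply(all_sets, length, integer(1)) <= 3
  brute <- expand.grid(sa = which(ok), scr = which(ok),
                       edge = c("none", "sa_to_scr", "scr_to_sa"))
  expect_equal(nrow(st), nrow(brute))
  lab <- function(s) if (length(s) == 0) "(none)" else paste(sort(s), collapse = ",")
  brute_keys <- sort(paste(
    vapply(all_sets[brute$sa], lab, character(1)),
    vapply(all_sets[brute$scr], lab, character(1)), brute$edge))
  st_keys <- sort(paste(
    vapply(strsplit(st$sa_parents, ","), function(x) lab(x[x != "(none)"]), character(1)),
    vapply(strsplit(st$scr_parents, ","), function(x) lab(x[x != "(none)"]), character(1)),
    st$edge))
  expect_equal(st_keys, brute_keys)
})

test_that("Raftery grades map BIC differences with closed right boundaries", {
  expect_equal(raftery_grade(c(0, 2)), c("Weak", "Weak"))
  expect_equal(raftery_grade(c(2.0001, 4.6, 6)), c("Positive", "Positive", "Positive"))
  expect_equal(raftery_grade(c(6.0001, 10)), c("Strong", "Strong"))
  expect_equal(raftery_grade(c(10.0001, 10.5, 100)), rep("Very Strong", 3))
  expect_error(raftery_grade(-0.5), "non-negative")
})

small_model_data <- function(seed, n_participants = 4) {
  tab <- apply_transforms(simulate_indicator_table(n_participants = n_participants,
                                                   seed = seed))
  tab[!tab$is_collision, ]
}

test_that("the empty structure decomposes into intercept-only node fits plus the factor constant", {
  md <- small_model_data(101)
  n <- nrow(md)
  cache <- new.env(parent = emptyenv())
  empty <- list(sa_parents = "(none)", scr_parents = "(none)", edge = "none")
  bic <- score_network(empty, md, "dynamics", cache)
  g <- riskbn:::gaussian_family_fit(md$iSA, NULL)
  tw <- tw_fit_glm(md$nSCR, matrix(1, n, 1))
  expect_equal(bic,
               (-2 * g$loglik + 2 * log(n)) + (-2 * tw$loglik + 3 * log(n)) +
                 2 * n * 7 * log(2),
               tolerance = 1e-8)
})

test_that("cached-family totals equal the monolithic joint-likelihood BIC", {
  md <- small_model_data(103)
  cache <- new.env(parent = emptyenv())
  st <- enumerate_structures(factor_specs()$name, 2)
  set.seed(42)
  pick <- sample(nrow(st), 12)
  for (i in pick) {
    s <- as.list(st[i, c("sa_parents", "scr_parents", "edge")])
    bic_fast <- score_network(s, md, "dynamics", cache)
    bic_slow <- monolithic_bic(s, md, "dynamics", cache)
    expect_equal(bic_fast, bic_slow, tolerance = 1e-8)
  }
})

test_that("a parent with no planted effect is penalised in most replicates", {
  worse <- 0
  for (r in 1:8) {
    md <- small_model_data(110 + r)
    cache <- new.env(parent = emptyenv())
    base <- score_network(list(sa_parents = "Order,Margin", scr_parents = "(none)",
                               edge = "sa_to_scr"), md, "dynamics", cache)
    extra <- score_network(list(sa_parents = "Order,Margin", scr_parents = "Side",
                                edge = "sa_to_scr"), md, "dynamics", cache)
    if (extra > base) worse <- worse + 1
  }
  expect_gte(worse, 6)
})

test_that("the search ranking is exhaustive, sorted, and invariant to row permutation", {
  md <- small_model_data(121, n_participants = 3)
  s1 <- search_networks(md, "dynamics", max_parents = 1,
                        p_grid = c(1.3, 1.5, 1.7))
  expect_equal(nrow(s1$ranking), count_structures(7, 1))
  expect_true(!is.unsorted(s1$ranking$bic))
  expect_equal(s1$ranking$delta_bic[1], 0)
  expect_equal(s1$ranking$grade[1], "Weak")
  set.seed(7)
  md2 <- md[sample(nrow(md)), ]
  s2 <- search_networks(md2, "dynamics", max_parents = 1,
                        p_grid = c(1.3, 1.5, 1.7))
  expect_equal(s2$ranking$bic, s1$ranking$bic, tolerance = 1e-6)
  expect_equal(s2$best, s1$best)
})

test_that("missing indicator values are rejected", {
  md <- small_model_data(131, n_participants = 3)
  md$iSA[5] <- NA
  expect_error(search_networks(md, "dynamics"), "missing")
})
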