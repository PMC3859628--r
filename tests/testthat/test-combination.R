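random_mass <- function() {
  x <- stats::rexp(3)
  x <- x / sum(x)
  mass_function(x[1], x[2], x[3])
}

test_that("mass functions must be non-negative and normalized", {
  m <- mass_function(0.4, 0.1, 0.5)
  expect_equal(m$m_a + m$m_nota + m$m_omega, 1)
  expect_error(mass_function(0.6, 0.6, 0.6), class = "adrsub_validation_error")
  expect_error(mass_function(-0.1, 0.5, 0.6), class = "adrsub_validation_error")
})

test_that("score-to-mass mappings behave as specified", {
  expect_equal(mass_from_score(0, 1)$m_omega, 1)           # vacuous
  expect_equal(mass_from_score(1, 1)$m_a, 1)               # categorical
  m <- mass_from_score(0.5, 0.8)
  expect_equal(m$m_a, 0.4)
  expect_equal(m$m_omega, 0.6)
  m2 <- mass_from_score(0.25, 0.8, "two_sided")
  expect_equal(m2$m_a, 0.2)
  expect_equal(m2$m_nota, 0.6)
  expect_equal(m2$m_omega, 0.2)
  expect_error(mass_from_score(0.5, 1.5), class = "adrsub_config_error")
})

test_that("Dempster combination: identity, worked example, total conflict", {
  set.seed(606)
  m <- random_mass()
  vac <- mass_function(0, 0, 1)
  expect_equal(dempster_combine(m, vac), m, tolerance = 1e-12)

  c12 <- dempster_combine(mass_from_score(0.6), mass_from_score(0.5))
  expect_equal(c12$m_a, 0.8, tolerance = 1e-12)
  expect_equal(c12$m_omega, 0.2, tolerance = 1e-12)

  expect_error(dempster_combine(mass_function(1, 0, 0),
                                mass_function(0, 1, 0)),
               class = "adrsub_conflict_error")
})

test_that("combined masses stay normalized over many random draws (property)", {
  set.seed(707)
  for (i in 1:10000) {
    m <- dempster_combine(random_mass(), random_mass())
    expect_true(abs(m$m_a + m$m_nota + m$m_omega - 1) <= 1e-9)
    expect_true(min(m$m_a, m$m_nota, m$m_omega) >= 0)
  }
})

test_that("combination is commutative and associative within tolerance", {
  set.seed(808)
  for (i in 1:200) {
    m1 <- random_mass(); m2 <- random_mass(); m3 <- random_mass()
    ab <- dempster_combine(m1, m2)
    ba <- dempster_combine(m2, m1)
    expect_equal(ab, ba, tolerance = 1e-9)
    abc <- dempster_combine(ab, m3)
    a_bc <- dempster_combine(m1, dempster_combine(m2, m3))
    expect_equal(abc, a_bc, tolerance = 1e-9)
  }
})

test_that("one-sided fold matches the simple-support closed form 1 - prod(1 - a_i)", {
  set.seed(909)
  for (i in 1:200) {
    a <- stats::runif(sample(1:5, 1))
    scores <- stats::setNames(a, paste0("p", seq_along(a)))
    v <- combine_all(scores)
    expect_equal(v$belief, 1 - prod(1 - a), tolerance = 1e-9)
    expect_true(v$belief <= v$plausibility + 1e-12)
  }
})

test_that("increasing any one-sided score never decreases belief", {
  set.seed(1010)
  for (i in 1:100) {
    scores <- stats::setNames(stats::runif(3), c("a", "b", "c"))
    j <- sample(3, 1)
    bumped <- scores
    bumped[j] <- min(1, bumped[j] + stats::runif(1, 0, 1 - bumped[j]))
    expect_true(combine_all(bumped)$belief >=
                  combine_all(scores)$belief - 1e-12)
  }
})

test_that("worked verdicts: vacuous, absorbing certainty, three moderate scores", {
  v0 <- combine_all(c(literature = 0))
  expect_equal(v0$belief, 0)
  expect_equal(v0$plausibility, 1)
  expect_identical(v0$tier, "L")
  expect_identical(unname(v0$per_provider_flags), "N")

  v1 <- combine_all(c(literature = 1, cooccurrence = 0.5, targets = 1))
  expect_equal(v1$belief, 1)
  expect_identical(v1$tier, "H")

  v2 <- combine_all(c(a = 0.5, b = 0.5, c = 0.5))
  expect_equal(v2$belief, 1 - 0.5^3)
  expect_identical(v2$tier, "H")
})

test_that("belief classification honors thresholds with inclusive boundaries", {
  expect_identical(classify_belief(0), "L")
  expect_identical(classify_belief(1), "H")
  expect_identical(classify_belief(0.7), "H")
  expect_identical(classify_belief(0.3), "M")
  expect_identical(classify_belief(0.5, c(M = 0.2, H = 0.5)), "H")
  expect_error(classify_belief(0.5, c(M = 0.8, H = 0.2)),
               class = "adrsub_config_error")
})

test_that("combination order does not matter and weights discount evidence", {
  scores <- c(literature = 1, cooccurrence = 0.5, targets = 0.8)
  v_ab <- combine_all(scores)
  v_ba <- combine_all(rev(scores))
  expect_equal(v_ab$belief, v_ba$belief, tolerance = 1e-9)

  cfg <- combination_config(weights = c(literature = 0.5, cooccurrence = 0.5,
                                        targets = 0.5))
  expect_true(combine_all(scores, cfg)$belief < v_ab$belief)
  expect_warning(combine_all(c(literature = 1, unknown = 0.5),
                             combination_config(weights = c(literature = 1))),
                 "no weight configured")
})
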