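test_that("dihedral handles planar references and matches an independent routine", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)

  skip_if_not_installed("bio3d")
  withr::with_seed(101, {
    for (i in 1:50) {
      p <- matrix(rnorm(12, sd = 3), 4, 3)
      ref <- bio3d::torsion.xyz(as.vector(t(p)))
      expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                   as.numeric(ref), tolerance = 1e-9)
    }
  })
})

test_that("dihedral is antisymmetric under reversal only up to atom order", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- matrix(rnorm(12), 4, 3)
      fwd <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
      rev <- dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ])
      # the torsion value is invariant under full reversal of the atom path,
      # which is what makes chi3 well-defined from either sulfur
      expect_equal(fwd, rev, tolerance = 1e-9)
    }
  })
})

test_that("degenerate dihedral geometry errors instead of returning numbers", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedral_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               "degenerate")
})

test_that("measure_cystine recovers builder targets and relabels under side swap", {
  specs <- random_cystine_specs(100, seed = 21)
  for (s in specs[1:20]) {
    sides <- cystine_sides(s)
    g <- measure_cystine(sides$res1, sides$res2)
    expect_equal(c(g$chi1, g$chi2, g$chi3, g$chi2p, g$chi1p), s$chi,
                 tolerance = 1e-6)
    expect_equal(c(g$alpha1, g$alpha2), s$alpha, tolerance = 1e-6)
    expect_equal(g$d, s$d, tolerance = 1e-6)

    gs <- measure_cystine(sides$res2, sides$res1)
    expect_equal(c(gs$chi1, gs$chi2, gs$chi3, gs$chi2p, gs$chi1p),
                 c(g$chi1p, g$chi2p, g$chi3, g$chi2, g$chi1), tolerance = 1e-9)
    expect_equal(c(gs$alpha1, gs$alpha2), c(g$alpha2, g$alpha1), tolerance = 1e-9)
    expect_equal(gs$d, g$d, tolerance = 1e-12)
    expect_equal(gs$dse, g$dse, tolerance = 1e-9)
  }
})

test_that("the equilibrium S-S target is reproduced exactly", {
  sides <- cystine_sides(cystine_spec(d = 2.038))
  expect_equal(measure_cystine(sides$res1, sides$res2)$d, 2.038,
               tolerance = 1e-6)
})

test_that("missing required atoms raise an error naming the atom", {
  sides <- cystine_sides(cystine_spec())
  r1 <- sides$res1[sides$res1$name != "SG", ]
  expect_error(measure_cystine(r1, sides$res2), "SG")
  r2 <- sides$res2[!(sides$res2$name %in% c("N", "CB")), ]
  expect_error(measure_cystine(sides$res1, r2), "N, CB")
})

test_that("dse reproduces hand-evaluated oracle values", {
  # all 3-fold cosines at -1, 2-fold chi3 cosine at -1, 3-fold chi3 cosine 0
  expect_equal(dse(-60, -60, -90, -60, -60), 2.51)
  # only the 2-fold chi3 term survives at all-trans
  expect_equal(dse(180, 180, 180, 180, 180), 29.28)
  # every cosine equals 1 at the eclipsed maximum
  expect_equal(dse(0, 0, 0, 0, 0), 84.5)
})

test_that("dse is invariant under side swap and 360-degree shifts", {
  withr::with_seed(5, {
    for (i in 1:50) {
      chi <- runif(5, -180, 180)
      expect_equal(dse(chi[1], chi[2], chi[3], chi[4], chi[5]),
                   dse(chi[5], chi[4], chi[3], chi[2], chi[1]),
                   tolerance = 1e-12)
      shift <- sample(c(-360, 0, 360), 5, replace = TRUE)
      expect_equal(dse(chi[1], chi[2], chi[3], chi[4], chi[5]),
                   dse(chi[1] + shift[1], chi[2] + shift[2], chi[3] + shift[3],
                       chi[4] + shift[4], chi[5] + shift[5]),
                   tolerance = 1e-9)
    }
  })
})

test_that("dse stays within [0, 84.5] over a 5-degree grid", {
  grid <- seq(-180, 180, by = 5)
  # the five angles act through separable terms, so scanning each term's
  # angle with the others at their minima bounds the full 5-d surface
  vals <- outer(grid, grid, function(a, b) dse(a, b, -90, -60, -60))
  expect_true(all(vals >= 0 - 1e-12))
  chi3_profile <- dse(-60, -60, grid, -60, -60)
  expect_true(all(chi3_profile >= 0 - 1e-12))
  expect_true(all(dse(grid, 0, 0, 0, 0) <= 84.5 + 1e-12))
  full_corner <- dse(0, 0, 0, 0, 0)
  expect_equal(full_corner, 84.5)
  expect_equal(dse(-60, -60, 90, -60, -60), 2.51) # |chi3| = 90 reference point
})

test_that("b-factor averaging follows the 12-atom contract", {
  sides <- cystine_sides(cystine_spec(b_factors = rep(20, 12)))
  expect_equal(b_factor_average(sides$res1, sides$res2)$b_avg, 20)

  sides <- cystine_sides(cystine_spec(b_factors = c(rep(10, 6), rep(30, 6))))
  expect_equal(b_factor_average(sides$res1, sides$res2)$b_avg, 20)

  sides <- cystine_sides(cystine_spec(b_factors = 1:12))
  expect_equal(b_factor_average(sides$res1, sides$res2)$b_avg, 6.5)

  # a missing atom degrades gracefully with a recorded deficit
  r1 <- sides$res1[sides$res1$name != "O", ]
  out <- b_factor_average(r1, sides$res2)
  expect_equal(out$n_missing, 1L)
  expect_equal(out$b_avg, mean(setdiff(1:12, 4)))
  expect_error(b_factor_average(sides$res1[0, ], sides$res2[0, ]), "no standard atoms")
})

test_that("secondary-structure assignment follows header ranges with helix precedence", {
  hel <- tibble::tibble(chain = "A", start_num = 10L, start_icode = "",
                        end_num = 20L, end_icode = "")
  sht <- tibble::tibble(chain = "A", start_num = 15L, start_icode = "",
                        end_num = 30L, end_icode = "")
  expect_equal(ss_state("A", 12, helices = hel, sheets = sht), "helix")
  expect_equal(ss_state("A", 25, helices = hel, sheets = sht), "strand")
  expect_equal(ss_state("A", 40, helices = hel, sheets = sht), "loop")
  expect_equal(ss_state("B", 12, helices = hel, sheets = sht), "loop")
  expect_equal(ss_state("A", 17, helices = hel, sheets = sht), "helix") # both declared
})
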