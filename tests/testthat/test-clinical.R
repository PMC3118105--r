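test_that("the packaged example cohort loads and round-trips", {
  path <- system.file("extdata", "cohort-example.csv", package = "crpsdystonia")
  co <- load_cohort(path)
  expect_equal(nrow(co), 3)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  expect_identical(load_cohort(tmp), co)
})

test_that("malformed records are rejected with row-numbered messages", {
  co <- fixture_cohort("arm")
  bad <- co
  bad$severity[2] <- "none"  # dystonic limb without a grade
  expect_error(validate_cohort(bad), "row 2")
  bad2 <- co
  bad2$fingers[5] <- "hyperextension"
  expect_error(validate_cohort(bad2), "row 5.*fingers")
  bad3 <- co
  bad3$toes[1] <- "plantar_flexion"  # leg joint on an arm record
  expect_error(validate_cohort(bad3), "NA")
  dup <- rbind(co, co[1, ])
  expect_error(validate_cohort(dup), "duplicate")
  # severity given with all joints "none"
  neutral <- co[1, ]
  for (j in c("fingers", "wrist", "elbow", "shoulder")) neutral[[j]] <- "none"
  expect_error(validate_cohort(rbind(co[-1, ], neutral)), "none")
})

test_that("combination tables count patterns, other-pattern and healthy limbs", {
  expect_equal(attr(combination_table(fixture_cohort("arm")[0, ], "arm"),
                    "grand_total"), 0)

  one <- fixture_cohort("arm")[1, ]
  one$fingers <- "flexion"; one$wrist <- "flexion"
  one$elbow <- "none"; one$shoulder <- "none"
  tab <- combination_table(one, "arm")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 1)
  expect_equal(unname(attr(tab, "column_totals")), c(1, 1, 0, 0))

  # a rare-posture-only limb is excluded but counted as other-pattern
  rare <- fixture_cohort("arm")[1:2, ]
  rare$fingers <- c("flexion", "extension")
  rare$wrist <- "none"; rare$elbow <- "none"; rare$shoulder <- "none"
  tab2 <- combination_table(rare, "arm")
  expect_equal(attr(tab2, "grand_total"), 1)
  expect_equal(attr(tab2, "other_pattern"), 1)
})

test_that("combination tables conserve limbs and marginals match a recount", {
  co <- generate_cohort(default_cohort_spec(n_patients = 300, seed = 5))
  for (limb in c("arm", "leg")) {
    tab <- combination_table(co, limb)
    n_type <- sum(co$limb == limb)
    expect_equal(attr(tab, "grand_total") + attr(tab, "other_pattern") +
                   attr(tab, "non_dystonic"), n_type)
    expect_equal(sum(tab$count), attr(tab, "grand_total"))
    # brute-force recount over raw records
    sub <- co[co$limb == limb, ]
    m <- marginal_counts(tab)
    if (limb == "arm") {
      expect_equal(unname(m$joints["fingers"]), sum(sub$fingers == "flexion"))
      expect_equal(unname(m$joints["shoulder"]), sum(sub$shoulder == "adduction"))
    } else {
      expect_equal(unname(m$joints["ankle"]),
                   sum(sub$ankle %in% c("plantar_flexion", "inversion",
                                        "plantar_flexion_inversion")))
      expect_equal(unname(m$joints["knee"]), sum(sub$knee == "flexion"))
    }
    expect_equal(sum(vapply(seq_len(nrow(tab)), function(i)
      sum(unlist(tab[i, 1:4])) * tab$count[i], numeric(1))),
      sum(unname(m$joints)))
  }
})

test_that("containment flags proximal involvement without distal involvement", {
  for (limb in c("arm", "leg"))
    expect_equal(nrow(proximal_distal_containment(fixture_cohort(limb), limb)), 0)
  expect_equal(nrow(proximal_distal_containment(fixture_cohort("arm")[0, ], "arm")), 0)

  bad <- fixture_cohort("arm")[1, ]
  bad$fingers <- "none"; bad$wrist <- "none"; bad$elbow <- "none"
  bad$shoulder <- "adduction"
  expect_equal(nrow(proximal_distal_containment(bad, "arm")), 1)
})

test_that("the symmetry test matches enumeration and is row-exchange invariant", {
  mk <- function(a, b, c, d) matrix(c(a, b, c, d), 2, byrow = TRUE)
  expect_equal(crpsdystonia:::fisher_p_2x2(mk(10, 10, 10, 10)), 1)
  # fully concordant table, frozen from the enumeration oracle:
  # p = 2 / choose(10, 5)
  expect_equal(crpsdystonia:::fisher_p_2x2(mk(5, 0, 0, 5)), 2 / choose(10, 5))
  expect_equal(crpsdystonia:::fisher_p_2x2(mk(5, 0, 0, 5)),
               fisher_oracle(mk(5, 0, 0, 5)))
  set.seed(11)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(crpsdystonia:::fisher_p_2x2(tb),
                 crpsdystonia:::fisher_p_2x2(tb[2:1, ]))
  }
  expect_warning(p <- crpsdystonia:::fisher_p_2x2(mk(0, 5, 0, 5)), "degenerate")
  expect_equal(p, 1)
})

test_that("lr_symmetry_test builds the side-by-dystonia table", {
  co <- generate_cohort(default_cohort_spec(n_patients = 200, seed = 9))
  res <- lr_symmetry_test(co, "arm")
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_equal(sum(res$table), sum(co$limb == "arm"))
  expect_equal(unname(rowSums(res$table)), c(200, 200))
})

test_that("severity summarises the most affected extremity per patient", {
  one <- fixture_cohort("arm")[1, ]
  one$severity <- "mild"
  s <- severity_summary(one)
  expect_equal(s$n[s$severity == "mild"], 1)
  expect_equal(sum(s$n), 1)

  # mild arm + severe leg counts once, as severe
  leg <- fixture_cohort("leg")[1, ]
  leg$patient_id <- one$patient_id
  leg$severity <- "severe"
  s2 <- severity_summary(rbind(one, leg))
  expect_equal(sum(s2$n), 1)
  expect_equal(s2$n[s2$severity == "severe"], 1)
})
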