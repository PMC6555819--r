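test_that("softmax PFM columns behave at the limits and match direct evaluation", {
  z_eq <- matrix(1.7, 4, 3, dimnames = list(BASES, NULL))
  expect_equal(unclass(pfm_from_zscores(z_eq, beta = 2)),
               matrix(0.25, 4, 3, dimnames = list(BASES, NULL)),
               ignore_attr = TRUE)

  withr::with_seed(70, z_any <- matrix(rnorm(4 * 5), 4, 5,
                                       dimnames = list(BASES, NULL)))
  expect_equal(unclass(pfm_from_zscores(z_any, beta = 0)),
               matrix(0.25, 4, 5, dimnames = list(BASES, NULL)),
               ignore_attr = TRUE)

  # z = (3,0,0,0), beta = 1 -> (e^3, 1, 1, 1)/(e^3 + 3)
  z <- matrix(c(3, 0, 0, 0), 4, 1, dimnames = list(BASES, NULL))
  f <- unclass(pfm_from_zscores(z, beta = 1))
  expect_equal(as.vector(f),
               c(exp(3), 1, 1, 1) / (exp(3) + 3), tolerance = 1e-12)
  expect_equal(as.vector(f)[1], 0.8700, tolerance = 1e-4)
  expect_equal(colSums(unclass(pfm_from_zscores(z_any, 0.7))),
               rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the softmax transform is shift-invariant per position", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      z <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(BASES, NULL))
      shift <- matrix(rep(rnorm(6), each = 4), 4, 6)
      b <- runif(1, 0.1, 3)
      expect_equal(unclass(pfm_from_zscores(z + shift, b)),
                   unclass(pfm_from_zscores(z, b)), tolerance = 1e-12)
    }
  })
})

test_that("beta defaults to 15 / maximum z-score and rejects non-positive maxima", {
  expect_equal(beta_param(30), 0.5)
  expect_equal(beta_param(7.5, numerator = 15), 2)
  expect_error(beta_param(0), "positive")
  expect_error(beta_param(-3), "positive")
})

test_that("PWM formulas match the printed pseudocount formalism", {
  b_gen <- dnase_background()
  expect_equal(unname(b_gen[c("A", "T", "C", "G")]),
               c(0.24, 0.24, 0.26, 0.26))

  # a column equal to the background maps to all-zero log-odds
  f_bg <- matrix(b_gen, 4, 2, dimnames = list(BASES, NULL))
  S <- pwm_from_pfm(structure(f_bg, class = "pfm"), background = b_gen)
  expect_equal(max(abs(unclass(S))), 0, tolerance = 1e-12)

  # extreme columns evaluated by independent arithmetic: f = (1,0,0,0)
  f1 <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(BASES, NULL))
  s <- 0.001
  S1 <- pwm_from_pfm(structure(f1, class = "pfm"), background = b_gen, s = s)
  p_manual <- (c(1, 0, 0, 0) + s * b_gen) / (1 + s)
  expect_equal(as.vector(unclass(S1)), as.vector(log2(p_manual / b_gen)),
               tolerance = 1e-12)
  # f_A = 0 cell with the printed background
  expect_equal(unclass(S1)["C", 1], log2((s * 0.26 / (1 + s)) / 0.26),
               tolerance = 1e-12, ignore_attr = TRUE)

  # round trip: 2^S * b recovers p
  withr::with_seed(72, fr <- random_pfm(7))
  Sr <- pwm_from_pfm(fr, background = b_gen)
  expect_equal(sweep(2^unclass(Sr), 1, b_gen, "*"),
               attr(Sr, "prob"), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(pwm_from_pfm(fr, background = c(A = 1, C = 0, G = 0, T = 0)),
               "positive")
  expect_error(pwm_from_pfm(fr, background = b_gen, s = 0), "> 0")
})

test_that("PFM averaging is the element mean with renormalized columns", {
  withr::with_seed(73, {
    p1 <- random_pfm(4)
    expect_equal(unclass(average_pfms(list(p1, p1, p1))), unclass(p1),
                 tolerance = 1e-12, ignore_attr = TRUE)
    p2 <- random_pfm(4)
    avg <- average_pfms(list(p1, p2))
    manual <- (unclass(p1) + unclass(p2)) / 2
    manual <- sweep(manual, 2, colSums(manual), "/")
    expect_equal(unclass(avg), manual, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(colSums(unclass(avg)), rep(1, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(average_pfms(list(p1, random_pfm(5))), "different lengths")
  })
})

test_that("information content is the KL divergence in bits", {
  uni <- structure(matrix(0.25, 4, 3, dimnames = list(BASES, NULL)),
                   class = "pfm")
  expect_equal(information_content(uni), rep(0, 3))
  det <- structure(matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(BASES, NULL)),
                   class = "pfm")
  expect_equal(information_content(det), 2)
  expect_equal(information_content(det, dnase_background()), -log2(0.24))
})

test_that("delta-z matrices have zero column medians and flag missing SNVs", {
  s <- fx("sim_full_small", function()
    make_mode_sim("full", n_seeds = 4, spacer_len = 1, seed = 200,
                  n_background = 40))
  sd1 <- s$truth$seeds[[1]]
  em <- delta_z_matrix(s$profile, sd1)
  expect_s3_class(em, "energy_matrix")
  expect_equal(ncol(em), 23)
  expect_equal(apply(unclass(em), 2, median), rep(0, 23), tolerance = 1e-12)
  expect_equal(attr(em, "seed_zmax"), max(attr(em, "z")))

  crippled <- s$profile[!(
    !is.na(s$profile$seed_id) & s$profile$seed_id == sd1$seed_id &
    s$profile$category == "snv" & s$profile$variant_position == 3), ]
  expect_error(delta_z_matrix(crippled, sd1), "missing SNV")
})

test_that("inferred per-position preferences recover the planted model", {
  s <- fx("sim_full_small", function()
    make_mode_sim("full", n_seeds = 4, spacer_len = 1, seed = 200,
                  n_background = 40))
  planted <- unclass(s$truth$pfm)
  informative <- which(apply(planted, 2, max) > 0.5)
  hits <- unlist(lapply(s$truth$seeds, function(sd) {
    em <- unclass(delta_z_matrix(s$profile, sd))[, 6:18]
    vapply(informative, function(j)
      which.max(em[, j]) == which.max(planted[, j]), TRUE)
  }))
  expect_gte(mean(hits), 0.95)

  rs <- vapply(s$truth$seeds, function(sd) {
    p <- unclass(pfm_from_profile(s$profile, sd))[, 6:18]
    cor(as.vector(p), as.vector(planted))
  }, 0)
  expect_true(all(rs >= 0.9))
})

test_that("MEME and TSV motif files round-trip", {
  withr::with_seed(74, pfms <- list(m1 = random_pfm(6), m2 = random_pfm(11)))
  f <- tempfile(fileext = ".meme")
  write_meme(pfms, f, background = dnase_background())
  back <- read_meme(f)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(unclass(back$m1), unclass(pfms$m1), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(unclass(back$m2), unclass(pfms$m2), tolerance = 1e-5,
               ignore_attr = TRUE)

  f2 <- tempfile(fileext = ".tsv")
  write_pfm_tsv(pfms$m1, f2)
  expect_equal(unclass(read_pfm_tsv(f2)), unclass(pfms$m1),
               tolerance = 1e-12, ignore_attr = TRUE)
})
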