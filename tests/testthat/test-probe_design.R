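test_that("SNV enumeration yields 3 x (12 + spacer + 2*flank) unique one-off variants", {
  cases <- data.frame(spacer = c(0L, 1L, 5L), expected = c(66L, 69L, 81L))
  for (i in seq_len(nrow(cases))) {
    S <- cases$spacer[i]
    sd <- seed_sequence(paste0("s", S), "AGGTCA", substr("GATCC", 1, S),
                        "AGTTCA", "CATTG", "GCAAT")
    snv <- enumerate_snv_probes(sd, flank_len = 5)
    expect_equal(nrow(snv), cases$expected[i])
    expect_equal(anyDuplicated(snv$context), 0L)
    ctx <- seed_context(sd)
    d <- vapply(snv$context, function(v)
      sum(strsplit(v, "")[[1]] != strsplit(ctx, "")[[1]]), 0L)
    expect_true(all(d == 1L))
    # variants cover every region: both half-sites, spacer and both flanks
    expect_setequal(unique(snv$position), 0:(nchar(ctx) - 1L))
    expect_true(all(nchar(snv$variable_region) == 34L))
  }
})

test_that("invalid seeds are rejected", {
  expect_error(seed_sequence("x", "AGGTNA", "A", "AGTTCA", "CATTG", "GCAAT"),
               "ACGT")
  expect_error(seed_sequence("x", "AGGTCA", "AAAAAA", "AGTTCA", "CATTG",
                             "GCAAT"), "spacer")
  expect_error(seed_sequence("x", "AGGTC", "A", "AGTTCA", "CATTG", "GCAAT"),
               "length 6")
})

test_that("the default full design reproduces the published unique-sequence counts", {
  lib <- fx("full_design", function() {
    build_library(generate_seeds(24, 0:5, rng_seed = 7), rng_seed = 8)
  })
  seed_snv <- lib$probes[lib$probes$category %in% c("seed", "snv"), ]
  useq <- unique(seed_snv$unique_seq)
  expect_equal(length(useq), 10728L)

  per_spacer <- tapply(seed_snv$unique_seq, seed_snv$spacer_len,
                       function(x) length(unique(x)))
  expect_equal(as.vector(per_spacer), 24L * (3L * (22L + 0:5) + 1L))
  expect_equal(unname(per_spacer["0"]), 1608L)

  # brute-force set-construction oracle for one spacer stratum
  dr0 <- Filter(function(s) s$spacer_len == 0L, lib$seeds)
  brute <- unique(unlist(lapply(dr0, function(sd) {
    ctx <- seed_context(sd)
    chars <- strsplit(ctx, "")[[1]]
    vars <- ctx
    for (p in seq_along(chars)) for (b in setdiff(BASES, chars[p])) {
      v <- chars; v[p] <- b
      vars <- c(vars, paste(v, collapse = ""))
    }
    vars
  })))
  expect_equal(length(brute), 1608L)
})

test_that("replicate/orientation expansion gives 10 probes per SNV sequence and 8 otherwise", {
  lib <- fx("full_design", function() {
    build_library(generate_seeds(24, 0:5, rng_seed = 7), rng_seed = 8)
  })
  n_by_seq <- table(lib$probes$unique_seq)
  cat_by_seq <- lib$probes$category[!duplicated(lib$probes$unique_seq)]
  names(cat_by_seq) <- lib$probes$unique_seq[!duplicated(lib$probes$unique_seq)]
  expect_true(all(n_by_seq[names(cat_by_seq)[cat_by_seq == "snv"]] == 10L))
  expect_true(all(n_by_seq[names(cat_by_seq)[cat_by_seq != "snv"]] == 8L))

  seeded <- lib$probes[lib$probes$category != "background", ]
  key <- with(seeded, paste(seed_id, category, variant_position,
                            variant_base, orientation, replicate_index))
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(anyDuplicated(lib$probes$probe_id), 0L)

  o2 <- lib$probes[lib$probes$orientation == "o2", ]
  expect_true(all(o2$variable_region == vapply(o2$unique_seq, rc_chr, "")))
  o1 <- lib$probes[lib$probes$orientation == "o1", ]
  expect_true(all(o1$variable_region == o1$unique_seq))
  expect_equal(sum(lib$probes$category == "background") / 8L, 500)
})

test_that("colliding seeds are rejected with the pair named", {
  s1 <- seed_sequence("near1", "AGGTCA", "A", "AGTTCA", "CATTG", "GCAAT")
  s2 <- seed_sequence("near2", "AGGTCA", "C", "AGTTCA", "CATTG", "GCAAT")
  expect_error(build_library(list(s1, s2), seeds_per_spacer = 2,
                             n_background = 12, rng_seed = 1),
               "near1.*near2|near2.*near1")
  expect_error(build_library(list(s1), seeds_per_spacer = 24,
                             n_background = 12, rng_seed = 1),
               "fewer than 24")
})

test_that("half-site ablation mutates the top-contribution position to the worst base", {
  sd <- seed_sequence("ab", "AGGTCA", "A", "AGTTCA", "CATTG", "GCAAT")
  # only informative position: 5' half-site position 2 (G preferred, T worst)
  m <- matrix(0, 4, 13, dimnames = list(BASES, NULL))
  m["G", 2] <- 5
  m["T", 2] <- -5
  abl <- ablate_half_site(sd, m, "5prime")
  expect_equal(abl$hs5, "ATGTCA")
  expect_equal(abl$hs3, sd$hs3)
  expect_equal(abl$seed_id, "ab_abl5")

  # tie between positions 2 and 3 resolves to the lower index
  m2 <- m
  m2["G", 3] <- 5
  expect_equal(ablate_half_site(sd, m2, "5prime")$hs5, "ATGTCA")

  # property: ablation never increases the model score, checked against an
  # exhaustive single-mutation scan over the chosen half-site
  withr::with_seed(42, {
    for (rep in 1:20) {
      mr <- matrix(runif(4 * 13, -1, 0), 4, 13, dimnames = list(BASES, NULL))
      site <- paste0(sd$hs5, sd$spacer, sd$hs3)
      site_chars <- strsplit(site, "")[[1]]
      mr[cbind(match(site_chars, BASES), 1:13)] <- runif(13, 0.5, 1)
      score <- function(s) {
        ch <- strsplit(paste0(s$hs5, s$spacer, s$hs3), "")[[1]]
        sum(mr[cbind(match(ch, BASES), 1:13)])
      }
      for (h in c("5prime", "3prime")) {
        a <- ablate_half_site(sd, mr, h)
        cols <- if (h == "5prime") 1:6 else 8:13
        scan <- c()
        for (p in cols) for (b in BASES) {
          v <- site_chars; v[p] <- b
          scan <- c(scan, sum(mr[cbind(match(v, BASES), 1:13)]))
        }
        expect_lt(score(a), score(sd))
        expect_equal(sum(strsplit(seed_context(a), "")[[1]] !=
                         strsplit(seed_context(sd), "")[[1]]), 1L)
      }
    }
  })
})

test_that("background sampling filters Ns and long runs, reproducibly", {
  withr::with_seed(5, {
    genome <- paste(sample(c(BASES, "N"), 6000, replace = TRUE,
                           prob = c(rep(0.24, 4), 0.04)), collapse = "")
  })
  bg <- sample_background(genome, n = 40, length = 34, rng_seed = 9)
  expect_length(bg, 40)
  expect_true(all(nchar(bg) == 34))
  expect_false(any(grepl("N", bg)))
  expect_false(any(grepl("A{4}|C{4}|G{4}|T{4}", bg)))
  expect_identical(bg, sample_background(genome, 40, 34, rng_seed = 9))
  expect_length(sample_background(genome, 0, 34, rng_seed = 9), 0)
  expect_error(sample_background("ACGTACGTAC", n = 5, length = 34),
               "at least 34")
  expect_error(sample_background(strrep("AN", 100), n = 5, length = 34),
               "insufficient|only")
})

test_that("ablation variants are recorded against existing SNV sequences", {
  lib <- fx("full_design", function() {
    build_library(generate_seeds(24, 0:5, rng_seed = 7), rng_seed = 8)
  })
  expect_equal(nrow(lib$ablations), 2L * length(lib$seeds))
  expect_true(all(lib$ablations$snv_of_seed))
  expect_true(all(lib$ablations$unique_seq %in% lib$probes$unique_seq))
})
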