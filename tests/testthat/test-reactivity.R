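test_that("C-repeat filter removes runs above the threshold only", {
  mk <- function(id, seqn) {
    n <- nchar(seqn)
    reactivity_profile(id, seqn, integer(n), rep(0.01, n))
  }
  out <- filter_c_repeats(list(mk("a", "AACCCCCA"), mk("b", "ACCCCA")))
  expect_equal(vapply(out$removed, `[[`, "", "construct_id"), "a")
  expect_equal(vapply(out$kept, `[[`, "", "construct_id"), "b")
  empty <- filter_c_repeats(list())
  expect_length(empty$kept, 0)
  expect_length(empty$removed, 0)
})

test_that("AUROC reproduces the worked example and its edge cases", {
  p <- make_profile_from_scores(c(0.5, 0.2), c(0.1, 0.3))
  expect_equal(auroc(p), 0.75)
  # perfect separation and all-ties
  expect_equal(auroc(make_profile_from_scores(c(0.5, 0.6), c(0.1, 0.2))), 1)
  expect_equal(auroc(make_profile_from_scores(rep(0.3, 3), rep(0.3, 4))), 0.5)
  # fewer than 2 positives or negatives: undefined, not an error
  one_pos <- reactivity_profile("x", "AAAAA", c(0L, 5L, 4L, 3L, 2L),
                                c(0.5, 0.1, 0.0, 0.2, 0.3))
  expect_true(is.na(auroc(one_pos)))
})

test_that("AUROC equals brute-force pair counting on random instances", {
  set.seed(31)
  for (rep in 1:300) {
    k <- sample(2:15, 1); m <- 2 * sample(1:7, 1)
    scores <- round(runif(k + m), sample(1:3, 1))  # induce ties
    p <- make_profile_from_scores(scores[1:k], scores[(k + 1):(k + m)])
    expect_equal(auroc(p), brute_auroc(scores[1:k], scores[(k + 1):(k + m)]),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(32)
  scores <- runif(20)
  p1 <- make_profile_from_scores(scores[1:8], scores[9:20])
  for (f in list(function(x) 10 * x, function(x) x^3, function(x) exp(x))) {
    p2 <- make_profile_from_scores(f(scores[1:8]), f(scores[9:20]))
    expect_equal(auroc(p2), auroc(p1), tolerance = 1e-12)
  }
})

test_that("AUROC restricts to A/C positions and the requested scope", {
  # G/U positions carry extreme values that would flip the score if used
  seqn <- "AGACUC"
  pt <- c(0L, 0L, 6L, 0L, 0L, 3L)     # pairs (3,6); positions 1,2,4,5 unpaired
  rx <- c(0.5, 0.0, 0.1, 0.2, 9.9, 0.3)
  p <- reactivity_profile("x", seqn, pt, rx, local = 1:3)
  # A/C global: positives {0.5, 0.2}, negatives {0.1, 0.3} -> 0.75
  expect_equal(auroc(p, "global"), 0.75)
  # local scope holds A1 (pos) and C3 (neg) only: under 2+2 -> NA
  expect_true(is.na(auroc(p, "local")))
  # distal positives {0.2}, negatives {0.3}: still under the floor
  expect_true(is.na(auroc(p, "distal")))
})

test_that("region means are A/C-restricted with the documented log rule", {
  seqn <- "GGAAACCAAUU"
  #        S S H H H S S E E E E   pairing (1,7),(2,6)? use explicit table
  pt <- c(7L, 6L, 0L, 0L, 0L, 2L, 1L, 0L, 0L, 0L, 0L)
  rx <- c(0.9, 0.01, 0.03, 0.5, 0.7, 0.03, 0.9, 0.2, 0.2, 9.0, 9.0)
  p <- reactivity_profile("x", seqn, pt, rx, local = 1:7)
  # local stem A/C positions: 2 (C via G?) -- base layout: G G A A A C C
  # stems at 1,2,6,7 = G,G,C,C -> A/C stems are 6,7: mean(0.03, 0.9)
  expect_equal(region_reactivity(p, "stem", "local"), mean(c(0.03, 0.9)))
  expect_equal(region_reactivity(p, "loop", "local"), mean(c(0.03, 0.5, 0.7)))
  # distal region has no structural loop positions (exterior tail excluded)
  expect_true(is.na(region_reactivity(p, "loop", "distal")))
  expect_equal(region_reactivity(p, "stem", "local", log_transform = TRUE),
               log(mean(c(0.03, 0.9)) + 1e-4))
  # all-G/U target region is undefined
  p2 <- reactivity_profile("y", "GGGUUU", c(6L, 5L, 4L, 3L, 2L, 1L),
                           rep(0.1, 6))
  expect_true(is.na(region_reactivity(p2, "stem", "local")))
  # zero mean logs to the pseudocount
  p3 <- reactivity_profile("z", "AACAAUU", c(7L, 6L, 0L, 0L, 0L, 2L, 1L),
                           rep(0, 7), local = 1:7)
  expect_equal(region_reactivity(p3, "stem", "local", log_transform = TRUE),
               log(1e-4))
})

test_that("distal metrics ignore perturbations of the local region", {
  lib <- generate_library("hairpin", 8, seed = 19)
  prof <- simulate_dms(lib, dms_sim_config(), seed = 20)
  p <- prof[[1]]
  q <- p
  q$reactivity[q$local] <- rev(q$reactivity[q$local]) * 3 + 0.05
  expect_identical(auroc(p, "distal"), auroc(q, "distal"))
  expect_identical(region_reactivity(p, "stem", "distal"),
                   region_reactivity(q, "stem", "distal"))
  expect_identical(region_reactivity(p, "loop", "distal"),
                   region_reactivity(q, "loop", "distal"))
  expect_false(identical(auroc(p, "local"), auroc(q, "local")))
})

test_that("per-position profiles recover known positional means", {
  lib <- generate_library("hairpin", 40, seed = 29)
  man <- lib$manifest
  profiles <- lapply(seq_len(nrow(man)), function(k) {
    st <- parse_dotbracket(man$id[k], man$sequence[k], man$dotbracket[k],
                           quiet = TRUE)
    # reactivity encodes a known function of stem depth: 0.3 / position
    stems <- local_stems_from_loop(reactivity_profile(
      man$id[k], man$sequence[k], st$pair_table,
      rep(0, st$length), local = lib$regions[[man$id[k]]]$local,
      net_dg = man$net_dg[k]))
    rx <- rep(0.5, st$length)
    for (pos in seq_len(nrow(stems[[1]]))) rx[stems[[1]][pos, ]] <- 0.3 / pos
    reactivity_profile(man$id[k], man$sequence[k], st$pair_table, rx,
                       local = lib$regions[[man$id[k]]]$local,
                       net_dg = man$net_dg[k])
  })
  pp <- per_position_profile(profiles, bins = c(-40, 0, 10), min_n = 20)
  got <- pp[pp$bin_left == -40, ]
  expect_equal(got$mean, 0.3 / got$position, tolerance = 1e-9)
  # constant reactivity: zero-width confidence intervals
  flat <- lapply(profiles, function(p) {
    p$reactivity <- rep(0.05, length(p$reactivity)); p
  })
  ppf <- per_position_profile(flat, bins = c(-40, 0, 10), min_n = 20)
  expect_true(all(abs(ppf$mean - 0.05) < 1e-12))
  expect_true(all(ppf$ci_hi - ppf$ci_lo < 1e-12))
  # bins under the floor are suppressed
  expect_warning(
    none <- per_position_profile(profiles[1:2], bins = c(-40, 0, 10),
                                 min_n = 70),
    "minimum nucleotide count")
  expect_equal(nrow(none), 0)
})

test_that("Hill fits recover noiseless parameters and the 0.9 crossing", {
  a0 <- 0.5; h <- 4; s50 <- 14; s_offset <- 10
  net <- seq(-15, 5, by = 0.2) + 0.1
  s <- s_offset - net
  fid <- data.frame(net_dg = net,
                    auroc_local = a0 + (1 - a0) * s^h / (s50^h + s^h))
  fit <- fit_hill(fid, bin_width = 0.2, s_offset = s_offset)
  expect_equal(fit$a0, a0, tolerance = 0.01)
  expect_equal(fit$h, h, tolerance = 0.01 * h)
  expect_equal(fit$s50, s50, tolerance = 0.01 * s50)
  r <- (0.9 - a0) / (1 - a0)
  g09_closed <- s_offset - s50 * (r / (1 - r))^(1 / h)
  expect_equal(fit$g09, g09_closed, tolerance = 0.01 * abs(g09_closed))
  # fitted curve is monotone non-decreasing in stability
  curve <- predict_hill(fit, seq(5, -15, by = -0.5))
  expect_true(all(diff(curve) >= -1e-12))
})

test_that("flat AUROC data yield an undefined 0.9 crossing", {
  fid <- data.frame(net_dg = seq(-10, 0, by = 0.2),
                    auroc_local = 0.5)
  fit <- fit_hill(fid)
  expect_true(is.na(fit$g09))
})

test_that("Hill fit preconditions are enforced", {
  fid <- data.frame(net_dg = c(-1, -1.3, -1.6, -2, -2.4, -2.8),
                    auroc_local = runif(6, 0.4, 1))
  expect_error(fit_hill(fid), "span")
  expect_error(fit_hill(fid[1:3, ]), "bins")
})

test_that("fidelity regressions separate responsive from null responses", {
  set.seed(41)
  x <- runif(1000, -15, 0)
  exact <- data.frame(net_dg = x, stem_local = 0.2 * x - 5)
  r <- regress_fidelity(exact, "stem_local", log_transform = FALSE)
  expect_equal(r$slope, 0.2, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  null <- data.frame(net_dg = x, stem_distal = rnorm(1000))
  rn <- regress_fidelity(null, "stem_distal", log_transform = FALSE)
  expect_lt(rn$r_squared, 0.02)
  expect_error(regress_fidelity(exact[1:5, ], "stem_local",
                                log_transform = FALSE), "fewer than")
  degenerate <- data.frame(net_dg = rep(-3, 20), stem_local = runif(20))
  expect_error(regress_fidelity(degenerate, "stem_local"), "zero variance")
})

test_that("reactivity tables round-trip through the TSV interface", {
  lib <- generate_library("hairpin", 6, seed = 51)
  prof <- simulate_dms(lib, dms_sim_config(), seed = 52)
  dir <- withr::local_tempdir()
  write_library(lib, file.path(dir, "lib"))
  rx <- do.call(rbind, lapply(prof, function(p) data.frame(
    construct_id = p$construct_id, position = seq_along(p$reactivity),
    base = strsplit(p$sequence, "")[[1]],
    mutation_fraction = p$reactivity, depth = p$depth)))
  write.table(rx, file.path(dir, "rx.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_reactivity_tsv(file.path(dir, "rx.tsv"),
                              file.path(dir, "lib_structures.tsv"),
                              file.path(dir, "lib_manifest.tsv"))
  expect_length(back, length(prof))
  id <- names(prof)[1]
  expect_equal(back[[id]]$reactivity, prof[[id]]$reactivity)
  expect_equal(back[[id]]$net_dg, prof[[id]]$net_dg, tolerance = 1e-6)
  expect_equal(back[[id]]$local, prof[[id]]$local)
  expect_equal(fidelity_records(list(back[[id]]))$auroc_local,
               fidelity_records(list(prof[[id]]))$auroc_local)
})
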