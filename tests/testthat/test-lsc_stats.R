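toy_records <- function() {
  # one structure with a hairpin, a bulge and an internal loop of known parts
  data.frame(
    structure_id = "s1",
    loop_label = c("H1", "B1", "I1"),
    loop_type = c("hairpin", "bulge", "internal"),
    loop_start = c(10L, 30L, 50L), loop_size = c(4L, 2L, 3L),
    loop_dg = c(5.5, 3.0, 2.0),
    stem_label1 = c("S1", "S2", "S4"), stem_label2 = c(NA, "S3", "S5"),
    stem_dg1 = c(-7.2, -4.0, -2.0), stem_dg2 = c(NA, -2.0, -2.0),
    stem_len1 = 5L, stem_len2 = c(NA, 5L, 5L),
    net_dg = c(-1.7, 0.0, 0.0), family = "toy", taxon = NA,
    stringsAsFactors = FALSE)
}

test_that("net dG applies the single-stem and stem-averaging rules", {
  s <- parse_dotbracket("toy", "GGGAAACCC", "(((...)))")
  rec <- make_records(annotate_structure_energies(s))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$net_dg, rec$loop_dg + rec$stem_dg1)
  # worked arithmetic: hairpin 5.5 - 7.2 = -1.7; bulge 3 + mean(-4,-2) = 0;
  # internal 2 + mean(-2,-2) = 0
  r <- toy_records()
  expect_equal(r$loop_dg + ifelse(is.na(r$stem_dg2), r$stem_dg1,
                                  (r$stem_dg1 + r$stem_dg2) / 2),
               c(-1.7, 0.0, 0.0))
})

test_that("records recompute their net dG and structures with ambiguity skip", {
  set.seed(3)
  rec <- simulate_structure_records(db_sim_config(n_per_type = 200), seed = 3)
  recomputed <- rec$loop_dg + ifelse(is.na(rec$stem_dg2), rec$stem_dg1,
                                     (rec$stem_dg1 + rec$stem_dg2) / 2)
  expect_equal(rec$net_dg, recomputed, tolerance = 1e-9)
  # a loop adjacent to an unscorable stem is skipped, with a count
  s <- parse_dotbracket("amb", "GNGAAACCC", "(((...)))")
  en <- annotate_structure_energies(s)
  r <- make_records(en)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "n_skipped"), 1L)
})

test_that("binned regression recovers an exact linear relation", {
  set.seed(5)
  # records at bin centers so the bin aggregate sits exactly on the line
  loop <- sample(seq(0.625, 7.875, by = 0.25), 500, replace = TRUE)
  rec <- data.frame(loop_dg = loop, stem_dg1 = -1 * loop - 2, stem_dg2 = NA)
  out <- bin_aggregate_regress(rec, bin_width = 0.25, aggregate = "median")
  expect_equal(out$fit$slope, -1, tolerance = 1e-9)
  expect_equal(out$fit$intercept, -2, tolerance = 1e-9)
  expect_equal(out$fit$r_squared, 1, tolerance = 1e-9)
  # binning conserves counts
  expect_equal(sum(out$binned$n), 500)
  # a single usable bin is an error
  rec1 <- data.frame(loop_dg = rep(1.1, 50), stem_dg1 = rnorm(50),
                     stem_dg2 = NA)
  expect_error(bin_aggregate_regress(rec1), "fewer than 2 usable bins")
})

test_that("the 5% quantile aggregate uses linear interpolation per bin", {
  rec <- data.frame(loop_dg = rep(c(1.1, 2.1), each = 100),
                    stem_dg1 = c(1:100, 1:100), stem_dg2 = NA)
  out <- bin_aggregate_regress(rec, aggregate = "quantile05", min_count = 10)
  expect_equal(out$binned$value,
               rep(unname(quantile(1:100, 0.05, type = 7)), 2))
})

test_that("rotation control reassigns stems away from their own loops", {
  # 4 hairpins in one structure: offset 2, a perfect derangement
  rec <- data.frame(
    structure_id = "s", loop_label = paste0("H", 1:4), loop_type = "hairpin",
    loop_start = c(5L, 15L, 25L, 35L), loop_size = 4L,
    loop_dg = c(1, 2, 3, 4),
    stem_label1 = paste0("S", 1:4), stem_label2 = NA,
    stem_dg1 = c(-10, -20, -30, -40), stem_dg2 = NA,
    stem_len1 = 5L, stem_len2 = NA,
    net_dg = c(1, 2, 3, 4) + c(-10, -20, -30, -40),
    family = "f", taxon = NA, stringsAsFactors = FALSE)
  rc <- rotation_control(rec, "hairpin")
  expect_equal(rc$control_net_dg, c(1, 2, 3, 4) + c(-30, -40, -10, -20))
  expect_equal(rc$n_structures, 1L)
  # structures contributing <= 3 loops are ineligible
  expect_error(rotation_control(rec[1:3, ], "hairpin"), "no eligible")
  # identical stems everywhere: control variance equals true variance, F = 1
  rec2 <- rec
  rec2$stem_dg1 <- -10
  rec2$net_dg <- rec2$loop_dg - 10
  rc2 <- rotation_control(rec2, "hairpin")
  expect_equal(rc2$f_statistic, 1, tolerance = 1e-12)
  # the per-bin frequencies are proper distributions over the shared bins
  expect_equal(sum(rc2$bin_diff$freq_true), 1, tolerance = 1e-12)
  expect_equal(sum(rc2$bin_diff$freq_control), 1, tolerance = 1e-12)
})

test_that("rotation control never hands a loop one of its own stems", {
  set.seed(9)
  rec <- simulate_structure_records(
    db_sim_config(n_per_type = 400, loops_per_structure = 5), seed = 9)
  for (lt in c("hairpin", "bulge", "internal")) {
    sub <- rec[rec$loop_type == lt, ]
    for (sid in unique(sub$structure_id)) {
      g <- sub[sub$structure_id == sid, ]
      g <- g[order(g$loop_start), ]
      k <- nrow(g)
      if (k <= 3) next
      off <- floor(k / 2)
      donor <- ((seq_len(k) - 1 + off) %% k) + 1
      own <- lapply(seq_len(k), function(i)
        na.omit(c(g$stem_label1[i], g$stem_label2[i])))
      for (i in seq_len(k)) {
        expect_length(intersect(own[[i]], own[[donor[i]]]), 0)
      }
    }
  }
})

test_that("variance F-test matches its closed form and var.test", {
  x <- c(1, 2, 3, 4, 5) * 2   # var 20
  y <- c(1, 2, 3, 4, 5)       # var 5
  ft <- variance_f_test(x, y)
  expect_equal(ft$f, 4)
  vt <- var.test(x, y)
  expect_equal(ft$f, unname(vt$statistic))
  expect_equal(ft$p, vt$p.value)
  # identical samples: F = 1, two-sided p = 1
  ft2 <- variance_f_test(y, y)
  expect_equal(ft2$f, 1)
  expect_equal(ft2$p, 1)
  # direct quadrature cross-check on unequal samples
  x3 <- c(1, 2, 3, 4, 5); y3 <- c(3, 3, 3, 3, 4)
  ft3 <- variance_f_test(x3, y3)
  expect_equal(ft3$f, var(x3) / var(y3))
  tail_hi <- integrate(function(q) df(q, 4, 4), ft3$f, Inf)$value
  expect_equal(ft3$p, 2 * min(tail_hi, 1 - tail_hi), tolerance = 1e-6)
  expect_error(variance_f_test(x3, rep(3, 5)), "zero variance")
  expect_error(variance_f_test(1, y3), "size >= 2")
})

test_that("kernel density estimates integrate to 1 and match the normal", {
  set.seed(13)
  x <- rnorm(10000)
  grid <- seq(-5, 5, length.out = 801)
  d <- density_estimate(x, grid)
  expect_equal(d$density[grid == 0], dnorm(0), tolerance = 0.1)
  integral <- sum(d$density) * diff(grid)[1]
  expect_equal(integral, 1, tolerance = 0.01)
  expect_error(density_estimate(x[1:5]), "at least 10")
  expect_error(density_estimate(rep(1, 100)), "identical")
})

test_that("group summaries report medians, SDs and rank-test contrasts", {
  rec <- data.frame(net_dg = c(-1, -2, -3, -1, -2, -3),
                    family = rep(c("a", "b"), each = 3),
                    taxon = NA, stringsAsFactors = FALSE)
  gs <- group_summary(rec, "family")
  expect_equal(gs$summary$median, c(-2, -2))
  expect_equal(gs$summary$sd, c(1, 1))
  expect_equal(gs$pairwise$p_value, 1, tolerance = 1e-9)
  # a clear 1-sigma shift at n = 200 is detected
  set.seed(17)
  rec2 <- data.frame(net_dg = c(rnorm(200, 0), rnorm(200, 1)),
                     family = rep(c("a", "b"), each = 200),
                     taxon = NA, stringsAsFactors = FALSE)
  gs2 <- group_summary(rec2, "family")
  expect_lt(gs2$pairwise$p_value, 1e-3)
  # undersized groups are excluded with a message
  rec3 <- rbind(rec, data.frame(net_dg = 0, family = "c", taxon = NA))
  expect_message(group_summary(rec3, "family"), "excluding")
})

test_that("record TSV round-trips", {
  rec <- simulate_structure_records(db_sim_config(n_per_type = 40), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records_tsv(rec, path)
  back <- read_records_tsv(path)
  expect_equal(back$net_dg, rec$net_dg, tolerance = 1e-9)
  expect_identical(back$loop_label, rec$loop_label)
})
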