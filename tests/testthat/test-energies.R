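params <- load_turner_params()

test_that("packaged tables load complete and self-consistent", {
  # all canonical-pair stack entries present and the matrix is rotation
  # symmetric (a duo read 5'->3' on either strand scores the same)
  expect_true(all(is.finite(params$stack[1:6, 1:6])))
  expect_equal(params$stack[1:6, 1:6], t(params$stack[1:6, 1:6]))
  expect_equal(params$stack["GC", "CG"], params$stack["CG", "GC"])
  # initiation tables monotone non-decreasing over the large-size regime
  # (the published hairpin table genuinely dips at sizes 6 and 8)
  expect_true(all(diff(params$hairpin_init[10:31]) >= 0))
  expect_true(all(diff(params$bulge_init[3:31]) >= 0))
  expect_true(all(diff(params$internal_init[5:31]) >= 0))
  expect_gt(length(params$special_hairpins), 15)
})

test_that("a parameter file missing a table errors by name", {
  src <- system.file("extdata", "turner2004_dg.txt", package = "rnalsc")
  lines <- readLines(src)
  drop <- grep("^# hairpin$", lines)
  stop_at <- grep("^# bulge$", lines)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines[-(drop:(stop_at - 1))], bad)
  expect_error(load_turner_params(bad), "hairpin initiation table absent")
})

test_that("stem energies follow stack sums plus end penalties", {
  p <- params
  # length-1 G-C stem: no stacks, no penalties
  s <- parse_dotbracket("l1", "AAGAAACA", "..(...).")
  en <- annotate_structure_energies(s, p)
  expect_equal(en$dg[en$label == "S1"], 0)
  # length-2 all-GC stem equals the single stack entry
  st <- list(label = "S", start5 = 1, end5 = 2, start3 = 7, end3 = 8,
             length = 2L)
  e2 <- stem_dg(st, "GGAAAACC", p)
  expect_equal(e2$dg, params$stack["GC", "CG"] / 100)
  # length-3 all-AU stem: two stacks + two AU end penalties (context-free)
  st3 <- list(label = "S", start5 = 1, end5 = 3, start3 = 8, end3 = 10,
              length = 3L)
  e3 <- stem_dg(st3, "AAAGGGAUUU", p)
  expect_length(e3$terms, 4)
  expect_equal(sum(grepl("au_end", names(e3$terms))), 2)
  expect_equal(e3$dg, sum(e3$terms))
  # non-canonical pair propagates unscorable, never silently zero
  bad <- stem_dg(st3, "AAAGGGAUUA", p)   # closes A-A
  expect_true(bad$unscorable)
  expect_true(is.na(bad$dg))
})

test_that("hairpin energies: special loops, size-3 rule, extrapolation", {
  p <- params
  # tabulated special tetraloop: value taken verbatim from the table
  s <- parse_dotbracket("tl", "GGCCAAGGCC", "(((....)))")
  h <- decompose(s)$hairpins$H1
  e <- hairpin_dg(h, s$sequence, p)
  expect_named(e$terms, "special")
  expect_equal(e$dg, unname(p$special_hairpins["CCAAGG"]) / 100)
  # size-3 loop: initiation only for G-C closing (no mismatch term)
  s3 <- parse_dotbracket("h3", "GAAAC", "(...)")
  e3 <- hairpin_dg(decompose(s3)$hairpins$H1, s3$sequence, p)
  expect_equal(e3$dg, p$hairpin_init[4] / 100)
  # size-31 vs size-30 loop differs by the truncated Jacobson-Stockmayer term
  mk <- function(n) {
    seqn <- paste0("G", strrep("A", n), "C")
    parse_dotbracket("h", seqn, paste0("(", strrep(".", n), ")"))
  }
  e30 <- hairpin_dg(decompose(mk(30))$hairpins$H1, mk(30)$sequence, p)
  e31 <- hairpin_dg(decompose(mk(31))$hairpins$H1, mk(31)$sequence, p)
  expect_equal(e31$dg - e30$dg, trunc(p$lxc * log(31 / 30)) / 100)
  # extrapolation continuous at the table boundary
  expect_equal(loop_init(p$hairpin_init, 30, p$lxc), p$hairpin_init[31])
  # sizes 1-2 below the Turner minimum are unscorable
  s1 <- parse_dotbracket("h1", "GGACC", "((.))")
  expect_true(hairpin_dg(decompose(s1)$hairpins$H1, s1$sequence, p)$unscorable)
})

test_that("bulge energies follow the size-1 stack-through and size>=2 rules", {
  p <- params
  # size-1 C bulge between two G-C pairs: init + through stack of the duo
  s <- parse_dotbracket("b1", "GCGGAAACCC", "(.((...)))")
  d <- decompose(s)
  expect_equal(d$bulges$B1$size, 1)
  e <- bulge_dg(d$bulges$B1, s$sequence, p)
  expect_equal(e$dg, (p$bulge_init[2] + p$stack["GC", "CG"]) / 100)
  expect_false(any(grepl("au_end", names(e$terms))))
  # size-3 bulge closed by G-C (outer) and A-U (inner): init + one AU penalty
  s2 <- parse_dotbracket("b3", "GAAAAAAAUC", "(...(...))")
  d2 <- decompose(s2)
  expect_equal(d2$bulges$B1$size, 3)
  e2 <- bulge_dg(d2$bulges$B1, s2$sequence, p)
  expect_equal(sum(grepl("au_end", names(e2$terms))), 1)
  expect_equal(e2$dg, (p$bulge_init[4] + p$terminal_au) / 100)
})

test_that("internal loop energies use the dedicated and generic tables", {
  p <- params
  # 1x1 loop: exact int11 entry (G.A mismatch between two G-C pairs)
  s <- parse_dotbracket("i11", "GGGGGAAACCACC", "((.((...)).))")
  d <- decompose(s)
  e <- internal_dg(d$internal_loops$I1, s$sequence, p)
  expect_named(e$terms, "int11")
  # symmetric 4x4 loop: zero asymmetry term
  s44 <- parse_dotbracket("i44", "GCAAAAGGAAACCAAAAGC",
                          "((....((...))....))")
  e44 <- internal_dg(decompose(s44)$internal_loops$I1, s44$sequence, p)
  expect_equal(unname(e44$terms["asymmetry"]), 0)
  # 2x3 loop: internal_init(5) + one ninio step + the 2x3 mismatch tables
  s23 <- parse_dotbracket("i23", "GCAAGGAAACCAAAGC", "((..((...))...))")
  e23 <- internal_dg(decompose(s23)$internal_loops$I1, s23$sequence, p)
  expect_equal(unname(e23$terms["initiation"]), p$internal_init[6] / 100)
  expect_equal(unname(e23$terms["asymmetry"]), p$ninio_m / 100)
})

test_that("every component's dG equals the sum of its terms", {
  set.seed(7)
  for (rep in 1:20) {
    s <- random_single_branch(sample(25:70, 1))
    en <- annotate_structure_energies(s, params)
    terms <- attr(en, "terms")
    for (lab in en$label[!en$unscorable]) {
      expect_equal(en$dg[en$label == lab], sum(terms[[lab]]), tolerance = 1e-9)
    }
  }
})

test_that("component sums match the reference evaluator on random structures", {
  set.seed(11)
  structs <- replicate(60, random_single_branch(sample(20:80, 1)),
                       simplify = FALSE)
  ref <- rnaeval_total(vapply(structs, `[[`, "", "sequence"),
                       vapply(structs, function(s)
                         dotbracket_from_pairs(s$pair_table), ""))
  mine <- vapply(structs, function(s)
    total_dg(annotate_structure_energies(s, params)), 0)
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("ambiguous bases mark only the touched components unscorable", {
  s <- parse_dotbracket("amb", "GGGANACCC", "(((...)))")
  en <- annotate_structure_energies(s, params)
  expect_true(en$unscorable[en$label == "H1"])
  expect_false(en$unscorable[en$label == "S1"])
  expect_error(total_dg(en), "unscorable")
})

test_that("toy hairpin annotates exactly one stem and one hairpin record", {
  en <- annotate_structure_energies(
    parse_dotbracket("toy", "GGGAAACCC", "(((...)))"), params)
  expect_equal(nrow(en), 2)
  expect_setequal(en$label, c("S1", "H1"))
})
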