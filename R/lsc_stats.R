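# Net-dG local stability compensation statistics over substructure databases:
# record construction, binned loop-vs-stem regressions, the in-structure
# rotation control with variance F-test, kernel density estimates and
# group-level summaries.

LOOP_TYPES <- c("hairpin", "bulge", "internal")

#' Build net-dG substructure records from annotated structures
#'
#' One record per scored hairpin, bulge or internal loop. The net free energy
#' is the loop energy plus the adjacent stem energy: the single closing stem
#' for hairpins, the arithmetic mean of the two flanking stems for two-way
#' junctions (bulges and internal loops). Loops with an unscorable energy, or
#' adjacent to an unscorable stem, are skipped and counted.
#'
#' @param energies A `component_energies` object from
#'   [annotate_structure_energies()], or a list of them (one per structure).
#' @param family Optional family label(s), recycled across structures.
#' @param taxon Optional taxon tag(s), recycled across structures.
#' @return A data frame of substructure records (class `lsc_records`) with
#'   columns `structure_id`, `loop_label`, `loop_type`, `loop_start`,
#'   `loop_size`, `loop_dg`, `stem_label1`, `stem_label2`, `stem_dg1`,
#'   `stem_dg2`, `stem_len1`, `stem_len2`, `net_dg`, `family`, `taxon`.
#'   The number of skipped loops is in attribute `n_skipped`.
#' @export
make_records <- function(energies, family = "unknown", taxon = NA_character_) {
  if (inherits(energies, "component_energies")) energies <- list(energies)
  family <- rep_len(family, length(energies))
  taxon <- rep_len(taxon, length(energies))
  rows <- list(); skipped <- 0L
  for (si in seq_along(energies)) {
    en <- energies[[si]]
    decomp <- attr(en, "decomposition")
    dg_of <- stats::setNames(en$dg, en$label)
    loops <- c(decomp$hairpins, decomp$bulges, decomp$internal_loops)
    for (lp in loops) {
      adj <- decomp$adjacency[[lp$label]]
      if (is.null(adj) || any(!adj %in% names(dg_of))) { skipped <- skipped + 1L; next }
      loop_dg <- dg_of[[lp$label]]
      stem_dgs <- unname(dg_of[adj])
      if (is.na(loop_dg) || anyNA(stem_dgs)) { skipped <- skipped + 1L; next }
      ltype <- switch(substr(lp$label, 1, 1), H = "hairpin", B = "bulge",
                      I = "internal")
      lstart <- if (ltype == "hairpin") min(lp$loop_positions)
                else if (ltype == "bulge") min(lp$bulge_positions)
                else min(lp$side5_positions)
      slen <- decomp$stems$length[match(adj, decomp$stems$label)]
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = decomp$structure_id, loop_label = lp$label,
        loop_type = ltype, loop_start = lstart, loop_size = lp$size,
        loop_dg = loop_dg,
        stem_label1 = adj[1], stem_label2 = if (length(adj) > 1) adj[2] else NA,
        stem_dg1 = stem_dgs[1], stem_dg2 = if (length(adj) > 1) stem_dgs[2] else NA,
        stem_len1 = slen[1], stem_len2 = if (length(adj) > 1) slen[2] else NA,
        net_dg = loop_dg + mean(stem_dgs),
        family = family[si], taxon = taxon[si], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_records()
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  class(out) <- c("lsc_records", "data.frame")
  out
}

empty_records <- function() {
  data.frame(structure_id = character(0), loop_label = character(0),
             loop_type = character(0), loop_start = integer(0),
             loop_size = integer(0), loop_dg = numeric(0),
             stem_label1 = character(0), stem_label2 = character(0),
             stem_dg1 = numeric(0), stem_dg2 = numeric(0),
             stem_len1 = integer(0), stem_len2 = integer(0),
             net_dg = numeric(0), family = character(0), taxon = character(0),
             stringsAsFactors = FALSE)
}

# per-record stem statistic: the single stem for hairpins, the mean of the
# two flanking stems for two-way junctions
record_stem_stat <- function(records) {
  ifelse(is.na(records$stem_dg2), records$stem_dg1,
         (records$stem_dg1 + records$stem_dg2) / 2)
}

#' Binned loop-vs-stem regression
#'
#' Bins records by loop free energy (left-closed bins of `bin_width`
#' kcal/mol), aggregates the per-record stem statistic within each bin
#' (median or 5% quantile, linear-interpolation type 7), and fits an ordinary
#' least-squares line of the aggregate against the bin center. Bins holding
#' fewer than `min_count` records are excluded from the regression.
#'
#' @param records An `lsc_records` data frame.
#' @param bin_width Bin width in kcal/mol (default 0.25).
#' @param aggregate `"median"` or `"quantile05"`.
#' @param min_count Minimum records for a bin to enter the regression.
#' @return List with `binned` (data frame `bin_left`, `bin_center`, `value`,
#'   `n`, `used`) and `fit` (a `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n_bins`).
#' @export
bin_aggregate_regress <- function(records, bin_width = 0.25,
                                  aggregate = c("median", "quantile05"),
                                  min_count = 10) {
  aggregate <- match.arg(aggregate)
  x <- records$loop_dg
  y <- record_stem_stat(records)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) stop("no usable records")
  lefts <- floor(x / bin_width) * bin_width
  agg_fun <- if (aggregate == "median") stats::median else
    function(v) unname(stats::quantile(v, 0.05, type = 7))
  sp <- split(y, lefts)
  binned <- data.frame(
    bin_left = as.numeric(names(sp)),
    value = vapply(sp, agg_fun, 0),
    n = vapply(sp, length, 0L), row.names = NULL)
  binned$bin_center <- binned$bin_left + bin_width / 2
  binned$used <- binned$n >= min_count
  use <- binned[binned$used, ]
  if (nrow(use) < 2) {
    stop("fewer than 2 usable bins (", nrow(use), " with >= ", min_count,
         " records)")
  }
  fit <- stats::lm(value ~ bin_center, data = use)
  res <- structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (stats::var(use$value) == 0) 1 else
      stats::cor(use$value, stats::fitted(fit))^2,
    n_bins = nrow(use)), class = "regression_result")
  list(binned = binned[, c("bin_left", "bin_center", "value", "n", "used")],
       fit = res)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.4f, intercept %.4f, r^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared,
              if (!is.null(x$n_bins)) x$n_bins else x$n))
  invisible(x)
}

#' In-structure rotation control for net dG
#'
#' Within-structure null that destroys local loop-stem pairing while
#' preserving the marginal energy distributions: in every structure
#' contributing more than three loops of the given type, loops are ordered
#' 5' to 3' and their adjacent-stem energy sets are reassigned by a cyclic
#' shift of offset floor(k/2) (k = loop count); if any reassigned stem set
#' still contains a stem adjacent to its recipient loop, the offset is
#' incremented until none does. Control net dG uses the same averaging rule
#' as the true statistic. Under compensation the control variance exceeds the
#' true variance; the two are compared with a variance F-test.
#'
#' @param records An `lsc_records` data frame.
#' @param loop_type One of `"hairpin"`, `"bulge"`, `"internal"`.
#' @param bin_width Bin width for the true-minus-control frequency
#'   differences.
#' @return A `rotation_control_result`: list with `true_net_dg`,
#'   `control_net_dg`, `f_statistic`, `p_value` (two-sided F-test of
#'   var(control)/var(true)), `bin_diff` data frame (`bin_left`, `freq_true`,
#'   `freq_control`, `diff`), `n_structures`, `n_loops`.
#' @export
rotation_control <- function(records, loop_type = "hairpin",
                             bin_width = 0.25) {
  stopifnot(loop_type %in% LOOP_TYPES)
  rec <- records[records$loop_type == loop_type, , drop = FALSE]
  true_net <- c(); ctrl_net <- c(); n_struct <- 0L
  for (sid in unique(rec$structure_id)) {
    g <- rec[rec$structure_id == sid, , drop = FALSE]
    k <- nrow(g)
    if (k <= 3) next                       # eligibility: > 3 loops of the type
    g <- g[order(g$loop_start), , drop = FALSE]
    own <- lapply(seq_len(k), function(i)
      stats::na.omit(c(g$stem_label1[i], g$stem_label2[i])))
    offset <- NA_integer_
    half <- floor(k / 2)                   # k > 3, so half >= 2
    for (off in c(half:(k - 1L), 1:(half - 1L))) {
      donor <- ((seq_len(k) - 1L + off) %% k) + 1L
      clash <- any(vapply(seq_len(k), function(i)
        length(intersect(own[[i]], own[[donor[i]]])) > 0, TRUE))
      if (!clash) { offset <- off; break }
    }
    if (is.na(offset)) next                # loops share stems at every offset
    donor <- ((seq_len(k) - 1L + offset) %% k) + 1L
    donor_stem <- record_stem_stat(g)[donor]
    true_net <- c(true_net, g$net_dg)
    ctrl_net <- c(ctrl_net, g$loop_dg + donor_stem)
    n_struct <- n_struct + 1L
  }
  if (n_struct == 0L) {
    stop("no eligible structures (need > 3 loops of type '", loop_type, "')")
  }
  ft <- variance_f_test(ctrl_net, true_net)
  all_net <- c(true_net, ctrl_net)
  lefts <- floor(all_net / bin_width) * bin_width
  breaks <- sort(unique(lefts))
  freq <- function(v) {
    tab <- table(factor(floor(v / bin_width) * bin_width, levels = breaks))
    as.numeric(tab) / length(v)
  }
  bin_diff <- data.frame(bin_left = breaks, freq_true = freq(true_net),
                         freq_control = freq(ctrl_net))
  bin_diff$diff <- bin_diff$freq_true - bin_diff$freq_control
  structure(list(true_net_dg = true_net, control_net_dg = ctrl_net,
                 f_statistic = ft$f, p_value = ft$p, bin_diff = bin_diff,
                 n_structures = n_struct, n_loops = length(true_net)),
            class = "rotation_control_result")
}

#' @export
print.rotation_control_result <- function(x, ...) {
  cat(sprintf(paste0("rotation control: %d loops in %d structures; ",
                     "var(control)/var(true) F = %.3f, p = %.3g\n"),
              x$n_loops, x$n_structures, x$f_statistic, x$p_value))
  invisible(x)
}

#' Two-sided variance F-test
#'
#' F = var(x)/var(y) with unbiased (n-1) variance estimators; the two-sided
#' p-value doubles the smaller tail of the F distribution with
#' (n_x - 1, n_y - 1) degrees of freedom.
#'
#' @param x,y Numeric samples of size >= 2.
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need size >= 2")
  vy <- stats::var(y)
  if (vy == 0) stop("zero variance in denominator sample")
  f <- stats::var(x) / vy
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  list(f = f, p = min(1, p), df1 = df1, df2 = df2)
}

#' Gaussian kernel density estimate of net dG values
#'
#' Evaluates a Gaussian-kernel density on the supplied grid using Scott's
#' rule-of-thumb bandwidth (`stats::bw.nrd`). With at least a few hundred
#' points the density integrates to 1 over a grid spanning the data within
#' about 1%.
#'
#' @param net_dgs Numeric values (n >= 10).
#' @param grid Evaluation grid (default: 512 points spanning the data plus
#'   three bandwidths).
#' @return Data frame with columns `x` (grid) and `density`, bandwidth in
#'   attribute `bw`.
#' @export
density_estimate <- function(net_dgs, grid = NULL) {
  net_dgs <- net_dgs[is.finite(net_dgs)]
  if (length(net_dgs) < 10) stop("need at least 10 values for a density estimate")
  if (stats::var(net_dgs) == 0) {
    stop("all values identical: zero bandwidth (point mass, no density estimate)")
  }
  bw <- stats::bw.nrd(net_dgs)
  if (is.null(grid)) {
    grid <- seq(min(net_dgs) - 3 * bw, max(net_dgs) + 3 * bw, length.out = 512)
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, net_dgs, bw)), 0)
  out <- data.frame(x = grid, density = dens)
  attr(out, "bw") <- bw
  out
}

#' Per-group net-dG summaries with pairwise rank tests
#'
#' Medians (linear-interpolation quantile), sample standard deviations
#' (n - 1) and sizes per group, plus two-sided Mann-Whitney U tests for every
#' pair of groups. Groups with fewer than 2 records are excluded with a
#' message.
#'
#' @param records An `lsc_records` data frame.
#' @param group_by Grouping column, `"family"` or `"taxon"`.
#' @param value Column to summarize (default `net_dg`).
#' @return List with `summary` (group, n, median, sd) and `pairwise` (group1,
#'   group2, u_statistic, p_value).
#' @export
group_summary <- function(records, group_by = c("family", "taxon"),
                          value = "net_dg") {
  group_by <- match.arg(group_by)
  g <- records[[group_by]]
  v <- records[[value]]
  keep <- !is.na(g) & is.finite(v)
  g <- g[keep]; v <- v[keep]
  sp <- split(v, g)
  small <- names(sp)[vapply(sp, length, 0L) < 2]
  if (length(small) > 0) {
    message("excluding group(s) with < 2 records: ", paste(small, collapse = ", "))
    sp <- sp[!names(sp) %in% small]
  }
  if (length(sp) == 0) stop("no groups with >= 2 records")
  summary <- data.frame(
    group = names(sp),
    n = vapply(sp, length, 0L),
    median = vapply(sp, stats::median, 0),
    sd = vapply(sp, stats::sd, 0), row.names = NULL)
  pairs <- if (length(sp) >= 2) utils::combn(names(sp), 2, simplify = FALSE)
           else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(sp[[pr[1]]], sp[[pr[2]]],
                                              alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               u_statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
  if (is.null(pairwise)) {
    pairwise <- data.frame(group1 = character(0), group2 = character(0),
                           u_statistic = numeric(0), p_value = numeric(0))
  }
  list(summary = summary, pairwise = pairwise)
}

#' Write / read substructure records as TSV
#'
#' One row per loop with the documented record columns; plain
#' tab-separated text with a header line.
#'
#' @param records An `lsc_records` data frame.
#' @param path Output path.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_tsv
#' @export
read_records_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("lsc_records", "data.frame")
  out
}
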