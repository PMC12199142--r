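# Folding fidelity from DMS chemical-mapping reactivity: QC filters,
# A/C-restricted AUROC in global/local/distal scopes, stem and loop
# reactivity summaries, per-position stem profiles, and the Hill-equation
# fidelity curve with its AUROC = 0.9 stability threshold.
#
# A reactivity profile is a list with: construct_id, sequence, pair_table
# (designed pairing), reactivity (per-position mutation fraction), depth
# (optional per-position read depth), local (positions of the randomized
# region), net_dg (net dG of the variable loop, kcal/mol).

#' Construct a reactivity profile
#'
#' @param construct_id Identifier.
#' @param sequence RNA sequence.
#' @param pair_table Designed per-position partner index (0 = unpaired), as
#'   from [parse_dotbracket()].
#' @param reactivity Per-position DMS mutation fraction (non-negative).
#' @param local Integer positions of the randomized (local) region.
#' @param net_dg Net dG of the variable loop, kcal/mol (NA if unknown).
#' @param depth Optional per-position read depth.
#' @return A `reactivity_profile` object.
#' @export
reactivity_profile <- function(construct_id, sequence, pair_table, reactivity,
                               local = integer(0), net_dg = NA_real_,
                               depth = NULL) {
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  stopifnot(length(pair_table) == n, length(reactivity) == n,
            all(reactivity >= 0, na.rm = TRUE))
  structure(list(construct_id = construct_id, sequence = sequence,
                 pair_table = as.integer(pair_table),
                 reactivity = as.numeric(reactivity),
                 depth = if (is.null(depth)) rep(NA_real_, n) else depth,
                 local = as.integer(local), net_dg = net_dg),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat("reactivity_profile '", x$construct_id, "' (",
      length(x$reactivity), " nt, net dG ",
      ifelse(is.na(x$net_dg), "NA", sprintf("%.2f", x$net_dg)), ")\n", sep = "")
  invisible(x)
}

#' Remove constructs containing long C repeats
#'
#' Runs of more than `max_run` consecutive cytosines give unreliable DMS
#' reactivities (as documented for A repeats), so constructs containing such
#' runs are removed before fidelity analysis.
#'
#' @param profiles List of `reactivity_profile` objects.
#' @param max_run Longest permitted C run (default 4; a run of exactly 4 is
#'   kept).
#' @return List with `kept` and `removed` profile lists.
#' @export
filter_c_repeats <- function(profiles, max_run = 4) {
  if (length(profiles) == 0) return(list(kept = list(), removed = list()))
  pat <- paste0("C{", max_run + 1, ",}")
  bad <- vapply(profiles, function(p) grepl(pat, p$sequence), TRUE)
  list(kept = profiles[!bad], removed = profiles[bad])
}

# midrank AUROC: probability that a random positive outranks a random
# negative, ties counted half
auroc_rank <- function(scores, is_positive) {
  n_pos <- as.numeric(sum(is_positive)); n_neg <- as.numeric(sum(!is_positive))
  if (n_pos < 2 || n_neg < 2) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUROC folding fidelity of one construct
#'
#' Rank-based area under the receiver-operator curve measuring how well
#' reactivity separates designed-unpaired (positives) from designed-paired
#' (negatives) nucleotides, restricted to A/C positions within the chosen
#' scope: `global` (all positions), `local` (the randomized region) or
#' `distal` (its complement). Ties are handled by midranks. Undefined (NA)
#' when the scope holds fewer than 2 positives or 2 negatives: an undefined
#' score is a value, not an error.
#'
#' @param profile A `reactivity_profile`.
#' @param scope `"global"`, `"local"` or `"distal"`.
#' @return AUROC in \[0, 1\], or NA.
#' @examples
#' p <- reactivity_profile("x", "AACC", c(0, 0, 4, 3),
#'                         c(0.5, 0.2, 0.1, 0.3))
#' auroc(p)   # 0.75
#' @export
auroc <- function(profile, scope = c("global", "local", "distal")) {
  scope <- match.arg(scope)
  n <- length(profile$reactivity)
  mask <- switch(scope,
                 global = rep(TRUE, n),
                 local = seq_len(n) %in% profile$local,
                 distal = !(seq_len(n) %in% profile$local))
  bases <- seq_chars(profile$sequence)
  use <- mask & bases %in% c("A", "C") & !is.na(profile$reactivity)
  if (!any(use)) return(NA_real_)
  auroc_rank(profile$reactivity[use], profile$pair_table[use] == 0L)
}

# position sets for the four region x component targets; distal loops exclude
# exterior tails (primer-binding flanks are not structural loops)
region_positions <- function(profile, target = c("stem", "loop"),
                             region = c("local", "distal")) {
  target <- match.arg(target); region <- match.arg(region)
  n <- length(profile$pair_table)
  paired <- profile$pair_table > 0L
  in_local <- seq_len(n) %in% profile$local
  codes <- position_codes_from_pairs(profile$pair_table)
  sel <- if (target == "stem") paired else (!paired & codes %in% c("H", "B", "I", "M"))
  which(sel & (if (region == "local") in_local else !in_local))
}

#' Mean reactivity of a stem/loop region
#'
#' Arithmetic mean of the A/C-restricted reactivities over the stems or
#' loops of the local (randomized) or distal region; optionally the natural
#' log of the mean plus a pseudocount.
#'
#' @param profile A `reactivity_profile`.
#' @param target `"stem"` or `"loop"`.
#' @param region `"local"` or `"distal"`.
#' @param log_transform Return `log(mean + pseudocount)`.
#' @param pseudocount Added before the log (default 1e-4).
#' @return The (optionally log) mean, or NA if the region holds no A/C
#'   positions.
#' @export
region_reactivity <- function(profile, target = c("stem", "loop"),
                              region = c("local", "distal"),
                              log_transform = FALSE, pseudocount = 1e-4) {
  pos <- region_positions(profile, target, region)
  bases <- seq_chars(profile$sequence)
  pos <- pos[bases[pos] %in% c("A", "C") & !is.na(profile$reactivity[pos])]
  if (length(pos) == 0) return(NA_real_)
  m <- mean(profile$reactivity[pos])
  if (log_transform) log(m + pseudocount) else m
}

#' Per-construct folding fidelity records
#'
#' Computes, for every profile, the global/local/distal AUROC and the mean
#' stem and loop reactivities of the local and distal regions, alongside the
#' construct's net dG.
#'
#' @param profiles List of `reactivity_profile` objects.
#' @return Data frame (class `fidelity_records`) with columns
#'   `construct_id`, `net_dg`, `auroc_global`, `auroc_local`, `auroc_distal`,
#'   `stem_local`, `stem_distal`, `loop_local`, `loop_distal`.
#' @export
fidelity_records <- function(profiles) {
  out <- do.call(rbind, lapply(profiles, function(p) data.frame(
    construct_id = p$construct_id, net_dg = p$net_dg,
    auroc_global = auroc(p, "global"),
    auroc_local = auroc(p, "local"),
    auroc_distal = auroc(p, "distal"),
    stem_local = region_reactivity(p, "stem", "local"),
    stem_distal = region_reactivity(p, "stem", "distal"),
    loop_local = region_reactivity(p, "loop", "local"),
    loop_distal = region_reactivity(p, "loop", "distal"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("fidelity_records", "data.frame")
  out
}

# Local stems of a profile, each as a matrix of pair positions ordered
# outward from the variable loop (row 1 = closing pair).
local_stems_from_loop <- function(profile) {
  pt <- profile$pair_table
  local <- profile$local
  loop_pos <- local[pt[local] == 0L]
  if (length(loop_pos) == 0) return(list())
  st <- parse_dotbracket(profile$construct_id, profile$sequence,
                         dotbracket_from_pairs(pt), quiet = TRUE)
  decomp <- decompose(st)
  hit <- NULL
  for (lp in c(decomp$hairpins, decomp$bulges, decomp$internal_loops)) {
    pos <- if (!is.null(lp$loop_positions)) lp$loop_positions
           else if (!is.null(lp$bulge_positions)) lp$bulge_positions
           else c(lp$side5_positions, lp$side3_positions)
    if (all(loop_pos %in% pos) && all(pos %in% loop_pos)) { hit <- lp; break }
  }
  if (is.null(hit)) return(list())
  adj <- decomp$adjacency[[hit$label]]
  lapply(adj, function(lab) {
    s <- decomp$stems[decomp$stems$label == lab, ]
    open <- s$start5:s$end5
    pairs <- cbind(open, pt[open])
    # order outward from the loop: a pair's distance is the smallest
    # sequence separation between either of its strands and the loop run
    d <- vapply(seq_len(nrow(pairs)), function(k)
      min(abs(outer(pairs[k, ], loop_pos, "-"))), 0)
    pairs[order(d), , drop = FALSE]
  })
}

#' Per-position stem reactivity profile by net-dG bin
#'
#' Mean reactivity (A/C nucleotides) of the k-th base pair counted outward
#' from the variable loop (position 1 = closing pair), averaged within bins
#' of net dG, with normal-approximation 95% confidence intervals. For
#' two-way junctions the per-construct value at position k is the mean over
#' the two flanking stems wherever both have a pair at k. Bins contributing
#' fewer than `min_n` nucleotides at a position are suppressed.
#'
#' @param profiles List of `reactivity_profile` objects.
#' @param bins Bin edges for net dG (left-closed); default matches the
#'   database analysis: -20, -15, -10, -5, 0, 10.
#' @param max_position Deepest stem position reported (default 6).
#' @param min_n Minimum contributing nucleotides per bin and position.
#' @return Data frame with `bin_left`, `bin_right`, `position`, `mean`,
#'   `ci_lo`, `ci_hi`, `n_nucleotides`.
#' @export
per_position_profile <- function(profiles, bins = c(-20, -15, -10, -5, 0, 10),
                                 max_position = 6, min_n = 70) {
  rows <- list()
  for (p in profiles) {
    if (is.na(p$net_dg)) next
    stems <- local_stems_from_loop(p)
    if (length(stems) == 0) next
    bases <- seq_chars(p$sequence)
    for (k in seq_len(max_position)) {
      present <- vapply(stems, function(m) nrow(m) >= k, TRUE)
      if (length(stems) > 1 && !all(present)) next  # need the pair on both stems
      if (!any(present)) next
      vals <- c(); nn <- 0L
      for (m in stems[present]) {
        pos <- m[k, ]
        ok <- bases[pos] %in% c("A", "C") & !is.na(p$reactivity[pos])
        if (any(ok)) {
          vals <- c(vals, mean(p$reactivity[pos[ok]]))
          nn <- nn + sum(ok)
        }
      }
      if (length(vals) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        net_dg = p$net_dg, position = k, value = mean(vals), n_nt = nn)
    }
  }
  if (length(rows) == 0) {
    warning("no bin reaches the minimum nucleotide count; empty profile")
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      position = integer(0), mean = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      n_nucleotides = integer(0)))
  }
  d <- do.call(rbind, rows)
  d$bin <- cut(d$net_dg, breaks = bins, right = FALSE)
  d <- d[!is.na(d$bin), , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, list(d$bin, d$position), drop = TRUE),
    function(g) {
      n_nt <- sum(g$n_nt)
      m <- mean(g$value)
      se <- if (nrow(g) > 1) stats::sd(g$value) / sqrt(nrow(g)) else 0
      data.frame(bin_left = bins[as.integer(g$bin[1])],
                 bin_right = bins[as.integer(g$bin[1]) + 1L],
                 position = g$position[1], mean = m,
                 ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
                 n_nucleotides = n_nt)
    }))
  out <- out[out$n_nucleotides >= min_n, , drop = FALSE]
  if (nrow(out) == 0) warning("no bin reaches the minimum nucleotide count")
  out <- out[order(out$bin_left, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the Hill fidelity curve to binned AUROC data
#'
#' Local AUROC values are averaged in bins of `bin_width` kcal/mol net dG,
#' the stability axis is s = s_offset - net dG (so larger s means more
#' stabilization), and the bin means are fit by bounded nonlinear least
#' squares to the Hill curve f(s) = A0 + (1 - A0) s^h / (s50^h + s^h), whose
#' plateau is fixed at 1. The AUROC = 0.9 crossing is solved from the fitted
#' parameters and reported on the net-dG scale as g09 = s_offset - s*, the
#' minimum local stability for consistent folding; g09 is NA when the fitted
#' curve stays below 0.9 over the observed stability range.
#'
#' @param fidelity A `fidelity_records` data frame (or any data frame with
#'   `net_dg` and `auroc_local`).
#' @param bin_width Net-dG bin width, kcal/mol (default 0.2).
#' @param s_offset Stability-axis transform constant (default 10).
#' @param min_bins Minimum nonempty bins (default 6); the bins must span at
#'   least 3 kcal/mol.
#' @return A `hill_fit`: list with `a0`, `h`, `s50`, `s_offset`, `g09`,
#'   `rss`, `n_bins`, `bins` (data frame of bin centers, mean AUROC, count).
#' @export
fit_hill <- function(fidelity, bin_width = 0.2, s_offset = 10, min_bins = 6) {
  d <- fidelity[is.finite(fidelity$net_dg) & is.finite(fidelity$auroc_local), ]
  if (nrow(d) == 0) stop("no records with defined net_dg and auroc_local")
  lefts <- floor(d$net_dg / bin_width) * bin_width
  sp <- split(d$auroc_local, lefts)
  bins <- data.frame(bin_center = as.numeric(names(sp)) + bin_width / 2,
                     auroc = vapply(sp, mean, 0),
                     n = vapply(sp, length, 0L), row.names = NULL)
  if (nrow(bins) < min_bins) {
    stop("need at least ", min_bins, " nonempty bins, got ", nrow(bins))
  }
  if (diff(range(bins$bin_center)) < 3) {
    stop("bins span ", sprintf("%.2f", diff(range(bins$bin_center))),
         " kcal/mol; need >= 3")
  }
  bins$s <- s_offset - bins$bin_center
  fit <- tryCatch(
    minpack.lm::nlsLM(
      auroc ~ a0 + (1 - a0) * s^h / (s50^h + s^h), data = bins,
      start = list(a0 = 0.5, h = 4, s50 = max(1, stats::median(bins$s))),
      lower = c(a0 = 0.3, h = 1e-3, s50 = 1e-3),
      upper = c(a0 = 0.9, h = 20, s50 = 30),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit did not converge: ", conditionMessage(e),
                             " (", nrow(bins), " bins, AUROC range ",
                             sprintf("%.2f-%.2f", min(bins$auroc),
                                     max(bins$auroc)), ")", call. = FALSE))
  cf <- stats::coef(fit)
  a0 <- unname(cf["a0"]); h <- unname(cf["h"]); s50 <- unname(cf["s50"])
  r <- (0.9 - a0) / (1 - a0)
  s_star <- s50 * (r / (1 - r))^(1 / h)
  # fitted value at the most stable observed bin
  s_max <- max(bins$s)
  f_max <- a0 + (1 - a0) * s_max^h / (s50^h + s_max^h)
  g09 <- if (f_max < 0.9) NA_real_ else s_offset - s_star
  structure(list(a0 = a0, h = h, s50 = s50, s_offset = s_offset, g09 = g09,
                 rss = sum(stats::resid(fit)^2), n_bins = nrow(bins),
                 bins = bins), class = "hill_fit")
}

#' Evaluate a fitted Hill fidelity curve at net-dG values
#'
#' @param fit A `hill_fit`.
#' @param net_dg Net dG values, kcal/mol.
#' @return Fitted AUROC values.
#' @export
predict_hill <- function(fit, net_dg) {
  s <- fit$s_offset - net_dg
  s <- pmax(s, 0)
  fit$a0 + (1 - fit$a0) * s^fit$h / (fit$s50^fit$h + s^fit$h)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("hill_fit: A0 = %.3f, h = %.2f, s50 = %.2f ",
                     "(s = %.0f - net dG); AUROC 0.9 at net dG %s kcal/mol; ",
                     "%d bins, RSS %.4g\n"),
              x$a0, x$h, x$s50, x$s_offset,
              ifelse(is.na(x$g09), "NA", sprintf("%.2f", x$g09)),
              x$n_bins, x$rss))
  invisible(x)
}

#' Per-construct regression of reactivity (or fidelity) on net dG
#'
#' Ordinary least squares on per-construct points (not bins), e.g. of log
#' mean local stem reactivity against the variable loop's net dG, and its
#' distal-control counterpart.
#'
#' @param fidelity A `fidelity_records` data frame.
#' @param y Response column: one of `stem_local`, `stem_distal`,
#'   `loop_local`, `loop_distal`, `auroc_local`, `auroc_distal`,
#'   `auroc_global`.
#' @param log_transform Natural-log the response (with `pseudocount`), the
#'   standard choice for reactivity means.
#' @param pseudocount Added before the log.
#' @param min_n Minimum usable records (default 10).
#' @return A `regression_result` with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_fidelity <- function(fidelity, y = "stem_local", log_transform = TRUE,
                             pseudocount = 1e-4, min_n = 10) {
  x <- fidelity$net_dg
  yy <- fidelity[[y]]
  if (log_transform) yy <- log(yy + pseudocount)
  keep <- is.finite(x) & is.finite(yy)
  x <- x[keep]; yy <- yy[keep]
  if (length(x) < min_n) stop("fewer than ", min_n, " usable records")
  if (stats::var(x) == 0) stop("degenerate regressor: net_dg has zero variance")
  fit <- stats::lm(yy ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (stats::var(yy) == 0) 1 else
                   stats::cor(yy, stats::fitted(fit))^2,
                 n = length(x)), class = "regression_result")
}

#' Read reactivity profiles from a TSV table plus designed structures
#'
#' The reactivity table has columns `construct_id`, `position`, `base`,
#' `mutation_fraction` and optionally `depth`; designed structures come as a
#' dot-bracket file (`id<TAB>sequence<TAB>dotbracket` per line, or the
#' two-column CSV variant `id,dotbracket` with sequence taken from the
#' table). The manifest (optional) supplies `construct_id`, `net_dg` and the
#' local region as `local_start..local_end`.
#'
#' @param reactivity_path TSV of per-position reactivities.
#' @param structures_path Dot-bracket file keyed by construct id.
#' @param manifest_path Optional TSV with `construct_id`, `net_dg`, `local`.
#' @return List of `reactivity_profile` objects.
#' @export
read_reactivity_tsv <- function(reactivity_path, structures_path,
                                manifest_path = NULL) {
  tab <- utils::read.table(reactivity_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("construct_id", "position", "base", "mutation_fraction")
  if (!all(need %in% names(tab))) {
    stop("reactivity table must have columns: ", paste(need, collapse = ", "))
  }
  sts <- read_dotbracket_file(structures_path)
  man <- if (!is.null(manifest_path)) {
    utils::read.table(manifest_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  profiles <- list()
  for (id in unique(tab$construct_id)) {
    g <- tab[tab$construct_id == id, ]
    g <- g[order(g$position), ]
    st <- sts[[id]]
    if (is.null(st)) { warning("no designed structure for '", id, "'; skipped"); next }
    rx <- rep(NA_real_, st$length)
    rx[g$position] <- g$mutation_fraction
    dp <- rep(NA_real_, st$length)
    if ("depth" %in% names(g)) dp[g$position] <- g$depth
    net <- NA_real_; local <- integer(0)
    if (!is.null(man)) {
      idcol <- if ("construct_id" %in% names(man)) "construct_id" else "id"
      if (id %in% man[[idcol]]) {
        mrow <- man[man[[idcol]] == id, ][1, ]
        if ("net_dg" %in% names(mrow)) net <- mrow$net_dg
        if ("local" %in% names(mrow) && nzchar(mrow$local)) {
          local <- string_to_ranges(gsub("\\.\\.", "-", mrow$local))
        }
      }
    }
    profiles[[id]] <- reactivity_profile(id, st$sequence, st$pair_table, rx,
                                         local = local, net_dg = net,
                                         depth = dp)
  }
  profiles
}

# dot-bracket file: "id<TAB>sequence<TAB>structure" lines (or ',' separated)
read_dotbracket_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[\t,]")[[1]]
    if (length(parts) < 3) stop("malformed dot-bracket line: ", ln)
    out[[parts[1]]] <- parse_dotbracket(parts[1], parts[2], parts[3],
                                        quiet = TRUE)
  }
  out
}

#' Write fidelity records / profiles to TSV
#'
#' @param fidelity A `fidelity_records` data frame.
#' @param path Output path.
#' @export
write_fidelity_tsv <- function(fidelity, path) {
  utils::write.table(as.data.frame(fidelity), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
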