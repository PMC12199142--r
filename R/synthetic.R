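# Synthetic inputs with the statistical structure the analysis assumes:
# random nested secondary structures, substructure databases with tunable
# linear loop-stem compensation, and DMS reactivity profiles from a
# two-state local-unfolding model. Outputs use exactly the containers the
# real pipeline consumes, so synthetic and real data are interchangeable.

# draw one canonical pair, optionally allowing G:U wobbles
random_pair <- function(gu_prob = 0.15) {
  kinds <- c("GC", "CG", "AU", "UA", "GU", "UG")
  w <- c(rep((1 - gu_prob) / 4, 4), rep(gu_prob / 2, 2))
  strsplit(sample(kinds, 1, prob = w), "")[[1]]
}

#' Random single-branch secondary structure
#'
#' Generates a structure with one helix path from the exterior to a terminal
#' hairpin, interrupted by a random number of bulges and internal loops —
#' the structure class on which the component-energy sum equals the full
#' nearest-neighbor structure energy (no multiloop terms). Sequences are
#' drawn so that every pair is canonical.
#'
#' @param target_length Approximate nucleotide count (the realized length
#'   varies with the drawn geometry).
#' @param max_junctions Maximum number of two-way junctions.
#' @param gu_prob Probability that a drawn pair is a G:U wobble.
#' @return An `rna_structure`.
#' @export
random_single_branch <- function(target_length = 50, max_junctions = 3,
                                 gu_prob = 0.15) {
  n_j <- sample(0:max_junctions, 1)
  n_stems <- n_j + 1L
  hp_size <- sample(3:8, 1)
  tail5 <- sample(0:3, 1); tail3 <- sample(0:3, 1)
  budget <- target_length - hp_size - tail5 - tail3
  stem_lens <- pmax(1L, stats::rmultinom(1, max(n_stems * 2L, budget %/% 3),
                                         rep(1, n_stems))[, 1])
  juncs <- replicate(n_j, {
    if (stats::runif(1) < 0.5) {
      list(n5 = sample(1:4, 1), n3 = 0L)            # bulge (random side below)
    } else {
      list(n5 = sample(1:3, 1), n3 = sample(1:3, 1)) # internal loop
    }
  }, simplify = FALSE)
  juncs <- lapply(juncs, function(j) {
    if (j$n3 == 0L && stats::runif(1) < 0.5) list(n5 = 0L, n3 = j$n5) else j
  })
  rand_nt <- function(k) sample(c("A", "C", "G", "U"), k, replace = TRUE)
  s5 <- list(); s3 <- list(); d5 <- list(); d3 <- list()
  push <- function(chars5, db5, chars3, db3) {
    k <- length(s5) + 1L
    s5[[k]] <<- chars5; d5[[k]] <<- rep(db5, length(chars5))
    s3[[k]] <<- chars3; d3[[k]] <<- rep(db3, length(chars3))
  }
  push(rand_nt(tail5), ".", rand_nt(tail3), ".")
  for (k in seq_len(n_stems)) {
    pairs <- t(vapply(seq_len(stem_lens[k]), function(i) random_pair(gu_prob),
                      character(2)))
    push(pairs[, 1], "(", rev(pairs[, 2]), ")")
    if (k <= n_j) {
      push(rand_nt(juncs[[k]]$n5), ".", rand_nt(juncs[[k]]$n3), ".")
    }
  }
  seqn <- paste(c(unlist(s5), rand_nt(hp_size), unlist(rev(s3))),
                collapse = "")
  db <- paste(c(unlist(d5), rep(".", hp_size), unlist(rev(d3))),
              collapse = "")
  parse_dotbracket(paste0("sb_", paste(sample(letters, 6, TRUE), collapse = "")),
                   seqn, db, quiet = TRUE)
}

#' Random nested secondary structure (with multiloops)
#'
#' Recursive generator over the full nested structure grammar: exterior
#' tails and between-helix runs, helices, hairpins, bulges, internal loops
#' and multiloops. Used by the decomposition property tests.
#'
#' @param target_length Approximate nucleotide count.
#' @param branch_prob Probability that an enclosed region becomes a
#'   multiloop rather than a continued helix path.
#' @return An `rna_structure`.
#' @export
random_nested_structure <- function(target_length = 60, branch_prob = 0.25) {
  rand_nt <- function(k) sample(c("A", "C", "G", "U"), k, replace = TRUE)
  # returns list(seq = chars, db = chars)
  gen_region <- function(budget, depth) {
    if (budget < 8 || depth > 6) {
      k <- max(3L, min(budget, sample(3:6, 1)))
      return(list(seq = rand_nt(k), db = rep(".", k)))  # hairpin interior
    }
    if (stats::runif(1) < branch_prob && budget >= 20) {
      # multiloop: 2-3 branches separated by unpaired runs
      nb <- sample(2:3, 1)
      parts_s <- list(rand_nt(sample(0:2, 1)))
      parts_d <- list(rep(".", length(parts_s[[1]])))
      for (b in seq_len(nb)) {
        h <- gen_helix(max(10, budget %/% nb - 3), depth + 1)
        gap <- rand_nt(sample(0:3, 1))
        parts_s <- c(parts_s, list(h$seq, gap))
        parts_d <- c(parts_d, list(h$db, rep(".", length(gap))))
      }
      return(list(seq = unlist(parts_s), db = unlist(parts_d)))
    }
    # two-way junction continuing into a helix, or terminal hairpin
    if (stats::runif(1) < 0.5 && budget >= 14) {
      n5 <- sample(0:3, 1); n3 <- sample(0:3, 1)
      if (n5 + n3 == 0) n5 <- 1L
      h <- gen_helix(budget - n5 - n3, depth + 1)
      return(list(seq = c(rand_nt(n5), h$seq, rand_nt(n3)),
                  db = c(rep(".", n5), h$db, rep(".", n3))))
    }
    k <- max(3L, min(budget, sample(3:7, 1)))
    list(seq = rand_nt(k), db = rep(".", k))
  }
  gen_helix <- function(budget, depth) {
    len <- sample(1:5, 1)
    pairs <- t(vapply(seq_len(len), function(i) random_pair(), character(2)))
    inner <- gen_region(budget - 2 * len, depth)
    list(seq = c(pairs[, 1], inner$seq, rev(pairs[, 2])),
         db = c(rep("(", len), inner$db, rep(")", len)))
  }
  t5 <- sample(0:3, 1); t3 <- sample(0:3, 1)
  h <- gen_helix(target_length - t5 - t3, 1)
  seqn <- paste(c(rand_nt(t5), h$seq, rand_nt(t3)), collapse = "")
  db <- paste(c(rep(".", t5), h$db, rep(".", t3)), collapse = "")
  parse_dotbracket(paste0("nested_", paste(sample(letters, 6, TRUE), collapse = "")),
                   seqn, db, quiet = TRUE)
}

#' Configuration for the substructure-database simulator
#'
#' The generative model behind the compensation analysis: loop free energies
#' drawn from a truncated exponential on \[0.5, 12\] kcal/mol, and each
#' adjacent stem's free energy a noisy linear function of its loop's,
#' stem = alpha * loop + beta + family_offset + N(0, sigma). Records are
#' grouped into synthetic structures of `loops_per_structure` loops so the
#' rotation control has eligible structures. The defaults emulate the
#' hairpin compensation signature of large structure databases (median net
#' dG near -2.7 kcal/mol with spread of order 1 kcal/mol at sigma = 1).
#'
#' @param n_per_type Records per loop type.
#' @param alpha Compensation slope (stem dG per loop dG).
#' @param beta Compensation intercept, kcal/mol.
#' @param sigma Stem noise SD, kcal/mol.
#' @param loop_rate Rate of the exponential loop-dG distribution (mean
#'   0.5 + 1/rate before truncation at 12).
#' @param loop_range Truncation interval for loop dG, kcal/mol.
#' @param family_offsets Named additive shifts by family; records are
#'   assigned families uniformly.
#' @param loops_per_structure Loops of each type per synthetic structure
#'   (> 3 keeps structures eligible for the rotation control).
#' @param loop_types Which loop types to simulate.
#' @return A `db_sim_config` list.
#' @export
db_sim_config <- function(n_per_type = 2000, alpha = -0.8, beta = -3.2,
                          sigma = 1.0, loop_rate = 0.4,
                          loop_range = c(0.5, 12),
                          family_offsets = c(generic = 0),
                          loops_per_structure = 5,
                          loop_types = LOOP_TYPES) {
  stopifnot(sigma >= 0, loops_per_structure >= 1)
  structure(list(n_per_type = n_per_type, alpha = alpha, beta = beta,
                 sigma = sigma, loop_rate = loop_rate,
                 loop_range = loop_range, family_offsets = family_offsets,
                 loops_per_structure = loops_per_structure,
                 loop_types = loop_types),
            class = "db_sim_config")
}

# truncated exponential by rejection (truncation mass is small)
rtrunc_exp <- function(n, rate, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- range[1] + stats::rexp(2 * (n - length(out)) + 10, rate)
    out <- c(out, x[x <= range[2]])
  }
  out[seq_len(n)]
}

#' Simulate a substructure-record database with linear compensation
#'
#' @param config A `db_sim_config`.
#' @param seed RNG seed.
#' @return An `lsc_records` data frame, as from [make_records()]. Stem
#'   labels within each synthetic structure mirror a helix chain: hairpin
#'   loops own one stem each; bulges and internal loops of consecutive
#'   loops share one flanking stem, as in a real chain of two-way junctions.
#' @export
simulate_structure_records <- function(config = db_sim_config(), seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fams <- names(config$family_offsets)
  rows <- list()
  for (lt in config$loop_types) {
    n <- config$n_per_type
    k <- config$loops_per_structure
    n_struct <- ceiling(n / k)
    struct_fam <- sample(fams, n_struct, replace = TRUE)
    made <- 0L
    for (si in seq_len(n_struct)) {
      kk <- min(k, n - made)
      loop_dg <- rtrunc_exp(kk, config$loop_rate, config$loop_range)
      off <- config$family_offsets[[struct_fam[si]]]
      stem_of <- function(ld) config$alpha * ld + config$beta + off +
        stats::rnorm(length(ld), 0, config$sigma)
      if (lt == "hairpin") {
        s1 <- stem_of(loop_dg); s2 <- rep(NA_real_, kk)
        lab1 <- paste0("S", seq_len(kk)); lab2 <- rep(NA_character_, kk)
        net <- loop_dg + s1
      } else {
        # each junction flanked by its own two stems, both compensating
        # the same loop (independent noise)
        s1 <- stem_of(loop_dg); s2 <- stem_of(loop_dg)
        lab1 <- paste0("S", 2L * seq_len(kk) - 1L)
        lab2 <- paste0("S", 2L * seq_len(kk))
        net <- loop_dg + (s1 + s2) / 2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = sprintf("sim_%s_%05d", lt, si),
        loop_label = paste0(toupper(substr(lt, 1, 1)), seq_len(kk)),
        loop_type = lt, loop_start = 10L * seq_len(kk),
        loop_size = pmax(1L, round(loop_dg)),
        loop_dg = loop_dg, stem_label1 = lab1, stem_label2 = lab2,
        stem_dg1 = s1, stem_dg2 = s2,
        stem_len1 = 5L, stem_len2 = if (lt == "hairpin") NA_integer_ else 5L,
        net_dg = net, family = struct_fam[si], taxon = NA_character_,
        stringsAsFactors = FALSE)
      made <- made + kk
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, names(empty_records())]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- 0L
  class(out) <- c("lsc_records", "data.frame")
  out
}

#' Configuration for the two-state DMS reactivity simulator
#'
#' Each construct occupies a designed-fold state with probability
#' f(s) = s^h / (s50^h + s^h), where s = s_offset - net dG of the variable
#' loop, and a locally divergent state otherwise. Designed-paired positions
#' in the LOCAL region draw their underlying mutation rate from the
#' paired-state distribution with probability f and from the unpaired-state
#' distribution otherwise; DISTAL positions always draw from their designed
#' state's distribution (the locality assumption under test). Observed
#' reactivity is Binomial(depth, rate) / depth.
#'
#' Reactivity distributions are log-normal with means 0.01 (paired) and
#' 0.10 (unpaired), typical DMS mutation-fraction scales.
#'
#' @param h_true,s50_true Hill coefficient and midpoint of the folded
#'   fraction on the stability axis.
#' @param s_offset Stability-axis transform constant (matches [fit_hill()]).
#' @param paired_meanlog,paired_sdlog Log-normal parameters of the
#'   paired-state rate (defaults give mean 0.01).
#' @param unpaired_meanlog,unpaired_sdlog Unpaired-state rate (mean 0.10).
#' @param loop_depression Multiplicative factor on loop reactivity in the
#'   folded state (weak trend, cosmetic).
#' @param depth_mean Poisson mean read depth per position.
#' @return A `dms_sim_config` list.
#' @export
dms_sim_config <- function(h_true = 4, s50_true = 14, s_offset = 10,
                           paired_meanlog = log(0.01) - 0.5^2 / 2,
                           paired_sdlog = 0.5,
                           unpaired_meanlog = log(0.10) - 0.5^2 / 2,
                           unpaired_sdlog = 0.5,
                           loop_depression = 0.8, depth_mean = 5000) {
  cfg <- list(h_true = h_true, s50_true = s50_true, s_offset = s_offset,
              paired_meanlog = paired_meanlog, paired_sdlog = paired_sdlog,
              unpaired_meanlog = unpaired_meanlog,
              unpaired_sdlog = unpaired_sdlog,
              loop_depression = loop_depression, depth_mean = depth_mean)
  mp <- exp(paired_meanlog + paired_sdlog^2 / 2)
  mu <- exp(unpaired_meanlog + unpaired_sdlog^2 / 2)
  if (mu <= mp) stop("mean unpaired reactivity must exceed mean paired reactivity")
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  structure(cfg, class = "dms_sim_config")
}

# folded fraction of the two-state model at a given net dG
folded_fraction <- function(net_dg, config) {
  s <- pmax(config$s_offset - net_dg, 0)
  s^config$h_true / (config$s50_true^config$h_true + s^config$h_true)
}

#' Simulate DMS reactivity profiles for a designed library
#'
#' @param library A `designed_library` from [generate_library()] (or any
#'   list with a compatible `manifest` and `regions`).
#' @param config A `dms_sim_config`.
#' @param seed RNG seed.
#' @return List of `reactivity_profile` objects; constructs without a net
#'   dG are skipped with a message.
#' @export
simulate_dms <- function(library, config = dms_sim_config(), seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  man <- library$manifest
  profiles <- list(); skipped <- 0L
  for (k in seq_len(nrow(man))) {
    if (!is.finite(man$net_dg[k])) { skipped <- skipped + 1L; next }
    st <- parse_dotbracket(man$id[k], man$sequence[k], man$dotbracket[k],
                           quiet = TRUE)
    n <- st$length
    local <- library$regions[[man$id[k]]]$local
    f <- folded_fraction(man$net_dg[k], config)
    paired <- st$pair_table > 0L
    in_local <- seq_len(n) %in% local
    rp <- stats::rlnorm(n, config$paired_meanlog, config$paired_sdlog)
    ru <- stats::rlnorm(n, config$unpaired_meanlog, config$unpaired_sdlog)
    # per-position underlying mutation rate
    rate <- numeric(n)
    # distal positions: designed state regardless of the local fold
    rate[!in_local & paired] <- rp[!in_local & paired]
    rate[!in_local & !paired] <- ru[!in_local & !paired]
    # local stems: two-state mixture of designed-paired and divergent states
    ls <- in_local & paired
    unfolded <- stats::runif(n) >= f
    rate[ls] <- ifelse(unfolded[ls], ru[ls], rp[ls])
    # local loops: unpaired either way, slightly depressed when folded
    ll <- in_local & !paired
    rate[ll] <- ifelse(unfolded[ll], ru[ll], ru[ll] * config$loop_depression)
    depth <- pmax(1, stats::rpois(n, config$depth_mean))
    obs <- stats::rbinom(n, depth, pmin(rate, 1)) / depth
    profiles[[man$id[k]]] <- reactivity_profile(
      man$id[k], man$sequence[k], st$pair_table, obs, local = local,
      net_dg = man$net_dg[k], depth = depth)
  }
  if (skipped > 0) message(skipped, " construct(s) without net dG skipped")
  profiles
}

#' Monte-Carlo expectation of local AUROC on a net-dG grid
#'
#' Semi-analytic oracle for recovery tests: at each grid point the expected
#' A/C local AUROC is computed by Monte-Carlo integration over the two-state
#' mixture, the log-normal rate distributions and binomial depth noise
#' (`n_draws` positive and negative draws per point), independently of the
#' pipeline's per-construct path.
#'
#' @param config A `dms_sim_config`.
#' @param grid Net-dG grid, kcal/mol.
#' @param n_draws Draws per class per grid point (default 1e5).
#' @param seed RNG seed.
#' @return Data frame with `net_dg` and `expected_auroc`.
#' @export
expected_auroc_curve <- function(config = dms_sim_config(), grid,
                                 n_draws = 1e5, seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  vals <- vapply(grid, function(g) {
    f <- folded_fraction(g, config)
    depth <- pmax(1, stats::rpois(2 * n_draws, config$depth_mean))
    ru <- stats::rlnorm(n_draws, config$unpaired_meanlog, config$unpaired_sdlog)
    folded <- stats::runif(n_draws) < f
    pos_rate <- ifelse(folded, ru * config$loop_depression, ru)
    rp <- stats::rlnorm(n_draws, config$paired_meanlog, config$paired_sdlog)
    ru2 <- stats::rlnorm(n_draws, config$unpaired_meanlog, config$unpaired_sdlog)
    folded2 <- stats::runif(n_draws) < f
    neg_rate <- ifelse(folded2, rp, ru2)
    pos <- stats::rbinom(n_draws, depth[seq_len(n_draws)],
                         pmin(pos_rate, 1)) / depth[seq_len(n_draws)]
    neg <- stats::rbinom(n_draws, depth[n_draws + seq_len(n_draws)],
                         pmin(neg_rate, 1)) / depth[n_draws + seq_len(n_draws)]
    auroc_rank(c(pos, neg), c(rep(TRUE, n_draws), rep(FALSE, n_draws)))
  }, 0)
  data.frame(net_dg = grid, expected_auroc = vals)
}
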