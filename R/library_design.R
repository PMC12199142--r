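# Randomized RNA construct libraries on a triply bulged hairpin template,
# under composition, length, energy-constancy and Hamming-distance
# constraints. The template chain is, 5' to 3': flank, stem1, bulge1, stem2,
# junction2, stem3, bulge3, stem4, hairpin loop, return strands, 3' flank.
# One slot varies per library: the hairpin loop and its closing stem
# (hairpin library), or junction2 with its two flanking stems (bulge and
# internal-loop libraries); every other slot uses constant-energy elements.

#' Design constraints for library generation
#'
#' Defaults follow the published template: stems 4-12 bp, hairpin loops
#' 3-11 nt, bulges 1-9 nt, internal loops 1-9 unpaired nt in total
#' (interpreted as the two-sided total with each side >= 1), loops drawn
#' from \{A, C\}, minimum pairwise Hamming distance 20, sequence lengths
#' within 20% of the library mean, and constant stems with G:C/C:G closing
#' pairs, a fixed GC fraction of 0.6 and no G:U pairs.
#'
#' @param stem_len Range of variable stem lengths (bp).
#' @param hairpin_size Range of hairpin loop sizes (nt).
#' @param bulge_size Range of bulge sizes (nt).
#' @param internal_size Range of internal-loop total unpaired counts (both
#'   sides summed, each side >= 1).
#' @param loop_alphabet Loop residue alphabet.
#' @param min_hamming Minimum pairwise distance between constructs. For
#'   unequal lengths the distance is the positional mismatch count over the
#'   shorter length plus the length difference.
#' @param length_window Allowed fractional deviation from the mean length.
#' @param const_gc GC fraction of constant-energy stems.
#' @param stem_gc_grid GC-fraction grid for variable stems.
#' @param stem_gu_max Maximum G:U pairs per variable stem.
#' @param max_attempts_per_construct Rejection-sampling budget multiplier.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(stem_len = c(4, 12), hairpin_size = c(3, 11),
                               bulge_size = c(1, 9), internal_size = c(1, 9),
                               loop_alphabet = c("A", "C"), min_hamming = 20,
                               length_window = 0.2, const_gc = 0.6,
                               stem_gc_grid = c(0, 0.25, 0.5, 0.75, 1),
                               stem_gu_max = 2,
                               max_attempts_per_construct = 50) {
  structure(list(stem_len = stem_len, hairpin_size = hairpin_size,
                 bulge_size = bulge_size, internal_size = internal_size,
                 loop_alphabet = loop_alphabet, min_hamming = min_hamming,
                 length_window = length_window, const_gc = const_gc,
                 stem_gc_grid = stem_gc_grid, stem_gu_max = stem_gu_max,
                 max_attempts_per_construct = max_attempts_per_construct),
            class = "design_constraints")
}

#' Template specification for the triply bulged hairpin
#'
#' Packaged default geometry: 5' flank `GG` (transcription leader), three
#' constant stems of 5 bp, constant single-A bulges, a constant `AACA`
#' tetraloop where the hairpin is not the variable slot, and a 3' flank
#' complementary to the reverse-transcription primer. The exact constant
#' sequences are stand-ins for the deposited designs; they satisfy the same
#' constraint set.
#'
#' @param variable_slot `"hairpin"`, `"bulge"` or `"internal"`: which loop
#'   (with its flanking stem or stems) varies.
#' @param const_stem_len Length of constant-energy stems (default 5; with
#'   the default GC fraction 0.6 this gives exactly 3 G:C pairs).
#' @param flank5,flank3 Unpaired flanking sequences.
#' @return A `template_spec` list.
#' @export
template_spec <- function(variable_slot = c("hairpin", "bulge", "internal"),
                          const_stem_len = 5,
                          flank5 = "GG",
                          flank3 = "AAAGAAACAACAACAACAAC") {
  variable_slot <- match.arg(variable_slot)
  structure(list(variable_slot = variable_slot,
                 const_stem_len = const_stem_len,
                 const_bulge = "A", const_hairpin = "AACA",
                 flank5 = flank5, flank3 = flank3),
            class = "template_spec")
}

# random orientation of a pair kind: "GC" -> c("G","C") or c("C","G"), etc.
orient_pair <- function(kind) {
  b <- strsplit(kind, "")[[1]]
  if (stats::runif(1) < 0.5) b else rev(b)
}

#' Sample a constant-energy stem
#'
#' Constant-energy stems pin their free energy by construction: both closing
#' pairs are G:C or C:G, the GC fraction is fixed, and no G:U pairs occur;
#' only pair order and orientation are randomized, so the stacking energy
#' varies little across resamples (the design target is a standard deviation
#' of at most 0.5 kcal/mol at fixed length).
#'
#' @param length Stem length in bp (4-12).
#' @param gc_fraction GC fraction; `gc_fraction * length` must be an integer
#'   >= 2 (the two closing pairs).
#' @return A `length` x 2 character matrix: column 1 the 5' strand base
#'   (outermost pair first), column 2 its partner.
#' @export
make_constant_stem <- function(length, gc_fraction = 0.6) {
  if (length < 4 || length > 12) stop("constant stem length must be in 4-12")
  n_gc <- gc_fraction * length
  if (abs(n_gc - round(n_gc)) > 1e-9) {
    stop("infeasible GC fraction ", gc_fraction, " at length ", length,
         ": non-integer pair count")
  }
  n_gc <- as.integer(round(n_gc))
  if (n_gc < 2) stop("GC fraction too low: both closing pairs must be G:C or C:G")
  interior <- sample(c(rep("GC", n_gc - 2L), rep("AU", length - n_gc)))
  kinds <- c("GC", interior, "GC")[seq_len(length)]
  if (length == 2) kinds <- c("GC", "GC")   # guard, not reachable with 4-12
  t(vapply(kinds, orient_pair, character(2)))
}

# variable stem: length, GC content and G:U count drawn from grids
sample_variable_stem <- function(constraints) {
  len <- sample(constraints$stem_len[1]:constraints$stem_len[2], 1)
  f <- sample(constraints$stem_gc_grid, 1)
  n_gc <- as.integer(round(f * len))
  gu_max <- min(constraints$stem_gu_max, len - n_gc)
  n_gu <- if (gu_max == 0) 0L else sample(0:gu_max, 1)
  n_au <- len - n_gc - n_gu
  kinds <- sample(c(rep("GC", n_gc), rep("AU", n_au), rep("GU", n_gu)))
  t(vapply(kinds, orient_pair, character(2)))
}

#' Sample one variable region
#'
#' Draws the variable loop (uniform size over its configured range,
#' residues from the loop alphabet) and its flanking variable stem(s)
#' (uniform length, GC-content and G:U-count grids).
#'
#' @param loop_type `"hairpin"`, `"bulge"` or `"internal"`.
#' @param constraints A `design_constraints` object.
#' @return List with `loop_type`, `loop5`, `loop3` (character vectors of
#'   loop residues; `loop3` empty except for internal loops) and `stems`
#'   (list of 1 or 2 pair matrices).
#' @export
sample_variable_region <- function(loop_type = c("hairpin", "bulge", "internal"),
                                   constraints = design_constraints()) {
  loop_type <- match.arg(loop_type)
  ab <- constraints$loop_alphabet
  draw <- function(k) sample(ab, k, replace = TRUE)
  if (loop_type == "hairpin") {
    size <- sample(constraints$hairpin_size[1]:constraints$hairpin_size[2], 1)
    list(loop_type = loop_type, loop5 = draw(size), loop3 = character(0),
         stems = list(sample_variable_stem(constraints)))
  } else if (loop_type == "bulge") {
    size <- sample(constraints$bulge_size[1]:constraints$bulge_size[2], 1)
    list(loop_type = loop_type, loop5 = draw(size), loop3 = character(0),
         stems = list(sample_variable_stem(constraints),
                      sample_variable_stem(constraints)))
  } else {
    lo <- max(2, constraints$internal_size[1])
    total <- sample(lo:constraints$internal_size[2], 1)
    n1 <- sample(seq_len(total - 1L), 1)
    list(loop_type = loop_type, loop5 = draw(n1), loop3 = draw(total - n1),
         stems = list(sample_variable_stem(constraints),
                      sample_variable_stem(constraints)))
  }
}

# Assemble one construct. Returns sequence, dot-bracket and the variable
# (local) region positions, with the variable loop positions separately.
assemble_construct <- function(id, template, var, constraints) {
  slot <- template$variable_slot
  cs <- function() make_constant_stem(template$const_stem_len,
                                      constraints$const_gc)
  # stems S1..S4 and junction unpaired runs j1..j3 (side5/side3 residues)
  stems <- list(cs(), NULL, NULL, NULL)
  juncs <- list(list(s5 = strsplit(template$const_bulge, "")[[1]], s3 = character(0)),
                NULL,
                list(s5 = strsplit(template$const_bulge, "")[[1]], s3 = character(0)))
  if (slot == "hairpin") {
    stems[[2]] <- cs(); stems[[3]] <- cs(); stems[[4]] <- var$stems[[1]]
    juncs[[2]] <- list(s5 = strsplit(template$const_bulge, "")[[1]],
                       s3 = character(0))
    loop <- var$loop5
  } else {
    stems[[2]] <- var$stems[[1]]; stems[[3]] <- var$stems[[2]]; stems[[4]] <- cs()
    juncs[[2]] <- list(s5 = var$loop5, s3 = var$loop3)
    loop <- strsplit(template$const_hairpin, "")[[1]]
  }
  flank5 <- strsplit(template$flank5, "")[[1]]
  flank3 <- strsplit(template$flank3, "")[[1]]

  seq_parts <- list(); db_parts <- list(); labels <- character(0)
  push <- function(chars, db, label) {
    k <- length(seq_parts) + 1L
    seq_parts[[k]] <<- chars; db_parts[[k]] <<- rep(db, length(chars))
    labels[k] <<- label
  }
  push(flank5, ".", "flank5")
  for (k in 1:4) {
    push(stems[[k]][, 1], "(", paste0("S", k, "_5"))
    if (k < 4) push(juncs[[k]]$s5, ".", paste0("J", k, "_5"))
  }
  push(loop, ".", "loop")
  for (k in 4:1) {
    push(rev(stems[[k]][, 2]), ")", paste0("S", k, "_3"))
    if (k > 1) push(rev(juncs[[k - 1L]]$s3), ".", paste0("J", k - 1L, "_3"))
  }
  push(flank3, ".", "flank3")

  lens <- vapply(seq_parts, length, 0L)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  span <- function(lab) {
    k <- which(labels == lab)
    if (lens[k] == 0L) integer(0) else starts[k]:ends[k]
  }
  if (slot == "hairpin") {
    loop_pos <- span("loop")
    local <- sort(c(span("S4_5"), loop_pos, span("S4_3")))
  } else {
    loop_pos <- sort(c(span("J2_5"), span("J2_3")))
    local <- sort(c(span("S2_5"), span("S3_5"), loop_pos,
                    span("S3_3"), span("S2_3")))
  }
  list(id = id,
       sequence = paste(unlist(seq_parts), collapse = ""),
       dotbracket = paste(unlist(db_parts), collapse = ""),
       loop_positions = loop_pos, local = local)
}

# distance between sequences of possibly unequal length: positional
# mismatches over the shorter length plus the length difference
seq_distance <- function(a, b) {
  m <- min(length(a), length(b))
  sum(a[seq_len(m)] != b[seq_len(m)]) + abs(length(a) - length(b))
}

#' Generate a randomized construct library
#'
#' Rejection-samples constructs on the template until `n` satisfy the
#' minimum pairwise distance, then applies the length-window post-filter
#' (constructs outside +/- `length_window` of the realized mean length are
#' removed, as in the published libraries). Each accepted construct is
#' decomposed and scored so its variable-loop net dG is part of the
#' manifest. Deterministic for a fixed seed.
#'
#' @param loop_type `"hairpin"`, `"bulge"` or `"internal"` library.
#' @param n Number of constructs to draw.
#' @param seed RNG seed (recorded in the result).
#' @param constraints A `design_constraints` object.
#' @param template A `template_spec`; defaults to the packaged template for
#'   `loop_type`.
#' @param params Turner parameters for scoring.
#' @return A `designed_library`: list with `manifest` (data frame: id,
#'   sequence, dotbracket, length, loop_type, loop_size, loop_dg,
#'   stem_mean_dg, net_dg), `regions` (per-id list with `local` and `loop`
#'   positions), `loop_type`, `seed`, `constraints`, `template`,
#'   `n_length_filtered`.
#' @export
generate_library <- function(loop_type = c("hairpin", "bulge", "internal"),
                             n = 100, seed = 1,
                             constraints = design_constraints(),
                             template = NULL,
                             params = load_turner_params()) {
  loop_type <- match.arg(loop_type)
  if (n < 1) stop("n must be >= 1")
  if (is.null(template)) template <- template_spec(loop_type)
  stopifnot(template$variable_slot == loop_type)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  accepted <- list(); accepted_chars <- list()
  attempts <- 0L
  budget <- constraints$max_attempts_per_construct * n
  while (length(accepted) < n && attempts < budget) {
    attempts <- attempts + 1L
    var <- sample_variable_region(loop_type, constraints)
    cand <- assemble_construct(sprintf("%s_%04d", loop_type, length(accepted) + 1L),
                               template, var, constraints)
    chars <- strsplit(cand$sequence, "")[[1]]
    ok <- TRUE
    for (ac in accepted_chars) {
      if (seq_distance(chars, ac) < constraints$min_hamming) { ok <- FALSE; break }
    }
    if (!ok) next
    accepted[[length(accepted) + 1L]] <- cand
    accepted_chars[[length(accepted)]] <- chars
  }
  if (length(accepted) < n) {
    stop("could not reach ", n, " constructs within ", budget,
         " attempts; achieved ", length(accepted))
  }
  # length-window post-filter around the realized mean
  lens <- vapply(accepted, function(a) nchar(a$sequence), 0L)
  mu <- mean(lens)
  keep <- abs(lens - mu) <= constraints$length_window * mu
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    message(n_filtered, " construct(s) outside +/-",
            constraints$length_window * 100, "% of mean length removed")
  }
  accepted <- accepted[keep]

  rows <- list(); regions <- list()
  for (a in accepted) {
    st <- parse_dotbracket(a$id, a$sequence, a$dotbracket, quiet = TRUE)
    en <- annotate_structure_energies(st, params)
    rec <- make_records(en)
    hit <- which(rec$loop_start == min(a$loop_positions) &
                   rec$loop_type == loop_type)
    if (length(hit) != 1) {
      stop("variable loop of '", a$id, "' not recovered by decomposition")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = a$id, sequence = a$sequence, dotbracket = a$dotbracket,
      length = nchar(a$sequence), loop_type = loop_type,
      loop_size = rec$loop_size[hit], loop_dg = rec$loop_dg[hit],
      stem_mean_dg = record_stem_stat(rec)[hit], net_dg = rec$net_dg[hit],
      stringsAsFactors = FALSE)
    regions[[a$id]] <- list(local = a$local, loop = a$loop_positions)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, regions = regions,
                 loop_type = loop_type, seed = seed,
                 constraints = constraints, template = template,
                 n_length_filtered = n_filtered),
            class = "designed_library")
}

#' @export
print.designed_library <- function(x, ...) {
  cat("designed_library (", x$loop_type, "): ", nrow(x$manifest),
      " constructs, seed ", x$seed, "; net dG range [",
      sprintf("%.2f", min(x$manifest$net_dg)), ", ",
      sprintf("%.2f", max(x$manifest$net_dg)), "] kcal/mol\n", sep = "")
  invisible(x)
}

#' Write a designed library to FASTA, dot-bracket and manifest files
#'
#' Emits `<prefix>.fasta` (sequences), `<prefix>_structures.tsv`
#' (id, sequence, dot-bracket) and `<prefix>_manifest.tsv` (design
#' manifest including per-construct energies, the local-region position
#' ranges and the RNG seed in a header comment).
#'
#' @param lib A `designed_library`.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_library <- function(lib, prefix) {
  fa <- paste0(prefix, ".fasta")
  writeLines(as.vector(rbind(paste0(">", lib$manifest$id),
                             lib$manifest$sequence)), fa)
  db <- paste0(prefix, "_structures.tsv")
  writeLines(paste(lib$manifest$id, lib$manifest$sequence,
                   lib$manifest$dotbracket, sep = "\t"), db)
  man <- paste0(prefix, "_manifest.tsv")
  m <- lib$manifest
  m$local <- vapply(m$id, function(id)
    ranges_to_string(lib$regions[[id]]$local), "")
  m$loop_positions <- vapply(m$id, function(id)
    ranges_to_string(lib$regions[[id]]$loop), "")
  con <- file(man, "w")
  writeLines(paste0("# designed_library loop_type=", lib$loop_type,
                    " seed=", lib$seed), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(fa, db, man))
}

# compress an integer position set to "a-b,c-d" run notation
ranges_to_string <- function(pos) {
  pos <- sort(unique(pos))
  if (length(pos) == 0) return("")
  br <- c(0, which(diff(pos) != 1), length(pos))
  paste(vapply(seq_len(length(br) - 1L), function(k) {
    a <- pos[br[k] + 1L]; b <- pos[br[k + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, ""), collapse = ",")
}

# inverse of ranges_to_string
string_to_ranges <- function(s) {
  if (!nzchar(s)) return(integer(0))
  unlist(lapply(strsplit(s, ",")[[1]], function(part) {
    ab <- as.integer(strsplit(part, "-")[[1]])
    if (length(ab) == 1) ab else ab[1]:ab[2]
  }))
}
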