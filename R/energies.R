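# Turner 2004 nearest-neighbor free energies per substructure at 37 C.
#
# Energies are handled internally as integer multiples of 10 cal/mol
# (decacal), the resolution of the published tables, and converted to
# kcal/mol at the interface. Loop-size extrapolation beyond 30 nt uses the
# Jacobson-Stockmayer term lxc*log(n/30) truncated to integer decacal, which
# keeps component sums bit-identical to reference nearest-neighbor totals on
# the same tables.

PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA", "NN")
BASE_ORDER5 <- c("N", "A", "C", "G", "U")
BASE_ORDER4 <- c("A", "C", "G", "U")

PARAM_SECTIONS <- c("stack", "mismatch_hairpin", "mismatch_internal",
                    "mismatch_internal_1n", "mismatch_internal_23",
                    "int11", "int21", "int22", "hairpin", "bulge", "internal",
                    "NINIO", "Misc", "Hexaloops", "Tetraloops", "Triloops")

# canonical pair type: CG=1 GC=2 GU=3 UG=4 AU=5 UA=6, 0 otherwise
pair_type <- function(b1, b2) {
  key <- paste0(b1, b2)
  m <- match(key, PAIR_NAMES[1:6])
  ifelse(is.na(m), 0L, m)
}

base5_index <- function(b) {
  m <- match(b, BASE_ORDER5)
  ifelse(is.na(m), 1L, m)   # unknown characters map to N
}

base4_index <- function(b) match(b, BASE_ORDER4)  # NA for non-ACGU

#' Load the packaged Turner 2004 free-energy tables
#'
#' Reads the tabular text assets shipped with the package (transcribed from
#' the published Turner 2004 nearest-neighbor set): stacking energies, loop
#' initiation by size, terminal mismatches, small internal-loop tables
#' (1x1, 2x1, 2x2), the Ninio asymmetry term, AU/GU helix-end penalty,
#' special hairpin sequences and the Jacobson-Stockmayer extrapolation
#' coefficient. All values are for 37 C in kcal/mol (stored as decacal
#' integers).
#'
#' @param path Path to the core table file. Defaults to the packaged asset.
#' @param int22_path Path to the 2x2 internal-loop table file.
#' @return A `turner_params` object (list of lookup arrays plus scalar
#'   coefficients `ninio_m`, `ninio_max`, `terminal_au`, `lxc`,
#'   `jacobson_coeff`, `temperature`, and zero-default auxiliary terms
#'   `c_bulge_bonus`, `c_hairpin_slope`, `c_hairpin_intercept`,
#'   `c_hairpin_of_3`).
#' @examples
#' p <- load_turner_params()
#' p$stack["CG", "GC"] / 100   # 5'CG3'/3'GC5' stack in kcal/mol
#' @export
load_turner_params <- function(path = NULL, int22_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "turner2004_dg.txt", package = "rnalsc",
                        mustWork = TRUE)
  }
  if (is.null(int22_path)) {
    int22_path <- system.file("extdata", "turner2004_int22_dg.txt",
                              package = "rnalsc", mustWork = TRUE)
  }
  sections <- read_param_sections(c(path, int22_path))
  need <- setdiff(PARAM_SECTIONS, names(sections))
  if (length(need) > 0) {
    stop("parameter table(s) absent: ", paste(need, collapse = ", "),
         if ("hairpin" %in% need) " (hairpin initiation table absent)" else "")
  }

  num <- function(name, n) {
    v <- sections[[name]]
    if (length(v) != n) {
      stop("malformed table '", name, "': expected ", n, " values, got ",
           length(v))
    }
    suppressWarnings(ifelse(v == "INF", Inf, as.numeric(v)))
  }
  # row-major stream -> R array: fill reversed dims, then transpose back
  arr <- function(name, dims) {
    aperm(array(num(name, prod(dims)), dim = rev(dims)), rev(seq_along(dims)))
  }
  special <- function(name) {
    v <- sections[[name]]
    stopifnot(length(v) %% 3 == 0)
    m <- matrix(v, ncol = 3, byrow = TRUE)
    stats::setNames(as.numeric(m[, 2]), m[, 1])   # dG column only
  }

  stack <- arr("stack", c(7, 7)); dimnames(stack) <- list(PAIR_NAMES, PAIR_NAMES)
  misc <- num("Misc", 2)
  ninio <- num("NINIO", 2)
  p <- list(
    stack = stack,
    mismatch_hairpin = arr("mismatch_hairpin", c(7, 5, 5)),
    mismatch_internal = arr("mismatch_internal", c(7, 5, 5)),
    mismatch_internal_1n = arr("mismatch_internal_1n", c(7, 5, 5)),
    mismatch_internal_23 = arr("mismatch_internal_23", c(7, 5, 5)),
    int11 = arr("int11", c(7, 7, 5, 5)),
    int21 = arr("int21", c(7, 7, 5, 5, 5)),
    int22 = arr("int22", c(6, 6, 4, 4, 4, 4)),
    hairpin_init = num("hairpin", 31),    # sizes 0..30
    bulge_init = num("bulge", 31),
    internal_init = num("internal", 31),
    ninio_m = ninio[1], ninio_max = ninio[2],
    terminal_au = misc[1],
    lxc = misc[2],
    special_hairpins = c(special("Triloops"), special("Tetraloops"),
                         special("Hexaloops")),
    # auxiliary terms absent from this table dialect; zero by default,
    # kept as tunable knobs for sensitivity checks
    c_bulge_bonus = 0, c_hairpin_slope = 0, c_hairpin_intercept = 0,
    c_hairpin_of_3 = 0,
    temperature = 37,
    jacobson_coeff = misc[2] / 100)       # kcal/mol
  if (!all(is.finite(p$stack[1:6, 1:6]))) stop("malformed table 'stack'")
  structure(p, class = "turner_params")
}

read_param_sections <- function(paths) {
  sections <- list()
  cur <- NULL
  for (path in paths) {
    for (line in readLines(path, warn = FALSE)) {
      if (startsWith(line, "#")) {
        name <- trimws(sub("^#", "", line))
        if (name %in% PARAM_SECTIONS) {
          cur <- name
          sections[[cur]] <- character(0)
        }
        next
      }
      line <- trimws(line)
      if (!nzchar(line) || is.null(cur)) next
      sections[[cur]] <- c(sections[[cur]], strsplit(line, "\\s+")[[1]])
    }
    cur <- NULL
  }
  sections
}

#' @export
print.turner_params <- function(x, ...) {
  cat("turner_params: Turner 2004 free energies at 37 C;",
      length(x$special_hairpins), "special hairpins; terminal AU/GU penalty",
      sprintf("%.2f", x$terminal_au / 100), "kcal/mol\n")
  invisible(x)
}

# decacal initiation with Jacobson-Stockmayer extrapolation past size 30
loop_init <- function(tab, size, lxc) {
  if (size <= 30) tab[size + 1L] else tab[31L] + trunc(lxc * log(size / 30))
}

component_energy <- function(label, kind, terms = NULL, unscorable = FALSE,
                             reason = NA_character_) {
  structure(list(label = label, kind = kind,
                 dg = if (unscorable) NA_real_ else sum(terms) / 100,
                 terms = if (is.null(terms)) numeric(0) else terms / 100,
                 unscorable = unscorable, reason = reason),
            class = "component_energy")
}

#' @export
print.component_energy <- function(x, ...) {
  if (x$unscorable) {
    cat(x$label, " (", x$kind, "): unscorable [", x$reason, "]\n", sep = "")
  } else {
    cat(x$label, " (", x$kind, "): ", sprintf("%.2f", x$dg), " kcal/mol\n",
        sep = "")
  }
  invisible(x)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Stem (helix) free energy
#'
#' Sum of stacking terms over consecutive base-pair steps plus the AU/GU
#' helix-end penalty for each terminal pair. A length-1 stem has no stacks
#' and, with canonical G-C ends, zero energy. The end penalties can be
#' suppressed per end: in the Turner 2004 accounting the closure penalty at
#' hairpins and internal loops is embedded in their mismatch tables and the
#' explicit penalties of a bulge belong to the bulge term, so
#' [annotate_structure_energies()] applies the stem-side penalty only at
#' ends facing the exterior or a multiloop, keeping the component sum equal
#' to the standard nearest-neighbor total.
#'
#' @param stem One row of the `stems` data frame from [decompose()] (or any
#'   list with `start5`, `end5`, `end3`, `length`, `label`).
#' @param sequence The full RNA sequence.
#' @param params A `turner_params` object.
#' @param penalize_outer,penalize_inner Apply the AU/GU end penalty at the
#'   outermost / innermost pair.
#' @return A `component_energy`; unscorable (never silently zero) if any pair
#'   is non-canonical or touches a non-ACGU base.
#' @export
stem_dg <- function(stem, sequence, params, penalize_outer = TRUE,
                    penalize_inner = TRUE) {
  s <- seq_chars(sequence)
  len <- stem$length
  i5 <- stem$start5 + seq_len(len) - 1L
  i3 <- stem$end3 - seq_len(len) + 1L
  types <- pair_type(s[i5], s[i3])
  if (any(types == 0L)) {
    k <- which(types == 0L)[1]
    return(component_energy(stem$label, "stem", unscorable = TRUE,
                            reason = paste0("non-canonical pair ", s[i5[k]], i5[k],
                                            ":", s[i3[k]], i3[k])))
  }
  terms <- c()
  if (len > 1) {
    st <- vapply(seq_len(len - 1L), function(k) {
      params$stack[types[k], pair_type(s[i3[k + 1L]], s[i5[k + 1L]])]
    }, 0)
    terms <- c(terms, stats::setNames(st, paste0("stack", seq_len(len - 1L))))
  }
  if (penalize_outer && types[1] > 2L) {
    terms <- c(terms, au_end_outer = params$terminal_au)
  }
  if (penalize_inner && types[len] > 2L) {
    terms <- c(terms, au_end_inner = params$terminal_au)
  }
  if (is.null(terms)) terms <- c(none = 0)
  component_energy(stem$label, "stem", terms)
}

#' Hairpin loop free energy
#'
#' Special tabulated tri-/tetra-/hexaloop sequences (closing pair plus loop)
#' take their exact tabulated value. Otherwise: size-dependent initiation,
#' plus the terminal mismatch for loops of size >= 4 or the AU/GU closure
#' penalty for size-3 loops; sizes beyond 30 are extrapolated by the
#' Jacobson-Stockmayer log term. Loops of size 1-2 are below the Turner
#' minimum and are unscorable.
#'
#' @param h A hairpin record from [decompose()].
#' @inheritParams stem_dg
#' @return A `component_energy`.
#' @export
hairpin_dg <- function(h, sequence, params) {
  s <- seq_chars(sequence)
  a <- h$closing_pair[1]; b <- h$closing_pair[2]
  size <- h$size
  if (size < 3) {
    return(component_energy(h$label, "hairpin", unscorable = TRUE,
                            reason = paste0("size ", size, " below Turner minimum 3")))
  }
  involved <- s[a:b]
  if (!all(involved %in% BASE_ORDER4)) {
    return(component_energy(h$label, "hairpin", unscorable = TRUE,
                            reason = "ambiguous base in loop or closing pair"))
  }
  type <- pair_type(s[a], s[b])
  if (type == 0L) {
    return(component_energy(h$label, "hairpin", unscorable = TRUE,
                            reason = "non-canonical closing pair"))
  }
  if (size %in% c(3L, 4L, 6L)) {
    key <- paste(involved, collapse = "")
    hit <- params$special_hairpins[key]
    if (!is.na(hit)) {
      return(component_energy(h$label, "hairpin", c(special = unname(hit))))
    }
  }
  terms <- c(initiation = loop_init(params$hairpin_init, size, params$lxc))
  if (size == 3L) {
    if (type > 2L) terms <- c(terms, au_closure = params$terminal_au)
    if (all(s[(a + 1):(b - 1)] == "C") && params$c_hairpin_of_3 != 0) {
      terms <- c(terms, all_c = params$c_hairpin_of_3)
    }
  } else {
    terms <- c(terms, mismatch = params$mismatch_hairpin[
      type, base5_index(s[a + 1L]), base5_index(s[b - 1L])])
    if (all(s[(a + 1):(b - 1)] == "C") &&
        (params$c_hairpin_slope != 0 || params$c_hairpin_intercept != 0)) {
      terms <- c(terms, all_c = params$c_hairpin_slope * size +
                   params$c_hairpin_intercept)
    }
  }
  component_energy(h$label, "hairpin", terms)
}

#' Bulge loop free energy
#'
#' Size-1 bulges: initiation plus the stacking of the two closing pairs
#' across the bulge (no AU/GU penalties at this junction). Size >= 2:
#' initiation plus the AU/GU end penalty for each closing pair. Sizes beyond
#' 30 are extrapolated.
#'
#' @param b A bulge record from [decompose()].
#' @inheritParams stem_dg
#' @return A `component_energy`.
#' @export
bulge_dg <- function(b, sequence, params) {
  s <- seq_chars(sequence)
  oi <- b$outer_pair[1]; oj <- b$outer_pair[2]
  ik <- b$inner_pair[1]; il <- b$inner_pair[2]
  size <- b$size
  bases <- s[c(oi, oj, ik, il, b$bulge_positions)]
  if (!all(bases %in% BASE_ORDER4)) {
    return(component_energy(b$label, "bulge", unscorable = TRUE,
                            reason = "ambiguous base"))
  }
  type <- pair_type(s[oi], s[oj])
  type2 <- pair_type(s[il], s[ik])     # inner pair viewed 3'->5'
  if (type == 0L || type2 == 0L) {
    return(component_energy(b$label, "bulge", unscorable = TRUE,
                            reason = "non-canonical closing pair"))
  }
  terms <- c(initiation = loop_init(params$bulge_init, size, params$lxc))
  if (size == 1L) {
    terms <- c(terms, through_stack = params$stack[type, type2])
    if (params$c_bulge_bonus != 0 && s[b$bulge_positions[1]] == "C") {
      nb <- s[c(b$bulge_positions[1] - 1L, b$bulge_positions[1] + 1L)]
      if (any(nb == "C")) terms <- c(terms, c_bulge = params$c_bulge_bonus)
    }
  } else {
    if (type > 2L) terms <- c(terms, au_end_outer = params$terminal_au)
    if (type2 > 2L) terms <- c(terms, au_end_inner = params$terminal_au)
  }
  component_energy(b$label, "bulge", terms)
}

#' Internal loop free energy
#'
#' 1x1, 2x1/1x2 and 2x2 loops are exact table lookups; 2x3 and 1xn loops use
#' their dedicated mismatch tables; all other sizes use the generic
#' initiation + Ninio asymmetry (capped) + terminal-mismatch scheme, with
#' Jacobson-Stockmayer extrapolation beyond total size 30.
#'
#' @param il An internal-loop record from [decompose()].
#' @inheritParams stem_dg
#' @return A `component_energy`.
#' @export
internal_dg <- function(il, sequence, params) {
  s <- seq_chars(sequence)
  i <- il$outer_pair[1]; j <- il$outer_pair[2]
  p <- il$inner_pair[1]; q <- il$inner_pair[2]
  n1 <- il$sizes[1]; n2 <- il$sizes[2]
  bases <- s[c(i:p, q:j)]
  if (!all(bases %in% BASE_ORDER4)) {
    return(component_energy(il$label, "internal", unscorable = TRUE,
                            reason = "ambiguous base"))
  }
  type <- pair_type(s[i], s[j])
  type2 <- pair_type(s[q], s[p])
  if (type == 0L || type2 == 0L) {
    return(component_energy(il$label, "internal", unscorable = TRUE,
                            reason = "non-canonical closing pair"))
  }
  si1 <- s[i + 1L]; sj1 <- s[j - 1L]; sp1 <- s[p - 1L]; sq1 <- s[q + 1L]
  ns <- min(n1, n2); nl <- max(n1, n2)
  b5 <- base5_index; b4 <- base4_index

  if (ns == 1L && nl == 1L) {
    return(component_energy(il$label, "internal", c(
      int11 = params$int11[type, type2, b5(si1), b5(sj1)])))
  }
  if (ns == 1L && nl == 2L) {
    val <- if (n1 == 1L) {
      params$int21[type, type2, b5(si1), b5(sq1), b5(sj1)]
    } else {
      params$int21[type2, type, b5(sq1), b5(si1), b5(sp1)]
    }
    return(component_energy(il$label, "internal", c(int21 = val)))
  }
  if (ns == 2L && nl == 2L) {
    return(component_energy(il$label, "internal", c(
      int22 = params$int22[type, type2, b4(si1), b4(sp1), b4(sq1), b4(sj1)])))
  }
  if (ns == 2L && nl == 3L) {
    return(component_energy(il$label, "internal", c(
      initiation = params$internal_init[5L + 1L],
      asymmetry = params$ninio_m,
      mismatch5 = params$mismatch_internal_23[type, b5(si1), b5(sj1)],
      mismatch3 = params$mismatch_internal_23[type2, b5(sq1), b5(sp1)])))
  }
  if (ns == 1L) {   # 1xn, n >= 3
    return(component_energy(il$label, "internal", c(
      initiation = loop_init(params$internal_init, nl + 1L, params$lxc),
      asymmetry = min(params$ninio_max, (nl - ns) * params$ninio_m),
      mismatch5 = params$mismatch_internal_1n[type, b5(si1), b5(sj1)],
      mismatch3 = params$mismatch_internal_1n[type2, b5(sq1), b5(sp1)])))
  }
  component_energy(il$label, "internal", c(
    initiation = loop_init(params$internal_init, n1 + n2, params$lxc),
    asymmetry = min(params$ninio_max, (nl - ns) * params$ninio_m),
    mismatch5 = params$mismatch_internal[type, b5(si1), b5(sj1)],
    mismatch3 = params$mismatch_internal[type2, b5(sq1), b5(sp1)]))
}

#' Free energies of all scored substructures of one RNA
#'
#' Runs [decompose()] and scores every stem, hairpin, bulge and internal
#' loop; multiloop and exterior segments are annotated but never scored.
#' AU/GU helix-end penalties are assigned to the stem component, except at
#' stem ends flanking a single-nucleotide bulge where the nearest-neighbor
#' model stacks through the bulge. For single-branch structures (no
#' multiloop) the sum of the scored components equals the standard
#' nearest-neighbor total energy of the structure.
#'
#' @param x An `rna_structure`.
#' @param params A `turner_params` object; loaded from the packaged asset if
#'   omitted.
#' @return A `component_energies` object: data frame with columns `label`,
#'   `kind`, `dg` (kcal/mol), `unscorable`, `reason`, carrying the
#'   `substructure_set` as attribute `decomposition` and per-component term
#'   breakdowns as attribute `terms`.
#' @examples
#' s <- parse_dotbracket("toy", "GGGAAACCC", "(((...)))")
#' annotate_structure_energies(s)
#' @export
annotate_structure_energies <- function(x, params = load_turner_params()) {
  decomp <- decompose(x)
  # AU/GU closure effects at hairpins and internal loops are embedded in
  # their mismatch/table values, and bulge_dg carries the explicit penalties
  # of its closing pairs (none for size 1); so stems take the explicit end
  # penalty only at ends facing the exterior or a multiloop.
  no_inner <- character(0); no_outer <- character(0)
  for (h in decomp$hairpins) {
    no_inner <- c(no_inner, decomp$adjacency[[h$label]][1])
  }
  for (lp in c(decomp$bulges, decomp$internal_loops)) {
    adj <- decomp$adjacency[[lp$label]]
    no_inner <- c(no_inner, adj[1])   # outer stem's innermost pair
    no_outer <- c(no_outer, adj[2])   # inner stem's outermost pair
  }
  comps <- list()
  for (k in seq_len(nrow(decomp$stems))) {
    st <- decomp$stems[k, ]
    comps[[st$label]] <- stem_dg(st, x$sequence, params,
                                 penalize_outer = !(st$label %in% no_outer),
                                 penalize_inner = !(st$label %in% no_inner))
  }
  for (h in decomp$hairpins) comps[[h$label]] <- hairpin_dg(h, x$sequence, params)
  for (b in decomp$bulges) comps[[b$label]] <- bulge_dg(b, x$sequence, params)
  for (il in decomp$internal_loops) {
    comps[[il$label]] <- internal_dg(il, x$sequence, params)
  }
  out <- data.frame(
    label = vapply(comps, `[[`, "", "label"),
    kind = vapply(comps, `[[`, "", "kind"),
    dg = vapply(comps, `[[`, 0, "dg"),
    unscorable = vapply(comps, `[[`, TRUE, "unscorable"),
    reason = vapply(comps, `[[`, "", "reason"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "terms") <- lapply(comps, `[[`, "terms")
  attr(out, "decomposition") <- decomp
  class(out) <- c("component_energies", "data.frame")
  out
}

#' Total scored component energy of a single-branch structure
#'
#' Sum of all scored substructure energies. Defined (and tested) only for
#' single-branch structures, where no multiloop or dangling-end terms exist;
#' errors if any component is unscorable or a multiloop is present.
#'
#' @param energies A `component_energies` object.
#' @return Total free energy in kcal/mol.
#' @export
total_dg <- function(energies) {
  decomp <- attr(energies, "decomposition")
  if (any(decomp$other_regions$code == "M")) {
    stop("total_dg is defined only for single-branch structures (multiloop present)")
  }
  if (any(energies$unscorable)) {
    stop("unscorable component(s): ",
         paste(energies$label[energies$unscorable], collapse = ", "))
  }
  sum(energies$dg)
}
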