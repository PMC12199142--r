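# Secondary-structure parsing, decomposition and bpRNA-style file I/O.
# Coordinates are 1-based and ranges are inclusive throughout, matching the
# .st convention.

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse a dot-bracket string into an RNA secondary structure
#'
#' Builds an `rna_structure` from a sequence and its Vienna dot-bracket
#' annotation. Only the primary bracket page `()` contributes base pairs;
#' extended bracket pages (`[]`, `{}`, `<>`) denote pseudoknotted pairs, which
#' are recorded as unpaired with a warning so that downstream analysis runs on
#' the nested skeleton.
#'
#' @param id Character identifier for the structure.
#' @param sequence RNA sequence over `A`, `C`, `G`, `U` (plus `N`/ambiguity
#'   codes, tolerated but marked unscorable by the energy layer). `T` is
#'   converted to `U`.
#' @param db Dot-bracket string of the same length as `sequence`.
#' @param quiet Suppress the pseudoknot warning.
#' @return An object of class `rna_structure` with elements `id`, `sequence`,
#'   `pair_table` (integer partner index per position, 0 = unpaired),
#'   `position_codes` (per-position substructure code in S/H/B/I/M/E/X),
#'   `length`, `pseudoknot_positions` and `headers`.
#' @examples
#' s <- parse_dotbracket("h1", "GGGAAACCC", "(((...)))")
#' s$pair_table
#' paste(s$position_codes, collapse = "")
#' @export
parse_dotbracket <- function(id, sequence, db, quiet = FALSE) {
  sequence <- toupper(gsub("T", "U", sequence))
  if (nchar(sequence) != nchar(db)) {
    stop("sequence (", nchar(sequence), " nt) and dot-bracket (", nchar(db),
         " characters) differ in length for '", id, "'")
  }
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bad <- setdiff(unique(chars), c(".", BRACKET_OPEN, BRACKET_CLOSE, "-", "_", ","))
  if (length(bad) > 0) {
    stop("unsupported dot-bracket characters for '", id, "': ",
         paste(bad, collapse = " "))
  }
  pair_table <- integer(n)
  pk <- integer(0)
  for (page in seq_along(BRACKET_OPEN)) {
    op <- BRACKET_OPEN[page]; cl <- BRACKET_CLOSE[page]
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (chars[i] == op) {
        stack <- c(stack, i)
      } else if (chars[i] == cl) {
        if (length(stack) == 0) {
          stop("unbalanced dot-bracket for '", id, "': unmatched '", cl,
               "' at position ", i)
        }
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (page == 1L) {
          pair_table[j] <- i
          pair_table[i] <- j
        } else {
          pk <- c(pk, j, i)
        }
      }
    }
    if (length(stack) > 0) {
      stop("unbalanced dot-bracket for '", id, "': unclosed '", op,
           "' at position ", stack[length(stack)])
    }
  }
  pk <- sort(pk)
  if (length(pk) > 0 && !quiet) {
    warning("structure '", id, "': ", length(pk) / 2,
            " pseudoknot pair(s) on extended bracket pages dropped to unpaired")
  }
  structure(
    list(id = id,
         sequence = sequence,
         pair_table = pair_table,
         position_codes = position_codes_from_pairs(pair_table),
         length = n,
         pseudoknot_positions = pk,
         headers = character(0)),
    class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure '", x$id, "' (", x$length, " nt, ",
      sum(x$pair_table > 0) / 2, " pairs)\n", sep = "")
  cat(x$sequence, "\n", sep = "")
  cat(dotbracket_from_pairs(x$pair_table), "\n", sep = "")
  cat(paste(x$position_codes, collapse = ""), "\n", sep = "")
  invisible(x)
}

dotbracket_from_pairs <- function(pair_table) {
  n <- length(pair_table)
  out <- rep(".", n)
  paired <- which(pair_table > 0)
  out[paired[pair_table[paired] > paired]] <- "("
  out[paired[pair_table[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

# Per-position S/H/B/I/M/E/X codes from a nested pair table.
position_codes_from_pairs <- function(pair_table) {
  n <- length(pair_table)
  codes <- rep("E", n)
  codes[pair_table > 0] <- "S"
  # classify each maximal unpaired run by its flanking context
  i <- 1L
  while (i <= n) {
    if (pair_table[i] > 0) { i <- i + 1L; next }
    j <- i
    while (j < n && pair_table[j + 1L] == 0) j <- j + 1L
    codes[i:j] <- classify_unpaired_run(pair_table, i, j)
    i <- j + 1L
  }
  codes
}

# Classify an unpaired run [i, j] given the nested pair table. With both
# flanks paired there are four flank configurations: (open, close) closes a
# hairpin; (open, open) is the 5' side of a junction; (close, close) the 3'
# side; (close, open) lies between sibling helices (multiloop or exterior).
classify_unpaired_run <- function(pair_table, i, j) {
  n <- length(pair_table)
  if (i == 1L || j == n) return("E")           # terminal tail
  a <- i - 1L; b <- j + 1L
  a_opens <- pair_table[a] > a
  b_opens <- pair_table[b] > b
  if (a_opens && !b_opens) {
    if (pair_table[a] == b) return("H")
    return("M")                                 # unreachable on nested input
  }
  if (a_opens && b_opens) {
    # 5' side between outer pair (a, pt[a]) and inner pair (b, pt[b])
    if (pair_table[a] > pair_table[b] && same_junction(pair_table, a, b)) {
      gap3 <- pair_table[a] - pair_table[b] - 1L
      return(if (gap3 == 0L) "B" else "I")
    }
    return("M")
  }
  if (!a_opens && !b_opens) {
    # 3' side between inner pair (pt[a], a) and outer pair (pt[b], b)
    if (pair_table[b] < pair_table[a] &&
        same_junction(pair_table, pair_table[b], pair_table[a])) {
      gap5 <- pair_table[a] - pair_table[b] - 1L
      return(if (gap5 == 0L) "B" else "I")
    }
    return("M")
  }
  # a closes, b opens: between two sibling helices
  if (enclosing_pair(pair_table, i)[1] == 0L) "X" else "M"
}

# TRUE iff pair (outer_i, pair[outer_i]) directly encloses (inner_k, pair[inner_k])
# with no other helix branching between them (two-way junction).
same_junction <- function(pair_table, outer_i, inner_k) {
  oj <- pair_table[outer_i]; il <- pair_table[inner_k]
  if (!(outer_i < inner_k && il < oj)) return(FALSE)
  gap5 <- if (inner_k > outer_i + 1L) (outer_i + 1L):(inner_k - 1L) else integer(0)
  gap3 <- if (oj > il + 1L) (il + 1L):(oj - 1L) else integer(0)
  all(pair_table[c(gap5, gap3)] == 0L)
}

# Innermost pair (i, j) with i < pos < j, or c(0, 0).
enclosing_pair <- function(pair_table, pos) {
  best <- c(0L, 0L); width <- Inf
  opens <- which(pair_table > seq_along(pair_table))
  for (i in opens) {
    j <- pair_table[i]
    if (i < pos && pos < j && (j - i) < width) { best <- c(i, j); width <- j - i }
  }
  best
}

#' Decompose a structure into typed substructures
#'
#' Identifies maximal helices (stems), hairpin loops, bulges, internal loops
#' and the remaining multiloop/exterior segments, together with the loop-stem
#' adjacency map that underlies the net-ΔG statistic: a hairpin is adjacent to
#' its single closing stem, a bulge or internal loop to the two stems flanking
#' the two-way junction. A single isolated base pair counts as a stem of
#' length 1 so two-way junction adjacency is always defined.
#'
#' @param x An `rna_structure` from [parse_dotbracket()] or [read_st()].
#' @return A `substructure_set`: list with data frame `stems` (label,
#'   strand5/strand3 ranges, length), lists `hairpins`, `bulges`,
#'   `internal_loops`, a data frame `other_regions` (multiloop/exterior runs,
#'   annotated but never scored), and `adjacency` (named list mapping loop
#'   label to adjacent stem label(s)).
#' @examples
#' decompose(parse_dotbracket("h1", "GGGAAACCC", "(((...)))"))
#' @export
decompose <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  pt <- x$pair_table
  n <- x$length

  # --- stems: maximal stacked runs; pair (i,j) stacks on (i+1, j-1)
  opens <- which(pt > seq_len(n))
  opens <- opens[order(opens)]
  stem_of_pair <- integer(n)            # stem index by opening position
  stems <- list()
  for (i in opens) {
    j <- pt[i]
    prev <- if (i > 1L && pt[i - 1L] == j + 1L) stem_of_pair[i - 1L] else 0L
    if (prev > 0L) {
      stems[[prev]]$open <- c(stems[[prev]]$open, i)
      stem_of_pair[i] <- prev
    } else {
      stems[[length(stems) + 1L]] <- list(open = i)
      stem_of_pair[i] <- length(stems)
    }
  }
  stem_df <- data.frame(
    label = if (length(stems)) paste0("S", seq_along(stems)) else character(0),
    start5 = vapply(stems, function(s) min(s$open), integer(1)),
    end5 = vapply(stems, function(s) max(s$open), integer(1)),
    start3 = vapply(stems, function(s) pt[max(s$open)], integer(1)),
    end3 = vapply(stems, function(s) pt[min(s$open)], integer(1)),
    length = vapply(stems, function(s) length(s$open), integer(1)),
    stringsAsFactors = FALSE)

  stem_label_at <- function(open_pos) stem_df$label[stem_of_pair[open_pos]]

  # --- loops from unpaired runs, reusing the positional classification
  hairpins <- list(); bulges <- list(); internals <- list()
  other <- list(); adjacency <- list()
  seen_internal <- character(0)
  i <- 1L
  while (i <= n) {
    if (pt[i] > 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && pt[j + 1L] == 0L) j <- j + 1L
    code <- x$position_codes[i]
    if (code == "H") {
      a <- i - 1L; b <- j + 1L
      lab <- paste0("H", length(hairpins) + 1L)
      hairpins[[lab]] <- list(label = lab, closing_pair = c(a, b),
                              loop_positions = i:j, size = j - i + 1L)
      adjacency[[lab]] <- stem_label_at(a)
    } else if (code == "B") {
      bi <- bulge_geometry(pt, i, j)
      lab <- paste0("B", length(bulges) + 1L)
      bulges[[lab]] <- c(list(label = lab), bi)
      adjacency[[lab]] <- c(stem_label_at(bi$outer_pair[1]),
                            stem_label_at(bi$inner_pair[1]))
    } else if (code == "I") {
      geo <- internal_geometry(pt, i, j)
      key <- paste(geo$outer_pair, collapse = "-")
      if (!(key %in% seen_internal)) {     # two runs, one loop record
        seen_internal <- c(seen_internal, key)
        lab <- paste0("I", length(internals) + 1L)
        internals[[lab]] <- c(list(label = lab), geo)
        adjacency[[lab]] <- c(stem_label_at(geo$outer_pair[1]),
                              stem_label_at(geo$inner_pair[1]))
      }
    } else {
      other[[length(other) + 1L]] <- data.frame(
        code = code, start = i, end = j, stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  other_df <- if (length(other)) do.call(rbind, other) else
    data.frame(code = character(0), start = integer(0), end = integer(0))

  structure(
    list(structure_id = x$id, stems = stem_df, hairpins = hairpins,
         bulges = bulges, internal_loops = internals,
         other_regions = other_df, adjacency = adjacency),
    class = "substructure_set")
}

# Geometry of a bulge whose unpaired run is [i, j].
bulge_geometry <- function(pt, i, j) {
  n <- length(pt)
  a <- i - 1L; b <- j + 1L
  if (pt[a] > a) {                       # 5' side bulge: a opens, b opens inner
    outer <- c(a, pt[a]); inner <- c(b, pt[b]); side <- "5'"
  } else {                               # 3' side bulge: a closes inner, b closes outer
    outer <- c(pt[b], b); inner <- c(pt[a], a); side <- "3'"
  }
  list(outer_pair = outer, inner_pair = inner, bulged_side = side,
       bulge_positions = i:j, size = j - i + 1L)
}

# Geometry of an internal loop given one of its unpaired runs [i, j].
internal_geometry <- function(pt, i, j) {
  a <- i - 1L; b <- j + 1L
  if (pt[a] > a) {                       # this is the 5' side run
    outer <- c(a, pt[a]); inner <- c(b, pt[b])
  } else {
    outer <- c(pt[b], b); inner <- c(pt[a], a)
  }
  side5 <- (outer[1] + 1L):(inner[1] - 1L)
  side3 <- (inner[2] + 1L):(outer[2] - 1L)
  list(outer_pair = outer, inner_pair = inner,
       side5_positions = side5, side3_positions = side3,
       sizes = c(length(side5), length(side3)),
       size = length(side5) + length(side3))
}

#' @export
print.substructure_set <- function(x, ...) {
  cat("substructure_set for '", x$structure_id, "': ",
      nrow(x$stems), " stems, ", length(x$hairpins), " hairpins, ",
      length(x$bulges), " bulges, ", length(x$internal_loops),
      " internal loops\n", sep = "")
  invisible(x)
}

#' Read a bpRNA-style structure-type (.st) file
#'
#' Accepts the bpRNA `.st` dialect: `#`-prefixed header lines, then the
#' sequence line, the dot-bracket line and the per-position structure-code
#' line; any further segment/annotation lines are ignored on read. Structure
#' codes recomputed from the dot-bracket are compared with the file's code
#' line and disagreements raise a validation warning listing the positions
#' (expected on pseudoknotted entries, whose codes this package does not
#' reproduce).
#'
#' @param path Path to the `.st` (or `.ste`) file.
#' @param quiet Suppress validation warnings.
#' @return An `rna_structure`; `#` headers are kept in `$headers` and the
#'   file's own code line in `$file_codes`.
#' @export
read_st <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  headers <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) < 3) {
    stop("malformed .st file '", path,
         "': need sequence, dot-bracket and structure-code lines")
  }
  seqline <- body[1]; dbline <- body[2]; codeline <- body[3]
  if (!grepl("^[ACGUTNacgutn]+$", seqline)) {
    stop("malformed .st file '", path, "': first body line is not a sequence")
  }
  if (nchar(seqline) != nchar(dbline) || nchar(seqline) != nchar(codeline)) {
    stop("malformed .st file '", path,
         "': sequence/dot-bracket/code line lengths differ")
  }
  id <- sub("^#\\s*Name:\\s*", "",
            headers[grepl("^#\\s*Name:", headers)][1])
  if (is.na(id) || !nzchar(id)) id <- basename(path)
  st <- parse_dotbracket(id, seqline, dbline, quiet = quiet)
  st$headers <- headers
  st$file_codes <- strsplit(toupper(codeline), "")[[1]]
  mism <- which(st$file_codes != st$position_codes)
  # pseudoknot positions legitimately differ (file says K/etc., we say unpaired code)
  mism <- setdiff(mism, st$pseudoknot_positions)
  if (length(mism) > 0 && !quiet) {
    warning("'", path, "': structure codes disagree with recomputed codes at ",
            length(mism), " position(s): ",
            paste(utils::head(mism, 10), collapse = ", "),
            if (length(mism) > 10) ", ..." else "")
  }
  st
}

#' Write a structure-type-with-energies (.ste) file
#'
#' Emits the `.st` content (headers, sequence, dot-bracket, structure codes)
#' plus one annotation line per scored substructure appending its free energy
#' in kcal/mol to two decimals, e.g. `S1 1..3 "GGG" 7..9 "CCC" -3.30`.
#' Coordinates are 1-based inclusive. The file round-trips through
#' [read_st()] / [read_ste_energies()].
#'
#' @param x An `rna_structure`.
#' @param energies A `component_energies` object from
#'   [annotate_structure_energies()] (or a compatible data frame with columns
#'   `label` and `dg`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ste <- function(x, energies, path) {
  stopifnot(inherits(x, "rna_structure"))
  decomp <- decompose(x)
  etab <- as.data.frame(energies)
  scored <- c(decomp$stems$label, names(decomp$hairpins), names(decomp$bulges),
              names(decomp$internal_loops))
  missing <- setdiff(scored, etab$label)
  if (length(missing) > 0) {
    stop("no energy record for substructure(s): ", paste(missing, collapse = ", "))
  }
  dg_of <- function(lab) sprintf("%.2f", etab$dg[match(lab, etab$label)])
  seg <- function(a, b) paste0(a, "..", b, " \"", substr(x$sequence, a, b), "\"")
  lines <- c(
    if (length(x$headers)) x$headers else paste0("#Name: ", x$id),
    x$sequence,
    dotbracket_from_pairs(x$pair_table),
    paste(x$position_codes, collapse = ""))
  for (k in seq_len(nrow(decomp$stems))) {
    s <- decomp$stems[k, ]
    lines <- c(lines, paste(s$label, seg(s$start5, s$end5),
                            seg(s$start3, s$end3), dg_of(s$label)))
  }
  for (h in decomp$hairpins) {
    lines <- c(lines, paste(h$label,
                            seg(min(h$loop_positions), max(h$loop_positions)),
                            dg_of(h$label)))
  }
  for (b in decomp$bulges) {
    lines <- c(lines, paste(b$label,
                            seg(min(b$bulge_positions), max(b$bulge_positions)),
                            dg_of(b$label)))
  }
  for (il in decomp$internal_loops) {
    lines <- c(lines, paste(il$label,
                            seg(min(il$side5_positions), max(il$side5_positions)),
                            seg(min(il$side3_positions), max(il$side3_positions)),
                            dg_of(il$label)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the per-substructure energies back from a .ste file
#'
#' @param path Path to a `.ste` file written by [write_ste()].
#' @return Data frame with columns `label` and `dg` (kcal/mol).
#' @export
read_ste_energies <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seglines <- grep("^[SHBI][0-9]+ ", lines, value = TRUE)
  if (length(seglines) == 0) {
    return(data.frame(label = character(0), dg = numeric(0)))
  }
  parts <- strsplit(seglines, " ")
  data.frame(
    label = vapply(parts, `[`, "", 1L),
    dg = vapply(parts, function(p) as.numeric(p[length(p)]), 0),
    stringsAsFactors = FALSE)
}

#' Export hard base-pair constraints for an external folding engine
#'
#' Produces the per-position constraint string in the standard Vienna
#' folding-constraint notation: designed pairs are forced (`(` and `)`), all
#' other positions are unconstrained (`.`). Pseudoknot positions flagged at
#' parse time are left unconstrained with a warning. The refolded dot-bracket
#' returned by the engine is re-ingested with [parse_dotbracket()].
#'
#' @param x An `rna_structure`.
#' @param quiet Suppress the pseudoknot warning.
#' @return A single constraint string of the same length as the sequence.
#' @export
export_hard_constraints <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "rna_structure"))
  if (length(x$pseudoknot_positions) > 0 && !quiet) {
    warning("structure '", x$id, "': pseudoknot positions left unconstrained")
  }
  dotbracket_from_pairs(x$pair_table)
}
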